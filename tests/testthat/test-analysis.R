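# synthetic analysis table with a planted group-varying linear dependence of
# the error outcomes on the compositional log-likelihood
planted_table <- function(n = 500, n_groups = 10, beta = -0.2, seed = 1,
                          noise_sd = 0.2) {
  set.seed(seed)
  g <- sample(n_groups, n, replace = TRUE)
  ll_comp <- rnorm(n, -50, 10)
  ll_spec <- rnorm(n, -55, 10)
  intercept <- 3 + rnorm(n_groups, 0, 0.3)[g]
  z <- (ll_comp - mean(ll_comp)) / sd(ll_comp)
  err <- intercept + beta * z + rnorm(n, 0, noise_sd)
  data.frame(pattern_id = paste0("p", seq_len(n)),
             drawer_id = paste0("g", g),
             absolute_error = err, wavelet_distance = err,
             mean_rating = 100 - 10 * err,
             loglik_comp = ll_comp, loglik_spectral = ll_spec,
             loglik_LIN = rnorm(n), loglik_RBF = rnorm(n),
             loglik_PER = rnorm(n),
             is_compositional = rep(c(TRUE, FALSE), length.out = n))
}

test_that("analysis tables join game output with fits one row per pattern-drawer", {
  ds <- simulate_game(game_config(n_describers = 2, n_drawers = 2, n_raters = 3,
                                  set_size = 3, pool_size = 6,
                                  ratings_per_rater = 8, seed = 5,
                                  channel = "dot-noise-only"))
  fits <- fit_dataset_patterns(ds, n_restarts = 1, seed = 9)
  tab <- build_table(ds, fits)
  expect_lte(nrow(tab), 2 * 6)
  expect_true(all(c("loglik_comp", "loglik_spectral", "loglik_LIN",
                    "loglik_RBF", "loglik_PER", "is_compositional") %in%
                  names(tab)))
  expect_false(anyNA(tab$loglik_comp))
  expect_equal(mean(tab$z_loglik_comp), 0, tolerance = 1e-10)
  expect_equal(sd(tab$z_loglik_comp), 1, tolerance = 1e-10)
  # best-structure log ML dominates every single-component log ML
  expect_true(all(tab$loglik_comp >= tab$loglik_LIN - 1e-6))
  # deterministic on identical inputs
  expect_identical(tab, build_table(ds, fits))
  # orphan identifiers are reported
  expect_error(build_table(ds, fits[-1]), "without fits")
})

test_that("planted regression coefficients are recovered", {
  hits <- 0
  for (s in 1:5) {
    tab <- planted_table(seed = s)
    res <- regress_errors(tab, "absolute_error",
                          c("loglik_comp", "loglik_spectral"))
    b <- res$coefficients$estimate[res$coefficients$term == "loglik_comp"]
    if (abs(b - (-0.2)) < 0.1) hits <- hits + 1
  }
  expect_gte(hits, 4)
  expect_error(regress_errors(transform(planted_table(), absolute_error = 1),
                              "absolute_error", "loglik_comp"), "degenerate")
})

test_that("null effects stay within two standard errors", {
  cover <- 0
  for (s in 1:20) {
    tab <- planted_table(n = 300, beta = 0, seed = 200 + s)
    res <- regress_errors(tab, "absolute_error", "loglik_comp")
    cf <- res$coefficients[res$coefficients$term == "loglik_comp", ]
    if (abs(cf$estimate) < 2 * cf$se) cover <- cover + 1
  }
  expect_gte(cover, 17)
})

test_that("BIC Bayes factors favor the model with the planted predictor", {
  wins <- 0
  for (s in 1:5) {
    tab <- planted_table(seed = 40 + s)
    comp_only <- regress_errors(tab, "absolute_error", "loglik_comp")
    spec_only <- regress_errors(tab, "absolute_error", "loglik_spectral")
    if (compare_models(comp_only, spec_only) > 10) wins <- wins + 1
  }
  expect_gte(wins, 4)
  # identity and antisymmetry
  tab <- planted_table(seed = 99)
  a <- regress_errors(tab, "absolute_error", "loglik_comp")
  expect_equal(compare_models(a, a), 1)
  b <- regress_errors(tab, "absolute_error", "loglik_spectral")
  expect_equal(compare_models(a, b) * compare_models(b, a), 1, tolerance = 1e-8)
  expect_error(compare_models(a, regress_errors(tab, "wavelet_distance",
                                                "loglik_comp")), "share")
})

test_that("single-component controls detect a planted compositional advantage", {
  mk <- function(seed, advantage) {
    tab <- planted_table(n = 500, beta = 0, seed = seed, noise_sd = 0.3)
    tab$absolute_error <- tab$absolute_error -
      advantage * tab$is_compositional +
      0.1 * zscore(tab$loglik_LIN)
    tab
  }
  ctl <- control_single_components(mk(1, advantage = 0.5), "absolute_error")
  expect_named(ctl, c("LIN", "RBF", "PER"))
  expect_true(all(sapply(ctl, function(x) x$bf) > 3))
  ctl0 <- control_single_components(mk(2, advantage = 0), "absolute_error")
  expect_true(all(sapply(ctl0, function(x) x$bf) < 3))
})

test_that("word-presence regression recovers planted emission dependence", {
  sim_presence <- function(seed, slope) {
    set.seed(seed)
    n <- 400
    g <- sample(8, n, replace = TRUE)
    prob <- runif(n, 0.2, 0.9)
    z <- (prob - mean(prob)) / sd(prob)
    eta <- -0.3 + slope * z + rnorm(8, 0, 0.2)[g]
    data.frame(describer_id = paste0("d", g),
               presence = rbinom(n, 1, plogis(eta)),
               component_prob = prob)
  }
  pos <- 0
  for (s in 1:20) {
    r <- regress_word_presence(sim_presence(s, slope = 1.2))
    if (r$slope > 0 && r$slope - 2 * r$se > 0) pos <- pos + 1
  }
  expect_gte(pos, 16)
  cover <- 0
  for (s in 1:20) {
    r <- regress_word_presence(sim_presence(300 + s, slope = 0))
    if (abs(r$slope) < 2 * r$se) cover <- cover + 1
  }
  expect_gte(cover, 17)
  # reverse direction by flag
  r2 <- regress_word_presence(sim_presence(7, slope = 1.2),
                              direction = "prob_on_presence")
  expect_gt(r2$slope, 0)
  # empty vocabulary is rejected at table construction
  expect_error(word_presence_table(list(), list(), character(0), "LIN"),
               "empty vocabulary")
})
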