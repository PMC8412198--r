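test_that("log marginal likelihood has the closed-form value in degenerate cases", {
  # N = 1, y = 0, K + noise = 1 (up to the documented jitter): -log(2*pi)/2
  s <- kernel_spec(k_lin(), list(theta1 = 0, noise_var = 1))
  expect_equal(log_marginal_likelihood(s, 0, 0), -0.5 * log(2 * pi),
               tolerance = 1e-5)
  # N = 2, y = 0, K + noise = I: -log(2*pi)
  expect_equal(log_marginal_likelihood(s, c(0, 0), c(0, 0)), -log(2 * pi),
               tolerance = 1e-5)
})

test_that("log marginal likelihood matches the dense MVN oracle", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(2:20, 1)
    x <- sort(runif(n))
    y <- rnorm(n)
    spec <- sample_compositional_spec()
    spec$params$noise_var <- runif(1, 0.01, 0.5)
    expect_equal(log_marginal_likelihood(spec, x, y),
                 oracle_mvn_logdens(y, noisy_cov(spec, x)),
                 tolerance = 1e-8)
  }
})

test_that("posterior prediction matches explicit Gaussian conditioning", {
  set.seed(202)
  for (i in 1:25) {
    n <- sample(3:10, 1)
    x <- sort(runif(n))
    y <- rnorm(n)
    xs <- runif(4)
    spec <- sample_compositional_spec()
    spec$params$noise_var <- runif(1, 0.01, 0.3)
    p <- posterior_predict(spec, x, y, xs)
    Ky <- noisy_cov(spec, x)
    Ks <- evaluate_kernel(spec, x, xs)
    Kss <- evaluate_kernel(spec, xs, xs)
    m <- drop(t(Ks) %*% solve(Ky) %*% y)
    v <- diag(Kss - t(Ks) %*% solve(Ky) %*% Ks)
    expect_equal(p$mean, m, tolerance = 1e-8)
    expect_equal(p$variance, pmax(v, 0), tolerance = 1e-8)
  }
})

test_that("posterior recovers the prior far from data and interpolates noiselessly", {
  spec <- kernel_spec(k_rbf(), list(theta2 = 1.3, theta3 = 0.02,
                                    noise_var = 1e-8))
  x <- c(0.1, 0.12, 0.15)
  y <- c(0.5, -0.2, 0.3)
  far <- posterior_predict(spec, x, y, 0.9)
  expect_equal(far$mean, 0, tolerance = 1e-6)
  expect_equal(far$variance, 1.3^2, tolerance = 1e-4)
  at <- posterior_predict(spec, x, y, x[2])
  expect_equal(at$mean, y[2], tolerance = 1e-3)
  expect_lt(at$variance, 1e-4)
})

test_that("predictive variance is nonnegative across random specs and test points", {
  set.seed(303)
  for (i in 1:10) {
    spec <- if (i %% 2) sample_compositional_spec() else sample_spectral_spec()
    spec$params$noise_var <- runif(1, 1e-4, 0.2)
    x <- sort(runif(12)); y <- rnorm(12)
    p <- posterior_predict(spec, x, y, runif(100))
    expect_true(all(p$variance >= 0))
  }
})

test_that("hyperparameter optimization improves on mismatched parameters", {
  set.seed(11)
  x <- pattern_grid()
  y <- 1.5 * (x - 0.5) + rnorm(100, 0, 0.05)
  fit <- gp_fit(x, y, k_lin(), n_restarts = 3, seed = 1)
  bad <- kernel_spec(k_lin(), list(theta1 = 4.9, noise_var = 0.01))
  expect_gt(fit$log_ml, log_marginal_likelihood(bad, x, y))
  expect_true(fit$converged)
})

test_that("fitting is reproducible given a seed", {
  set.seed(12)
  x <- pattern_grid()
  y <- sin(2 * pi * x / 0.3) + rnorm(100, 0, 0.1)
  f1 <- gp_fit(x, y, k_per(), n_restarts = 3, seed = 7)
  f2 <- gp_fit(x, y, k_per(), n_restarts = 3, seed = 7)
  expect_identical(f1$log_ml, f2$log_ml)
  expect_identical(coef(f1), coef(f2))
  g1 <- gp_grammar(x = x, y = y, n_restarts = 1, seed = 5)
  g2 <- gp_grammar(x = x, y = y, n_restarts = 1, seed = 5)
  expect_identical(g1$log_ml, g2$log_ml)
})

test_that("the periodic kernel recovers a planted period", {
  ok <- 0
  for (s in 1:20) {
    set.seed(4000 + s)
    x <- pattern_grid()
    y <- sin(2 * pi * x / 0.2) + rnorm(100, 0, 0.05)
    f <- gp_fit(x, y, k_per(), n_restarts = 5, seed = s, standardize = TRUE)
    if (abs(f$spec$params$theta5 - 0.2) / 0.2 < 0.10) ok <- ok + 1
  }
  expect_gte(ok, 16)
})

test_that("grammar search handles degenerate input and finds planted structure", {
  x <- pattern_grid()
  # constant zero pattern completes with flags, no error
  g0 <- gp_grammar(x = x, y = rep(0, 100), n_restarts = 1, seed = 1)
  expect_length(g0$fits, 17)
  expect_type(vapply(g0$fits, `[[`, logical(1), "converged"), "logical")
  # noisy ramp: best structure contains LIN
  set.seed(21)
  g1 <- gp_grammar(x = x, y = 2 * x + rnorm(100, 0, 0.05),
                   n_restarts = 2, seed = 2)
  leaves <- strsplit(gsub("[()]", "", gsub("\\*", "+", names(g1$fits)[g1$best])),
                     "\\+")[[1]]
  expect_true("LIN" %in% leaves)
  expect_equal(unname(g1$log_ml[g1$best]), max(g1$log_ml))
})

test_that("component scores follow the summed log-likelihood ratio", {
  # equal log ML everywhere: any component sits in 13 of 17 structures
  gf <- fake_grammar(rep(-5, 17))
  for (comp in c("LIN", "RBF", "PER")) {
    expect_equal(as.numeric(component_probability(gf, comp)), 13 / 17)
  }
  # restricted to the three singletons with equal log ML: 1/3 each
  singles <- enumerate_grammar()[c("LIN", "RBF", "PER")]
  gf3 <- fake_grammar(rep(-2, 3), structures = singles)
  expect_equal(as.numeric(component_probability(gf3, "PER")), 1 / 3)
  # scores need not sum to one across components
  expect_gt(sum(sapply(c("LIN", "RBF", "PER"), function(b)
    as.numeric(component_probability(gf, b)))), 1)
  # mixed signs in the denominator attach a warning; softmax mode does not
  gfm <- fake_grammar(c(rep(5, 8), rep(-5, 9)))
  expect_warning(component_probability(gfm, "LIN"), "mixed-sign")
  sm <- component_probability(gfm, "LIN", mode = "softmax")
  expect_gte(sm, 0); expect_lte(sm, 1)
})

test_that("model methods are coherent on a fitted object", {
  set.seed(31)
  x <- pattern_grid()
  y <- 2 * x + rnorm(100, 0, 0.1)
  f <- gp_fit(x, y, k_lin(), n_restarts = 2, seed = 1, standardize = TRUE)
  expect_named(coef(f), c("theta1", "noise_var"))
  p <- predict(f, newdata = c(0.25, 0.75))
  expect_length(p$mean, 2)
  # posterior mean tracks the ramp on the original scale
  expect_equal(p$mean, 2 * c(0.25, 0.75), tolerance = 0.15)
  r <- residuals(f)
  expect_lt(mean(abs(r)), 0.15)
  sims <- simulate(f, nsim = 3, seed = 9, newdata = c(0.2, 0.4, 0.6))
  expect_equal(dim(sims), c(3, 3))
  expect_output(print(f), "GP fit")
  g <- gp_grammar(x = x, y = y, n_restarts = 1, seed = 2)
  expect_output(print(summary(g)), "best structure")
  expect_equal(nrow(grammar_fit_table(g, "p1")), 17)
})
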