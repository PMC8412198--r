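#' Linking model likelihoods to communicability
#'
#' The statistical layer: build one row per (pattern, drawer) pair carrying
#' reconstruction errors, ratings, model log marginal likelihoods and
#' controls; regress outcomes on standardized likelihood predictors with
#' random intercepts and slopes by participant; and compare models through
#' the BIC approximation to the Bayes factor, BF_ab = exp((BIC_b - BIC_a)/2).
#'
#' @name communicability_analysis
NULL

#' Fit the grammar (and spectral model) to every pattern of a dataset
#'
#' @param dataset a `"game_dataset"`
#' @param n_restarts,seed passed to [gp_grammar()]
#' @return named list of `"gp_grammar"` objects keyed by pattern id
#' @export
fit_dataset_patterns <- function(dataset, n_restarts = 2, seed = 1) {
  fits <- list()
  for (i in seq_along(dataset$patterns)) {
    p <- dataset$patterns[[i]]
    fits[[p$pattern_id]] <- gp_grammar(x = p$x, y = p$y,
                                       include_spectral = TRUE,
                                       n_restarts = n_restarts,
                                       seed = seed + i)
  }
  fits
}

#' Assemble the analysis table
#'
#' One row per (pattern_id, drawer_id) pair: absolute error and wavelet
#' distance of the drawing against the original, mean rating, best-grammar
#' and spectral log marginal likelihoods, the three single-component log
#' marginal likelihoods, optional memorability scores, and the
#' compositional flag.  Standardized (z-scored) copies of the likelihood
#' and memorability predictors are added with a `z_` prefix.
#'
#' @param dataset a `"game_dataset"`
#' @param fits named list of `"gp_grammar"` fits keyed by pattern id (see
#'   [fit_dataset_patterns()]); must include the spectral fit
#' @param memorability optional named numeric vector keyed by pattern id
#' @return a data frame
#' @export
build_table <- function(dataset, fits, memorability = NULL) {
  orphan <- setdiff(names(dataset$patterns), names(fits))
  if (length(orphan) > 0) {
    stop("patterns without fits: ", paste(orphan, collapse = ", "))
  }
  rows <- lapply(dataset$drawings, function(dr) {
    pat <- dataset$patterns[[dr$pattern_id]]
    if (is.null(pat)) stop("drawing references unknown pattern ", dr$pattern_id)
    gf <- fits[[dr$pattern_id]]
    recon <- if (is.null(dr$resampled)) spline_resample(dr, pat$x) else dr$resampled
    rt <- dataset$ratings[dataset$ratings$pattern_id == dr$pattern_id &
                          dataset$ratings$drawer_id == dr$drawer_id, "score"]
    singles <- gf$log_ml[BASE_KERNELS]
    data.frame(
      pattern_id = dr$pattern_id, drawer_id = dr$drawer_id,
      absolute_error = absolute_error(pat$y, recon),
      wavelet_distance = wavelet_distance(pat$y, recon),
      mean_rating = if (length(rt) > 0) mean(rt) else NA_real_,
      loglik_comp = unname(gf$log_ml[gf$best]),
      loglik_spectral = if (!is.null(gf$spectral)) gf$spectral$log_ml else NA_real_,
      loglik_LIN = singles[["LIN"]], loglik_RBF = singles[["RBF"]],
      loglik_PER = singles[["PER"]],
      memorability = if (!is.null(memorability)) {
        if (is.null(memorability[[dr$pattern_id]]))
          stop("no memorability score for pattern ", dr$pattern_id)
        memorability[[dr$pattern_id]]
      } else NA_real_,
      is_compositional = pat$source_class == "compositional",
      row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  for (col in c("loglik_comp", "loglik_spectral", "loglik_LIN", "loglik_RBF",
                "loglik_PER", "memorability")) {
    if (!all(is.na(tab[[col]]))) tab[[paste0("z_", col)]] <- zscore(tab[[col]])
  }
  tab
}

## shared lmer machinery: random intercept + slopes with intercept-only fallback
.fit_lmm <- function(formula_full, formula_fallback, data) {
  fallback <- FALSE
  model <- tryCatch({
    m <- suppressWarnings(suppressMessages(
      lme4::lmer(formula_full, data = data, REML = TRUE)))
    if (lme4::isSingular(m, tol = 1e-4)) stop("singular")
    m
  }, error = function(e) NULL)
  if (is.null(model)) {
    fallback <- TRUE
    model <- suppressWarnings(suppressMessages(
      lme4::lmer(formula_fallback, data = data, REML = TRUE)))
  }
  list(model = model, fallback = fallback)
}

.lmm_result <- function(fit, outcome, grouping, data) {
  model <- fit$model
  cf <- summary(model)$coefficients
  ml <- lme4::refitML(model)
  out <- list(coefficients = data.frame(term = rownames(cf),
                                        estimate = cf[, "Estimate"],
                                        se = cf[, "Std. Error"],
                                        row.names = NULL),
              outcome = outcome, grouping = grouping,
              n = nrow(data), logLik = as.numeric(stats::logLik(ml)),
              BIC = stats::BIC(ml), fallback = fit$fallback,
              model = model)
  class(out) <- "comm_regression"
  out
}

#' @export
print.comm_regression <- function(x, ...) {
  cat("Mixed-effects regression of ", x$outcome, " (n = ", x$n,
      ", grouping: ", x$grouping, ")",
      if (x$fallback) "  [random-intercept fallback]", "\n", sep = "")
  print(transform(x$coefficients, estimate = signif(estimate, 4),
                  se = signif(se, 4)), row.names = FALSE)
  cat("BIC (ML):", format(x$BIC, digits = 6), "\n")
  invisible(x)
}

#' Regress a communicability outcome on model likelihoods
#'
#' Fits a hierarchical linear model of the outcome on z-scored predictors
#' with a random intercept and random slopes for every predictor by the
#' grouping factor (REML).  A singular or failing random-slope fit falls
#' back to a random-intercept-only model, flagged in the result.  The BIC
#' reported for model comparison comes from an ML refit.
#'
#' @param table a data frame (see [build_table()])
#' @param outcome column name: `"absolute_error"`, `"wavelet_distance"` or
#'   `"mean_rating"` (any numeric column works)
#' @param predictors character vector of predictor column names; each is
#'   z-scored before fitting
#' @param grouping column name of the participant grouping factor
#' @return a `"comm_regression"` with standardized coefficients, SEs,
#'   log-likelihood and BIC
#' @export
regress_errors <- function(table, outcome, predictors,
                           grouping = "drawer_id") {
  stopifnot(outcome %in% names(table), all(predictors %in% names(table)),
            grouping %in% names(table))
  if (length(unique(table[[grouping]])) < 2) stop("need at least two groups")
  y <- table[[outcome]]
  if (stats::sd(y) < 1e-12) stop("degenerate fit: constant outcome")
  dat <- data.frame(.y = y, .g = factor(table[[grouping]]))
  znames <- paste0("zp_", seq_along(predictors))
  for (i in seq_along(predictors)) {
    z <- zscore(table[[predictors[i]]])
    if (stats::sd(z) < 1e-12) stop("degenerate predictor: ", predictors[i])
    dat[[znames[i]]] <- z
  }
  rhs <- paste(znames, collapse = " + ")
  f_full <- stats::as.formula(paste0(".y ~ ", rhs, " + (1 + ", rhs, " | .g)"))
  f_fall <- stats::as.formula(paste0(".y ~ ", rhs, " + (1 | .g)"))
  fit <- .fit_lmm(f_full, f_fall, dat)
  res <- .lmm_result(fit, outcome, grouping, dat)
  res$coefficients$term <- c("(Intercept)", predictors)
  res
}

#' BIC-approximate Bayes factor between two regressions
#'
#' BF_ab = exp((BIC_b - BIC_a) / 2); values above 1 favor model `a`.  Both
#' models must share the outcome and the number of rows.
#'
#' @param result_a,result_b `"comm_regression"` objects
#' @return the approximate Bayes factor favoring `result_a`
#' @export
compare_models <- function(result_a, result_b) {
  stopifnot(inherits(result_a, "comm_regression"),
            inherits(result_b, "comm_regression"))
  if (!identical(result_a$outcome, result_b$outcome) ||
      result_a$n != result_b$n) {
    stop("models must share outcome and data")
  }
  exp((result_b$BIC - result_a$BIC) / 2)
}

#' Control for single-component likelihoods
#'
#' For each base kernel, fits the outcome on the z-scored single-component
#' log marginal likelihood with the compositional flag as a random effect
#' only, then refits with the flag added as a fixed effect, and reports the
#' BIC-approximate Bayes factor for the flag.
#'
#' @param table a data frame from [build_table()]
#' @param outcome outcome column (default `"wavelet_distance"`)
#' @param grouping participant grouping column
#' @return named list (LIN, RBF, PER) of lists with elements `base`,
#'   `with_flag` and `bf` (BF favoring the flag model)
#' @export
control_single_components <- function(table, outcome = "wavelet_distance",
                                      grouping = "drawer_id") {
  out <- list()
  for (comp in BASE_KERNELS) {
    col <- paste0("loglik_", comp)
    stopifnot(col %in% names(table))
    dat <- data.frame(.y = table[[outcome]],
                      .g = factor(table[[grouping]]),
                      zll = zscore(table[[col]]),
                      comp_flag = as.numeric(table$is_compositional))
    base <- .fit_lmm(.y ~ zll + (1 + zll + comp_flag | .g),
                     .y ~ zll + (1 | .g), dat)
    withf <- .fit_lmm(.y ~ zll + comp_flag + (1 + zll + comp_flag | .g),
                      .y ~ zll + comp_flag + (1 | .g), dat)
    ## the BIC comparison is only meaningful when both models carry the same
    ## random-effects structure; if either fell back, refit both as fallback
    if (base$fallback != withf$fallback) {
      base <- list(model = suppressWarnings(suppressMessages(
        lme4::lmer(.y ~ zll + (1 | .g), data = dat, REML = TRUE))),
        fallback = TRUE)
      withf <- list(model = suppressWarnings(suppressMessages(
        lme4::lmer(.y ~ zll + comp_flag + (1 | .g), data = dat, REML = TRUE))),
        fallback = TRUE)
    }
    rb <- .lmm_result(base, outcome, grouping, dat)
    rw <- .lmm_result(withf, outcome, grouping, dat)
    out[[comp]] <- list(base = rb, with_flag = rw,
                        bf = compare_models(rw, rb))
  }
  out
}

## ridge-penalized logistic regression, used when the mixed model separates
.penalized_logit <- function(X, y, lambda = 0.01) {
  nb <- ncol(X)
  obj <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta))) + lambda * sum(b[-1]^2) / 2
  }
  grd <- function(b) {
    eta <- drop(X %*% b)
    p <- 1 / (1 + exp(-eta))
    g <- -drop(crossprod(X, y - p))
    g[-1] <- g[-1] + lambda * b[-1]
    g
  }
  fit <- stats::optim(rep(0, nb), obj, grd, method = "BFGS", hessian = TRUE)
  se <- sqrt(diag(solve(fit$hessian)))
  list(coef = fit$par, se = se)
}

#' Regress composition-specific word presence on component probability
#'
#' Logistic mixed model of a binary word-presence indicator on the z-scored
#' component probability, with a random intercept over describers
#' (`direction = "presence_on_prob"`, the default).  The reverse direction
#' (component probability as a Gaussian outcome of presence) is available
#' by flag.  Apparent separation (divergent slope) is flagged and refit
#' with a ridge-penalized logistic regression.
#'
#' @param presence_table data frame with columns `describer_id`, `presence`
#'   (0/1) and `component_prob`
#' @param direction which variable is the outcome
#' @return a list with `slope`, `se`, `direction`, `separation` flag and
#'   the fitted model
#' @export
regress_word_presence <- function(presence_table,
                                  direction = c("presence_on_prob",
                                                "prob_on_presence")) {
  direction <- match.arg(direction)
  stopifnot(all(c("describer_id", "presence", "component_prob") %in%
                names(presence_table)))
  if (stats::sd(presence_table$component_prob) < 1e-12) {
    stop("degenerate component probabilities")
  }
  dat <- data.frame(presence = presence_table$presence,
                    zprob = zscore(presence_table$component_prob),
                    .g = factor(presence_table$describer_id))
  if (direction == "prob_on_presence") {
    fit <- .fit_lmm(zprob ~ presence + (1 + presence | .g),
                    zprob ~ presence + (1 | .g), dat)
    cf <- summary(fit$model)$coefficients
    return(list(slope = cf["presence", "Estimate"],
                se = cf["presence", "Std. Error"],
                direction = direction, separation = FALSE,
                model = fit$model))
  }
  model <- tryCatch(suppressWarnings(suppressMessages(
    lme4::glmer(presence ~ zprob + (1 | .g), data = dat, family = stats::binomial))),
    error = function(e) NULL)
  sep <- is.null(model) ||
    abs(lme4::fixef(model)[["zprob"]]) > 15 ||
    mean(dat$presence) %in% c(0, 1)
  if (!sep) {
    cf <- summary(model)$coefficients
    return(list(slope = cf["zprob", "Estimate"], se = cf["zprob", "Std. Error"],
                direction = direction, separation = FALSE, model = model))
  }
  pen <- .penalized_logit(cbind(1, dat$zprob), dat$presence)
  list(slope = pen$coef[2], se = pen$se[2], direction = direction,
       separation = TRUE, model = NULL)
}

#' Build a word-presence table for one component
#'
#' Links each description to the presence of the component's vocabulary and
#' the fitted component probability of its pattern.
#'
#' @param descriptions list of `"description"` objects
#' @param fits named list of `"gp_grammar"` fits keyed by pattern id
#' @param vocabulary character vector of component-specific words
#' @param component `"LIN"`, `"RBF"` or `"PER"`
#' @param mode passed to [component_probability()]
#' @return data frame with describer_id, pattern_id, presence,
#'   component_prob
#' @export
word_presence_table <- function(descriptions, fits, vocabulary, component,
                                mode = "softmax") {
  if (length(vocabulary) == 0) stop("empty vocabulary")
  rows <- lapply(descriptions, function(d) {
    gf <- fits[[d$pattern_id]]
    if (is.null(gf)) stop("no fit for pattern ", d$pattern_id)
    data.frame(describer_id = d$describer_id, pattern_id = d$pattern_id,
               presence = as.numeric(any(d$tokens %in% vocabulary)),
               component_prob = as.numeric(
                 component_probability(gf, component, mode = mode)))
  })
  do.call(rbind, rows)
}
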