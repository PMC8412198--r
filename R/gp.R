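#' Gaussian process inference over the kernel grammar
#'
#' Exact GP regression with zero prior mean.  The log marginal likelihood of
#' observations y at inputs x under kernel matrix K and noise variance s2 is
#'   -1/2 y' (K + s2 I)^-1 y - 1/2 log|K + s2 I| - n/2 log(2 pi),
#' computed through a Cholesky factorization after adding a jitter of
#' 1e-6 times the mean diagonal.  Hyperparameters are optimized by L-BFGS-B
#' on log-transformed positive parameters with analytic gradients, restarted
#' from log-uniform random initializations.
#'
#' @name gp_inference
NULL

JITTER_REL <- 1e-6

## factorize K + noise + jitter; returns cholesky (upper), alpha, lml
.gp_factor <- function(K, y, noise_var) {
  n <- length(y)
  Ky <- K + diag(noise_var, n)
  jit <- JITTER_REL * mean(diag(Ky))
  Ky <- Ky + diag(jit, n)
  U <- chol(Ky)  # may throw for non-PSD; caller handles
  alpha <- backsolve(U, backsolve(U, y, transpose = TRUE))
  lml <- -0.5 * sum(y * alpha) - sum(log(diag(U))) - 0.5 * n * log(2 * pi)
  list(U = U, alpha = alpha, lml = lml)
}

#' Log marginal likelihood of data under a kernel spec
#'
#' @param spec a `"kernel_spec"` (parameters taken from the spec)
#' @param x,y observed inputs and outputs, equal length
#' @return the log marginal likelihood in nats
#' @export
log_marginal_likelihood <- function(spec, x, y) {
  stopifnot(length(x) == length(y), length(y) >= 1)
  K <- evaluate_kernel(spec, x, x)
  f <- tryCatch(.gp_factor(K, y, spec$params$noise_var),
                error = function(e) stop("covariance not positive definite after jitter: ",
                                         conditionMessage(e)))
  f$lml
}

#' GP posterior predictive distribution
#'
#' Mean k*' (K + s2 I)^-1 y and variance k(x*, x*) - k*' (K + s2 I)^-1 k*
#' at each test input.
#'
#' @inheritParams log_marginal_likelihood
#' @param x_star test inputs
#' @return list with elements `mean` and `variance` (variance clamped at 0)
#' @export
posterior_predict <- function(spec, x, y, x_star) {
  stopifnot(length(x) == length(y))
  K <- evaluate_kernel(spec, x, x)
  f <- .gp_factor(K, y, spec$params$noise_var)
  Ks <- evaluate_kernel(spec, x, x_star)      # n x m
  mean <- drop(crossprod(Ks, f$alpha))
  V <- backsolve(f$U, Ks, transpose = TRUE)   # U^-T Ks
  kss <- diag(evaluate_kernel(spec, x_star, x_star))
  var <- pmax(kss - colSums(V^2), 0)
  list(mean = mean, variance = var)
}

## ---- parameter transforms -------------------------------------------------

## per-parameter optimization metadata: transform, box bounds (transformed
## scale) and log-uniform initialization range (natural scale)
.param_info_one <- function(name) {
  base <- sub("[0-9]+$", "", name)
  switch(name,
    theta1 = list(transform = "id", lower = -5, upper = 5, init = c(0, 1)),
    theta5 = list(transform = "log", lower = log(0.02), upper = log(10), init = c(0.05, 1)),
    noise_var = list(transform = "log", lower = log(1e-8), upper = log(10), init = c(1e-4, 1)),
    switch(base,
      theta = list(transform = "log", lower = log(1e-3), upper = log(100), init = c(0.05, 5)),
      w  = list(transform = "log", lower = log(1e-6), upper = log(100), init = c(0.05, 5)),
      mu = list(transform = "log", lower = log(0.1), upper = log(60), init = c(0.5, 10)),
      v  = list(transform = "log", lower = log(0.01), upper = log(1000), init = c(0.5, 20)),
      stop("unknown parameter ", name)))
}

flat_param_names <- function(expr) {
  if (is_spectral_expr(expr)) {
    Q <- expr$Q
    c(paste0("w", 1:Q), paste0("mu", 1:Q), paste0("v", 1:Q), "noise_var")
  } else {
    c(expr_params(expr), "noise_var")
  }
}

flatten_params <- function(expr, params) {
  nms <- flat_param_names(expr)
  if (is_spectral_expr(expr)) {
    Q <- expr$Q
    vec <- c(params$w, params$mu, params$v, params$noise_var)
  } else {
    vec <- c(unlist(params[expr_params(expr)], use.names = FALSE), params$noise_var)
  }
  stats::setNames(vec, nms)
}

unflatten_params <- function(expr, vec) {
  if (is_spectral_expr(expr)) {
    Q <- expr$Q
    list(w = unname(vec[paste0("w", 1:Q)]),
         mu = unname(vec[paste0("mu", 1:Q)]),
         v = unname(vec[paste0("v", 1:Q)]),
         noise_var = unname(vec[["noise_var"]]))
  } else {
    as.list(vec)
  }
}

to_transformed <- function(vec, info) {
  out <- vec
  for (i in seq_along(vec)) if (info[[i]]$transform == "log") out[i] <- log(vec[i])
  out
}

to_natural <- function(tvec, info) {
  out <- tvec
  for (i in seq_along(tvec)) if (info[[i]]$transform == "log") out[i] <- exp(tvec[i])
  out
}

## dominant periodogram period of a (near-)equidistant series, in x units
dominant_period <- function(x, y) {
  n <- length(y)
  z <- y - mean(y)
  if (all(abs(z) < 1e-14)) return(0.5)
  P <- Mod(stats::fft(z))^2
  k <- which.max(P[2:(floor(n / 2) + 1)])  # cycles over the x span
  span <- diff(range(x))
  if (span <= 0) return(0.5)
  span * n / ((n - 1) * k)
}

## ---- single-structure fit -------------------------------------------------

#' Fit GP hyperparameters for one kernel structure
#'
#' Maximizes the log marginal likelihood by L-BFGS-B with analytic gradients
#' over log-transformed positive parameters.  The first restart starts from
#' the default parameters; subsequent restarts draw log-uniform random
#' initializations (amplitudes and length-scales in \[0.05, 5\], period in
#' \[0.05, 1\], noise variance in \[1e-4, 1\]).  The restart with the highest
#' log marginal likelihood wins; with a seed the result is reproducible.
#'
#' @param x,y observed inputs and outputs
#' @param structure a kernel expression (see [enumerate_grammar()]) or a
#'   `"kernel_spec"` whose parameters seed the first restart
#' @param n_restarts number of optimizer restarts, >= 1
#' @param seed optional integer seed for the restart initializations
#' @param standardize if `TRUE`, center and scale `y` before fitting (the
#'   scaling is stored and undone by `predict`)
#' @return an object of class `"gp_fit"` with the optimized `spec`,
#'   `log_ml`, `converged` flag and `restarts_used`
#' @export
gp_fit <- function(x, y, structure, n_restarts = 5, seed = NULL,
                   standardize = FALSE) {
  stopifnot(n_restarts >= 1, length(x) == length(y), length(y) >= 2)
  expr <- if (inherits(structure, "kernel_spec")) structure$expr else structure
  init_params <- if (inherits(structure, "kernel_spec")) structure$params else
    default_params(expr)
  validate_expr(expr)

  center <- 0; scale <- 1
  if (standardize) {
    center <- mean(y)
    scale <- stats::sd(y)
    if (!is.finite(scale) || scale < 1e-12) scale <- 1
    y <- (y - center) / scale
  }

  nms <- flat_param_names(expr)
  info <- lapply(nms, .param_info_one)
  lower <- vapply(info, `[[`, numeric(1), "lower")
  upper <- vapply(info, `[[`, numeric(1), "upper")

  negobj <- function(tvec) {
    vec <- stats::setNames(to_natural(tvec, info), nms)
    params <- unflatten_params(expr, vec)
    out <- tryCatch({
      cov <- expr_cov(expr, x, x, params, grad = TRUE)
      f <- .gp_factor(cov$K, y, params$noise_var)
      Kinv <- chol2inv(f$U)
      A <- tcrossprod(f$alpha) - Kinv
      trA <- 0.5 * sum(diag(A))
      ## the jitter is proportional to the mean diagonal, so every parameter
      ## leaks a small extra term through it
      grad_nat <- vapply(nms, function(nm) {
        if (nm == "noise_var") trA * (1 + JITTER_REL) else
          0.5 * sum(A * cov$grad[[nm]]) +
            trA * JITTER_REL * mean(diag(cov$grad[[nm]]))
      }, numeric(1))
      ## chain rule for log-transformed parameters
      gt <- grad_nat
      for (i in seq_along(nms)) if (info[[i]]$transform == "log") gt[i] <- gt[i] * vec[i]
      list(value = -f$lml, grad = -gt)
    }, error = function(e) list(value = 1e10, grad = rep(0, length(tvec))))
    out
  }
  cache_par <- NULL; cache <- NULL
  fn <- function(tv) { cache <<- negobj(tv); cache_par <<- tv; cache$value }
  gr <- function(tv) {
    if (is.null(cache_par) || !isTRUE(all.equal(cache_par, tv))) {
      cache <<- negobj(tv); cache_par <<- tv
    }
    cache$grad
  }

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
    set.seed(seed)
  }
  inits <- vector("list", n_restarts)
  first <- flatten_params(expr, init_params)
  ## periodogram-informed period initialization: start the periodic kernel
  ## at the dominant spectral period of the data (standard heuristic for
  ## the multimodal period likelihood)
  if ("theta5" %in% nms && !inherits(structure, "kernel_spec") &&
      length(y) >= 8) {
    first["theta5"] <- min(max(dominant_period(x, y), 0.02), 10)
  }
  inits[[1]] <- to_transformed(first, info)
  if (n_restarts > 1) {
    for (r in 2:n_restarts) {
      iv <- vapply(info, function(pi) {
        if (pi$transform == "log") {
          stats::runif(1, log(pi$init[1]), log(pi$init[2]))
        } else {
          stats::runif(1, pi$init[1], pi$init[2])
        }
      }, numeric(1))
      inits[[r]] <- iv
    }
  }

  best <- NULL
  any_conv <- FALSE
  for (r in seq_len(n_restarts)) {
    tv0 <- pmin(pmax(inits[[r]], lower), upper)
    cache_par <- NULL
    res <- tryCatch(
      stats::optim(tv0, fn, gr, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 100)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value) || res$value >= 1e9) next
    any_conv <- any_conv || res$convergence %in% c(0L, 1L)
    if (is.null(best) || res$value < best$value) best <- res
  }

  if (is.null(best)) {
    spec <- kernel_spec(expr, unflatten_params(expr,
              stats::setNames(flatten_params(expr, init_params), nms)))
    fit <- list(spec = spec, log_ml = NA_real_, converged = FALSE,
                restarts_used = n_restarts, x = x, y = y,
                center = center, scale = scale)
    class(fit) <- "gp_fit"
    return(fit)
  }
  vec <- stats::setNames(to_natural(best$par, info), nms)
  spec <- kernel_spec(expr, unflatten_params(expr, vec))
  fit <- list(spec = spec, log_ml = -best$value, converged = any_conv,
              restarts_used = n_restarts, x = x, y = y,
              center = center, scale = scale)
  class(fit) <- "gp_fit"
  fit
}

## ---- grammar-wide search --------------------------------------------------

#' Fit every structure in the compositional grammar (and optionally the
#' spectral mixture) to a pattern
#'
#' The main fitting entry point.  Either give a formula `y ~ x` with a data
#' frame, or vectors via `x` and `y`.  Outputs are standardized (zero mean,
#' unit variance) before fitting by default.  Each of the 17 grammar
#' structures is optimized independently; the best structure is the one with
#' the maximal log marginal likelihood (under a uniform prior over
#' structures, the posterior over structures is proportional to the marginal
#' likelihood).  Component scores for LIN/RBF/PER come from
#' [component_probability()].
#'
#' @param formula optional formula `y ~ x`
#' @param data data frame for the formula interface
#' @param x,y vectors (used when no formula is given)
#' @param structures list of kernel expressions; defaults to the full grammar
#' @param include_spectral also fit the spectral-mixture model (stored as
#'   `$spectral`)
#' @param spectral_Q number of spectral components when `include_spectral`
#' @param n_restarts,seed passed to [gp_fit()]; per-structure seeds are
#'   derived deterministically from `seed`
#' @param standardize standardize y before fitting (default `TRUE`)
#' @return an object of class `"gp_grammar"`: `fits` (one `"gp_fit"` per
#'   structure), `best` (index of the maximal log marginal likelihood),
#'   `component_prob`, and optionally `spectral`
#' @export
gp_grammar <- function(formula = NULL, data = NULL, x = NULL, y = NULL,
                       structures = enumerate_grammar(),
                       include_spectral = FALSE, spectral_Q = 3,
                       n_restarts = 5, seed = NULL, standardize = TRUE) {
  if (!is.null(formula)) {
    mf <- stats::model.frame(formula, data)
    y <- stats::model.response(mf)
    x <- mf[[2L]]
  }
  stopifnot(!is.null(x), !is.null(y), length(x) == length(y))
  if (is.unsorted(x)) {
    ord <- order(x)
    x <- x[ord]; y <- y[ord]
  }
  seeds <- if (is.null(seed)) rep(list(NULL), length(structures) + 1) else
    as.list(seed + seq_len(length(structures) + 1))
  fits <- vector("list", length(structures))
  for (i in seq_along(structures)) {
    fits[[i]] <- gp_fit(x, y, structures[[i]], n_restarts = n_restarts,
                        seed = seeds[[i]], standardize = standardize)
  }
  names(fits) <- vapply(structures, expr_label, character(1))
  lmls <- vapply(fits, `[[`, numeric(1), "log_ml")
  best <- which.max(ifelse(is.na(lmls), -Inf, lmls))
  obj <- list(fits = fits, best = best, log_ml = lmls,
              x = x, y = y, n_restarts = n_restarts, seed = seed)
  class(obj) <- "gp_grammar"
  obj$component_prob <- vapply(BASE_KERNELS, function(b)
    suppressWarnings(as.numeric(component_probability(obj, b))), numeric(1))
  if (include_spectral) {
    obj$spectral <- gp_fit(x, y, k_spectral(spectral_Q), n_restarts = n_restarts,
                           seed = seeds[[length(structures) + 1]],
                           standardize = standardize)
  }
  obj
}

#' Component score from a grammar fit
#'
#' The default (`mode = "raw"`) is the summed log marginal likelihood over
#' structures containing the component divided by the sum over all
#' structures.  This ratio of raw log likelihoods is sign-sensitive: when
#' the summed denominator mixes signs a warning is attached.  The
#' `"softmax"` mode instead exp-normalizes the log marginal likelihoods into
#' posterior structure weights and sums the weights of structures containing
#' the component.
#'
#' @param gf a `"gp_grammar"` object
#' @param component `"LIN"`, `"RBF"` or `"PER"`
#' @param mode `"raw"` (as-printed log-likelihood ratio) or `"softmax"`
#' @return a numeric score
#' @export
component_probability <- function(gf, component, mode = c("raw", "softmax")) {
  mode <- match.arg(mode)
  component <- match.arg(component, BASE_KERNELS)
  lmls <- vapply(gf$fits, `[[`, numeric(1), "log_ml")
  has <- vapply(gf$fits, function(f) component %in% expr_leaves(f$spec$expr),
                logical(1))
  if (mode == "softmax") {
    wts <- exp(lmls - max(lmls, na.rm = TRUE))
    wts <- wts / sum(wts, na.rm = TRUE)
    return(sum(wts[has], na.rm = TRUE))
  }
  denom <- sum(lmls)
  score <- sum(lmls[has]) / denom
  if (any(lmls > 0) && any(lmls < 0)) {
    warning("mixed-sign log marginal likelihoods in component score denominator")
    attr(score, "mixed_sign") <- TRUE
  }
  score
}

## ---- methods --------------------------------------------------------------

#' @export
print.gp_fit <- function(x, ...) {
  cat("GP fit: ", expr_label(x$spec$expr),
      "  (n = ", length(x$y), ")\n", sep = "")
  cat("  log marginal likelihood: ", format(x$log_ml, digits = 6),
      if (!x$converged) "  [not converged]", "\n", sep = "")
  invisible(x)
}

#' @export
coef.gp_fit <- function(object, ...) flatten_params(object$spec$expr, object$spec$params)

#' @export
logLik.gp_fit <- function(object, ...) {
  structure(object$log_ml, df = length(coef(object)), class = "logLik")
}

#' @export
predict.gp_fit <- function(object, newdata = NULL, ...) {
  x_star <- if (is.null(newdata)) object$x else
    if (is.data.frame(newdata)) newdata[[1L]] else newdata
  p <- posterior_predict(object$spec, object$x, object$y, x_star)
  list(mean = p$mean * object$scale + object$center,
       variance = p$variance * object$scale^2)
}

#' @export
residuals.gp_fit <- function(object, ...) {
  p <- posterior_predict(object$spec, object$x, object$y, object$x)
  (object$y - p$mean) * object$scale
}

#' @export
fitted.gp_fit <- function(object, ...) predict(object)$mean

#' @export
simulate.gp_fit <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  x_star <- if (is.null(newdata)) object$x else
    if (is.data.frame(newdata)) newdata[[1L]] else newdata
  K <- evaluate_kernel(object$spec, object$x, object$x)
  f <- .gp_factor(K, object$y, object$spec$params$noise_var)
  Ks <- evaluate_kernel(object$spec, object$x, x_star)
  mean <- drop(crossprod(Ks, f$alpha))
  V <- backsolve(f$U, Ks, transpose = TRUE)
  Kpost <- evaluate_kernel(object$spec, x_star, x_star) - crossprod(V)
  draws <- mvn_sample(nsim, mean, Kpost)
  draws * object$scale + object$center
}

#' @export
plot.gp_fit <- function(x, n_grid = 200, ...) {
  xs <- seq(min(x$x), max(x$x), length.out = n_grid)
  p <- predict(x, newdata = xs)
  sd <- sqrt(p$variance)
  yobs <- x$y * x$scale + x$center
  ylim <- range(yobs, p$mean + 2 * sd, p$mean - 2 * sd)
  plot(x$x, yobs, pch = 16, cex = 0.6, ylim = ylim,
       xlab = "x", ylab = "y", main = expr_label(x$spec$expr), ...)
  graphics::polygon(c(xs, rev(xs)), c(p$mean + 2 * sd, rev(p$mean - 2 * sd)),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::lines(xs, p$mean, col = "steelblue", lwd = 2)
  invisible(x)
}

#' @export
print.gp_grammar <- function(x, ...) {
  cat("Compositional GP grammar fit (n = ", length(x$y), ", ",
      length(x$fits), " structures)\n", sep = "")
  cat("  best structure: ", names(x$fits)[x$best],
      "  (log ML ", format(x$log_ml[x$best], digits = 6), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.gp_grammar <- function(object, ...) {
  tab <- data.frame(structure = names(object$fits),
                    log_ml = object$log_ml,
                    converged = vapply(object$fits, `[[`, logical(1), "converged"),
                    row.names = NULL)
  tab <- tab[order(-tab$log_ml), ]
  out <- list(table = tab, best = names(object$fits)[object$best],
              component_prob = object$component_prob,
              spectral_log_ml = if (!is.null(object$spectral)) object$spectral$log_ml)
  class(out) <- "summary.gp_grammar"
  out
}

#' @export
print.summary.gp_grammar <- function(x, ...) {
  cat("Grammar fit summary -- best structure:", x$best, "\n\n")
  print(x$table, row.names = FALSE, digits = 6)
  cat("\nComponent scores:\n")
  print(round(x$component_prob, 4))
  if (!is.null(x$spectral_log_ml)) {
    cat("\nSpectral mixture log ML:", format(x$spectral_log_ml, digits = 6), "\n")
  }
  invisible(x)
}

#' @export
coef.gp_grammar <- function(object, ...) coef(object$fits[[object$best]])

#' @export
logLik.gp_grammar <- function(object, ...) logLik(object$fits[[object$best]])

#' @export
predict.gp_grammar <- function(object, newdata = NULL, ...) {
  predict(object$fits[[object$best]], newdata = newdata, ...)
}

#' @export
residuals.gp_grammar <- function(object, ...) residuals(object$fits[[object$best]])

#' @export
simulate.gp_grammar <- function(object, nsim = 1, seed = NULL, ...) {
  simulate(object$fits[[object$best]], nsim = nsim, seed = seed, ...)
}

#' @export
plot.gp_grammar <- function(x, ...) plot(x$fits[[x$best]], ...)

#' Export a grammar fit as a per-structure table
#'
#' @param gf a `"gp_grammar"`
#' @param pattern_id optional identifier repeated down the table
#' @return data frame with columns pattern_id, structure, log_ml, converged
#' @export
grammar_fit_table <- function(gf, pattern_id = NA) {
  data.frame(pattern_id = pattern_id,
             structure = names(gf$fits),
             log_ml = gf$log_ml,
             converged = vapply(gf$fits, `[[`, logical(1), "converged"),
             row.names = NULL)
}
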