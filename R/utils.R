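## shared numerical helpers

#' Draw from a multivariate normal via Cholesky with jitter
#'
#' @param n number of draws
#' @param mean mean vector
#' @param Sigma covariance matrix (jitter of 1e-6 x mean diagonal is added
#'   before factorization)
#' @return an `n` x `length(mean)` matrix of draws
#' @export
mvn_sample <- function(n, mean, Sigma) {
  d <- length(mean)
  Sigma <- (Sigma + t(Sigma)) / 2
  jit <- JITTER_REL * mean(diag(Sigma))
  if (!is.finite(jit) || jit <= 0) jit <- 1e-10
  U <- NULL
  for (k in 0:6) {
    U <- tryCatch(chol(Sigma + diag(jit * 10^k, d)), error = function(e) NULL)
    if (!is.null(U)) break
  }
  if (is.null(U)) stop("covariance factorization failed")
  Z <- matrix(stats::rnorm(n * d), n, d)
  sweep(Z %*% U, 2, mean, `+`)
}

## z-score a vector; constant vectors map to zeros
zscore <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s < 1e-12) return(rep(0, length(v)))
  (v - mean(v)) / s
}
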