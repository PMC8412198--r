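# shared test helpers: independent oracles and small constructors

# dense multivariate-normal log density by explicit inversion/determinant,
# independent of the package's Cholesky path
oracle_mvn_logdens <- function(y, Sigma) {
  n <- length(y)
  Sinv <- solve(Sigma)
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  drop(-0.5 * t(y) %*% Sinv %*% y - 0.5 * ld - 0.5 * n * log(2 * pi))
}

# the noisy covariance exactly as the package documents it (noise + relative
# jitter), built here from the public kernel evaluator
noisy_cov <- function(spec, x) {
  K <- evaluate_kernel(spec, x, x)
  Ky <- K + diag(spec$params$noise_var, length(x))
  Ky + diag(1e-6 * mean(diag(Ky)), length(x))
}

# independent brute-force enumeration of compositional structures:
# all binary operator trees over distinct base-kernel subsets, canonicalized
# by flattening associative operators and sorting children
oracle_enumerate <- function() {
  bases <- c("LIN", "RBF", "PER")
  gen_trees <- function(leaves) {
    if (length(leaves) == 1) return(list(leaves))
    out <- list()
    n <- length(leaves)
    for (mask in 1:(2^(n - 1) - 1)) {      # unordered splits
      sel <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
      for (lt in gen_trees(leaves[sel])) {
        for (rt in gen_trees(leaves[!sel])) {
          for (op in c("+", "*")) {
            out <- c(out, list(list(op = op, l = lt, r = rt)))
          }
        }
      }
    }
    out
  }
  canon <- function(t) {
    if (is.character(t)) return(t)
    flat <- function(node, op) {
      if (is.character(node)) return(list(node))
      if (node$op == op) c(flat(node$l, op), flat(node$r, op)) else list(node)
    }
    kids <- c(flat(t$l, t$op), flat(t$r, t$op))
    labs <- sort(vapply(kids, canon, character(1)))
    if (t$op == "+") return(paste(labs, collapse = "+"))
    labs <- ifelse(grepl("\\+", labs), paste0("(", labs, ")"), labs)
    paste(labs, collapse = "*")
  }
  subsets <- unlist(lapply(1:3, function(k)
    combn(bases, k, simplify = FALSE)), recursive = FALSE)
  unique(unlist(lapply(subsets, function(lv)
    vapply(gen_trees(lv), canon, character(1)))))
}

# fake grammar-fit object with prescribed log marginal likelihoods, for
# component-score arithmetic
fake_grammar <- function(log_mls, structures = enumerate_grammar()) {
  fits <- mapply(function(expr, lml) {
    list(spec = kernel_spec(expr), log_ml = lml, converged = TRUE)
  }, structures, log_mls, SIMPLIFY = FALSE)
  structure(list(fits = fits, log_ml = unlist(log_mls)), class = "gp_grammar")
}

# hand-run Haar pyramid (averaging/differencing), for the wavelet oracle
hand_haar_approx <- function(v, level) {
  a <- v
  for (l in seq_len(level)) {
    half <- length(a) / 2
    out <- numeric(half)
    for (i in seq_len(half)) out[i] <- (a[2 * i - 1] + a[2 * i]) / sqrt(2)
    a <- out
  }
  a
}
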