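#' Base kernels, the composition grammar, and the spectral mixture kernel
#'
#' A kernel specification (`"kernel_spec"`) is an expression tree whose leaves
#' are base kernels -- linear (`LIN`), radial basis (`RBF`) and periodic
#' (`PER`) -- or a single spectral-mixture node, and whose internal nodes are
#' `SUM` or `PRODUCT` operators.  Compositional trees carry at most three
#' leaves and never repeat a base kernel; the spectral node carries 2--6
#' Gaussian spectral-density components.
#'
#' Base kernel formulas (input x, x'; hyperparameters theta1..theta6):
#' \itemize{
#'   \item LIN: k(x, x') = (x - theta1)(x' - theta1)
#'   \item RBF: k(x, x') = theta2^2 exp(-(x - x')^2 / (2 theta3^2))
#'   \item PER: k(x, x') = theta4^2 exp(-2 sin^2(pi |x - x'| / theta5) / theta6^2)
#' }
#' The spectral mixture is the stationary Gaussian spectral-density mixture
#' k(tau) = sum_q w_q exp(-2 pi^2 tau^2 v_q) cos(2 pi tau mu_q).
#'
#' @name kernels
NULL

BASE_KERNELS <- c("LIN", "RBF", "PER")

## which hyperparameters each base kernel owns
.leaf_params <- list(
  LIN = "theta1",
  RBF = c("theta2", "theta3"),
  PER = c("theta4", "theta5", "theta6")
)

#' Construct a base-kernel leaf
#'
#' @param base one of `"LIN"`, `"RBF"`, `"PER"`
#' @return an unparameterized kernel expression node
#' @export
k_base <- function(base) {
  base <- match.arg(base, BASE_KERNELS)
  structure(list(kind = "leaf", base = base), class = "kernel_expr")
}

#' @rdname k_base
#' @export
k_lin <- function() k_base("LIN")

#' @rdname k_base
#' @export
k_rbf <- function() k_base("RBF")

#' @rdname k_base
#' @export
k_per <- function() k_base("PER")

#' Combine kernel expressions by addition or multiplication
#'
#' Children with the same operator are flattened (the operators are
#' associative) and sorted into canonical order, so two expressions that
#' differ only by commutativity compare equal.
#'
#' @param ... two or more kernel expressions
#' @return a kernel expression node
#' @export
k_sum <- function(...) .k_op("SUM", list(...))

#' @rdname k_sum
#' @export
k_prod <- function(...) .k_op("PRODUCT", list(...))

.k_op <- function(op, children) {
  if (length(children) < 2) stop("operator nodes need at least two children")
  flat <- list()
  for (ch in children) {
    if (!inherits(ch, "kernel_expr")) stop("children must be kernel expressions")
    if (identical(ch$kind, "op") && identical(ch$op, op)) {
      flat <- c(flat, ch$children)
    } else {
      flat <- c(flat, list(ch))
    }
  }
  flat <- flat[order(vapply(flat, expr_label, character(1)))]
  structure(list(kind = "op", op = op, children = flat), class = "kernel_expr")
}

#' Construct a spectral-mixture kernel expression
#'
#' @param Q number of Gaussian spectral-density components, 2--6
#' @return a kernel expression node
#' @export
k_spectral <- function(Q) {
  Q <- as.integer(Q)
  if (is.na(Q) || Q < 2L || Q > 6L) {
    stop("spectral mixture requires between 2 and 6 components")
  }
  structure(list(kind = "spectral", Q = Q), class = "kernel_expr")
}

#' Canonical label of a kernel expression
#'
#' Leaves print as their names, sums as `a+b`, products as `a*b` with
#' sum-children parenthesized; children appear in sorted order, so the label
#' is unique under commutativity and associativity.
#'
#' @param expr a kernel expression
#' @return a character scalar
#' @export
expr_label <- function(expr) {
  if (expr$kind == "leaf") return(expr$base)
  if (expr$kind == "spectral") return(paste0("SPECTRAL", expr$Q))
  labs <- vapply(expr$children, expr_label, character(1))
  if (expr$op == "SUM") return(paste(labs, collapse = "+"))
  wrap <- vapply(expr$children, function(ch) {
    identical(ch$kind, "op") && identical(ch$op, "SUM")
  }, logical(1))
  labs[wrap] <- paste0("(", labs[wrap], ")")
  paste(labs, collapse = "*")
}

#' @export
print.kernel_expr <- function(x, ...) {
  cat("<kernel expression> ", expr_label(x), "\n", sep = "")
  invisible(x)
}

expr_leaves <- function(expr) {
  if (expr$kind == "leaf") return(expr$base)
  if (expr$kind == "spectral") return(character(0))
  unlist(lapply(expr$children, expr_leaves))
}

is_spectral_expr <- function(expr) identical(expr$kind, "spectral")

#' Hyperparameters used by a compositional expression
#'
#' @param expr a kernel expression
#' @return character vector of hyperparameter names (excluding noise)
#' @export
expr_params <- function(expr) {
  unlist(.leaf_params[expr_leaves(expr)], use.names = FALSE)
}

validate_expr <- function(expr) {
  if (!inherits(expr, "kernel_expr") || is.null(expr$kind)) {
    stop("malformed kernel expression")
  }
  if (expr$kind == "spectral") return(invisible(TRUE))
  leaves <- expr_leaves(expr)
  if (length(leaves) == 0 || length(leaves) > 3) {
    stop("compositional expressions carry between 1 and 3 base kernels")
  }
  if (anyDuplicated(leaves)) stop("base kernels may not repeat within an expression")
  invisible(TRUE)
}

#' Bundle a kernel expression with parameter values
#'
#' For compositional expressions `params` is a named list drawn from
#' `theta1`..`theta6` plus `noise_var`; scale parameters (`theta3`, `theta5`,
#' `theta6` and the amplitudes `theta2`, `theta4`) must be strictly positive
#' and `noise_var` nonnegative.  For the spectral node `params` holds vectors
#' `w` (weights, >= 0), `mu` (frequencies, > 0), `v` (bandwidths, > 0), each
#' of length `Q`, plus `noise_var`.
#'
#' @param expr a kernel expression
#' @param params named list of parameter values; missing entries are filled
#'   with defaults (`theta1 = 0`, amplitudes 1, `theta3 = 0.2`,
#'   `theta5 = 0.5`, `theta6 = 1`, `noise_var = 0.01`; spectral `w = 1`,
#'   `mu` spread over 1..Q, `v = 5`)
#' @return an object of class `"kernel_spec"`
#' @export
kernel_spec <- function(expr, params = list()) {
  validate_expr(expr)
  params <- utils::modifyList(default_params(expr), params)
  validate_params(expr, params)
  structure(list(expr = expr, params = params), class = "kernel_spec")
}

default_params <- function(expr) {
  if (is_spectral_expr(expr)) {
    Q <- expr$Q
    return(list(w = rep(1, Q), mu = seq_len(Q), v = rep(5, Q), noise_var = 0.01))
  }
  defaults <- list(theta1 = 0, theta2 = 1, theta3 = 0.2,
                   theta4 = 1, theta5 = 0.5, theta6 = 1)
  c(defaults[expr_params(expr)], list(noise_var = 0.01))
}

validate_params <- function(expr, params) {
  if (is.null(params$noise_var) || params$noise_var < 0) {
    stop("invalid parameter: noise_var must be >= 0")
  }
  if (is_spectral_expr(expr)) {
    Q <- expr$Q
    for (nm in c("w", "mu", "v")) {
      if (length(params[[nm]]) != Q) stop("spectral parameter ", nm, " must have length Q")
    }
    if (any(params$w < 0)) stop("invalid parameter: spectral weights must be >= 0")
    if (any(params$mu <= 0) || any(params$v <= 0)) {
      stop("invalid parameter: spectral frequencies and bandwidths must be > 0")
    }
    return(invisible(TRUE))
  }
  pos <- c("theta2", "theta3", "theta4", "theta5", "theta6")
  for (nm in intersect(names(params), pos)) {
    if (!is.finite(params[[nm]]) || params[[nm]] <= 0) {
      stop("invalid parameter: ", nm, " must be strictly positive")
    }
  }
  invisible(TRUE)
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat("<kernel spec> ", expr_label(x$expr), "\n", sep = "")
  p <- x$params
  flat <- unlist(p)
  cat("  params: ", paste(names(flat), signif(flat, 4), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

## ---- evaluation -----------------------------------------------------------

leaf_cov <- function(base, x, xp, p, grad = FALSE) {
  switch(base,
    LIN = {
      K <- outer(x - p$theta1, xp - p$theta1)
      g <- if (grad) list(theta1 = outer(rep(1, length(x)), rep(1, length(xp))) *
                            (2 * p$theta1 - outer(x, xp, "+")))
      list(K = K, grad = g)
    },
    RBF = {
      D2 <- outer(x, xp, "-")^2
      K <- p$theta2^2 * exp(-D2 / (2 * p$theta3^2))
      g <- if (grad) list(theta2 = 2 * K / p$theta2,
                          theta3 = K * D2 / p$theta3^3)
      list(K = K, grad = g)
    },
    PER = {
      D <- abs(outer(x, xp, "-"))
      ang <- pi * D / p$theta5
      S <- sin(ang)
      K <- p$theta4^2 * exp(-2 * S^2 / p$theta6^2)
      g <- if (grad) list(
        theta4 = 2 * K / p$theta4,
        theta5 = K * (4 * S * cos(ang) / p$theta6^2) * (pi * D / p$theta5^2),
        theta6 = K * 4 * S^2 / p$theta6^3)
      list(K = K, grad = g)
    },
    stop("unknown base kernel ", base))
}

spectral_cov <- function(Q, x, xp, p, grad = FALSE) {
  tau <- outer(x, xp, "-")
  K <- 0
  g <- if (grad) list()
  for (q in seq_len(Q)) {
    E <- exp(-2 * pi^2 * tau^2 * p$v[q])
    C <- cos(2 * pi * tau * p$mu[q])
    term <- p$w[q] * E * C
    K <- K + term
    if (grad) {
      g[[paste0("w", q)]]  <- E * C
      g[[paste0("mu", q)]] <- -p$w[q] * E * sin(2 * pi * tau * p$mu[q]) * 2 * pi * tau
      g[[paste0("v", q)]]  <- term * (-2 * pi^2 * tau^2)
    }
  }
  list(K = K, grad = g)
}

## recursive evaluation with optional gradients w.r.t. natural parameters
expr_cov <- function(expr, x, xp, params, grad = FALSE) {
  if (expr$kind == "leaf") return(leaf_cov(expr$base, x, xp, params, grad))
  if (expr$kind == "spectral") return(spectral_cov(expr$Q, x, xp, params, grad))
  parts <- lapply(expr$children, expr_cov, x = x, xp = xp,
                  params = params, grad = grad)
  if (expr$op == "SUM") {
    K <- Reduce(`+`, lapply(parts, `[[`, "K"))
    g <- if (grad) do.call(c, lapply(parts, `[[`, "grad"))
    return(list(K = K, grad = g))
  }
  Ks <- lapply(parts, `[[`, "K")
  K <- Reduce(`*`, Ks)
  g <- NULL
  if (grad) {
    g <- list()
    for (i in seq_along(parts)) {
      others <- Reduce(`*`, Ks[-i], accumulate = FALSE)
      for (nm in names(parts[[i]]$grad)) {
        g[[nm]] <- parts[[i]]$grad[[nm]] * others
      }
    }
  }
  list(K = K, grad = g)
}

#' Evaluate a kernel covariance matrix
#'
#' `SUM` nodes add child covariance matrices elementwise and `PRODUCT` nodes
#' multiply them elementwise; leaves evaluate the base-kernel formulas.
#'
#' @param spec a `"kernel_spec"`
#' @param x,x_prime input vectors; `x_prime` defaults to `x`
#' @return the `length(x)` by `length(x_prime)` covariance matrix
#' @export
evaluate_kernel <- function(spec, x, x_prime = x) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (!all(is.finite(x)) || !all(is.finite(x_prime))) stop("inputs must be finite")
  validate_expr(spec$expr)
  validate_params(spec$expr, spec$params)
  expr_cov(spec$expr, x, x_prime, spec$params, grad = FALSE)$K
}

#' Evaluate a spectral-mixture covariance matrix
#'
#' Stationary: entries depend only on tau = x[i] - x_prime[j], and the
#' diagonal equals the sum of the mixture weights.
#'
#' @inheritParams evaluate_kernel
#' @export
evaluate_spectral <- function(spec, x, x_prime = x) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (!is_spectral_expr(spec$expr)) stop("spec is not a spectral-mixture kernel")
  evaluate_kernel(spec, x, x_prime)
}

## ---- grammar enumeration --------------------------------------------------

#' Enumerate the compositional kernel grammar
#'
#' All distinct expression structures with at most three non-repeating base
#' kernels, distinct under commutativity and associativity of each operator:
#' 3 singletons, 6 pairs, and 8 triples (the full sum, the full product,
#' three of the form (a*b)+c and three of the form (a+b)*c) -- 17 in total,
#' in a deterministic canonical order (by leaf count, then label).
#'
#' @return a named list of unparameterized kernel expressions
#' @export
enumerate_grammar <- function() {
  if (!is.null(.grammar_cache$structures)) return(.grammar_cache$structures)
  bases <- lapply(BASE_KERNELS, k_base)
  out <- bases
  pairs <- utils::combn(3, 2, simplify = FALSE)
  for (idx in pairs) {
    out <- c(out, list(k_sum(bases[[idx[1]]], bases[[idx[2]]]),
                       k_prod(bases[[idx[1]]], bases[[idx[2]]])))
  }
  out <- c(out, list(k_sum(bases[[1]], bases[[2]], bases[[3]]),
                     k_prod(bases[[1]], bases[[2]], bases[[3]])))
  for (k in 1:3) {
    rest <- setdiff(1:3, k)
    out <- c(out, list(k_sum(k_prod(bases[[rest[1]]], bases[[rest[2]]]), bases[[k]]),
                       k_prod(k_sum(bases[[rest[1]]], bases[[rest[2]]]), bases[[k]])))
  }
  labs <- vapply(out, expr_label, character(1))
  ord <- order(vapply(out, function(e) length(expr_leaves(e)), integer(1)), labs)
  out <- out[ord]
  names(out) <- labs[ord]
  .grammar_cache$structures <- out
  out
}

.grammar_cache <- new.env(parent = emptyenv())

## ---- serialization --------------------------------------------------------

expr_to_list <- function(expr) {
  if (expr$kind == "leaf") return(expr$base)
  if (expr$kind == "spectral") return(list(SPECTRAL = expr$Q))
  c(list(expr$op), lapply(expr$children, expr_to_list))
}

expr_from_list <- function(x) {
  if (is.character(x) && length(x) == 1) return(k_base(x))
  if (!is.null(x$SPECTRAL)) return(k_spectral(x$SPECTRAL))
  op <- x[[1]]
  children <- lapply(x[-1], expr_from_list)
  .k_op(op, children)
}

#' Serialize a kernel spec to JSON (and back)
#'
#' The layout is `{"expr": nested ["SUM"|"PRODUCT", child, child] |
#' "LIN"|"RBF"|"PER"|{"SPECTRAL": Q}, "params": {...}}`; parameter values
#' round-trip losslessly (full double precision).
#'
#' @param spec a `"kernel_spec"`
#' @return `spec_to_json`: a JSON string; `spec_from_json`: a `"kernel_spec"`
#' @export
spec_to_json <- function(spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  jsonlite::toJSON(list(expr = expr_to_list(spec$expr), params = spec$params),
                   auto_unbox = TRUE, digits = I(17))
}

#' @rdname spec_to_json
#' @param json a JSON string produced by `spec_to_json`
#' @export
spec_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  params <- lapply(x$params, function(p) unlist(p, use.names = FALSE))
  kernel_spec(expr_from_list(x$expr), params)
}
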