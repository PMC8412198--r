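#' Reconstruction scoring: splines, absolute error, Haar-wavelet distance
#'
#' A drawing is an ordered list of at least five (x, y) dots on a canvas.
#' To compare a drawing against the original 100-point pattern, the dots are
#' connected by an interpolating cubic spline (forced through every dot) and
#' evaluated on the pattern's grid so both series have the same length.
#' Fidelity is then scored by mean absolute error and by a Haar-wavelet
#' distance that is robust to scaling and shifting of the patterns.
#'
#' @name reconstruction_metrics
NULL

#' Construct a drawing
#'
#' @param dots data frame (or matrix) with columns `x` and `y`; at least 5 dots
#' @param drawer_id,pattern_id optional identifiers
#' @return an object of class `"drawing"`
#' @export
drawing <- function(dots, drawer_id = NULL, pattern_id = NULL) {
  dots <- as.data.frame(dots)
  stopifnot(all(c("x", "y") %in% names(dots)))
  if (nrow(dots) < 5) stop("a drawing needs at least five dots")
  if (!all(is.finite(dots$x)) || !all(is.finite(dots$y))) stop("dots must be finite")
  structure(list(dots = dots[, c("x", "y")], drawer_id = drawer_id,
                 pattern_id = pattern_id, resampled = NULL),
            class = "drawing")
}

#' @export
print.drawing <- function(x, ...) {
  cat("<drawing> ", nrow(x$dots), " dots",
      if (!is.null(x$pattern_id)) paste0(", pattern ", x$pattern_id),
      if (!is.null(x$drawer_id)) paste0(", drawer ", x$drawer_id), "\n", sep = "")
  invisible(x)
}

#' Normalize a drawing's canvas units
#'
#' Maps dot x-positions onto \[0, 1\] (min-max) and z-scores the dot
#' y-values, so drawings from canvases with arbitrary pixel units become
#' comparable.
#'
#' @param d a `"drawing"`
#' @return the drawing with normalized dots
#' @export
normalize_drawing <- function(d) {
  stopifnot(inherits(d, "drawing"))
  rng <- range(d$dots$x)
  if (diff(rng) < 1e-12) stop("dots span no horizontal extent")
  d$dots$x <- (d$dots$x - rng[1]) / diff(rng)
  d$dots$y <- zscore(d$dots$y)
  d
}

#' Resample a drawing onto a grid through an interpolating spline
#'
#' Natural cubic spline forced through every dot (after sorting by x and
#' averaging any duplicate x-positions, which is reported via a warning);
#' evaluation beyond the outermost dots is constant at the boundary values.
#'
#' @param d a `"drawing"` or a data frame of dots
#' @param x_grid evaluation grid (default the 100-point pattern grid)
#' @return numeric series of length `length(x_grid)`
#' @export
spline_resample <- function(d, x_grid = pattern_grid()) {
  dots <- if (inherits(d, "drawing")) d$dots else as.data.frame(d)
  if (nrow(dots) < 5) stop("a drawing needs at least five dots")
  dots <- dots[order(dots$x), ]
  if (anyDuplicated(dots$x)) {
    warning("duplicate dot x-positions averaged")
    dots <- stats::aggregate(y ~ x, data = dots, FUN = mean)
  }
  f <- stats::splinefun(dots$x, dots$y, method = "natural")
  f(pmin(pmax(x_grid, min(dots$x)), max(dots$x)))
}

#' Mean absolute error between two equal-length series
#'
#' @param a,b numeric series of equal length
#' @param type `"mean"` (default) or `"sum"` over the pointwise absolute
#'   differences
#' @return a nonnegative scalar
#' @export
absolute_error <- function(a, b, type = c("mean", "sum")) {
  type <- match.arg(type)
  if (length(a) != length(b)) stop("series lengths differ")
  d <- abs(a - b)
  if (type == "mean") mean(d) else sum(d)
}

## one Haar analysis step on the approximation vector
.haar_step <- function(a) {
  n <- length(a)
  (a[seq(1, n, by = 2)] + a[seq(2, n, by = 2)]) / sqrt(2)
}

#' Haar approximation coefficients at a given level
#'
#' Repeated pairwise averaging scaled by 1/sqrt(2); the input length must be
#' a power of two at least `2^level`.
#'
#' @param v numeric vector, length a power of two
#' @param level number of analysis steps
#' @return approximation coefficients, length `length(v) / 2^level`
#' @export
haar_approx <- function(v, level) {
  n <- length(v)
  if (abs(log2(n) - round(log2(n))) > 1e-9) stop("length must be a power of two")
  if (level < 0 || 2^level > n) stop("level out of range")
  a <- v
  for (l in seq_len(level)) a <- .haar_step(a)
  a
}

## mirror-pad to the next power of two
.pad_pow2 <- function(v) {
  n <- length(v)
  m <- 2^ceiling(log2(n))
  if (m == n) return(v)
  pad <- m - n
  c(v, v[n - seq_len(pad)])
}

## deepest level whose Haar approximation retains >= energy of the total
.energy_level <- function(v, energy) {
  total <- sum(v^2)
  if (total <= 0) return(1L)
  level <- 1L
  for (l in seq_len(round(log2(length(v))))) {
    if (sum(haar_approx(v, l)^2) >= energy * total) level <- l else break
  }
  level
}

#' Haar-wavelet distance between two series
#'
#' Both series are standardized (zero mean, unit variance; a constant series
#' falls back to a zero vector with a warning), mirror-padded to a power of
#' two, and Haar-transformed.  The comparison level is the deepest level
#' whose approximation retains at least `energy` (default 90%) of the first
#' series' total energy (the first argument is the reference pattern; level
#' 1 if none qualifies); the same level is applied to both series and the
#' Euclidean distance between the approximation coefficients at that shared
#' level is returned.  At a shared level the coefficients live in a fixed
#' Euclidean space, so the distance is symmetric and satisfies the triangle
#' inequality; pass `level` to force one.  Standardization makes the
#' measure invariant to affine transforms y -> a*y + b (a > 0).
#'
#' @param a,b numeric series of equal length >= 8
#' @param energy minimum fraction of total energy the approximation must
#'   retain (default 0.9)
#' @param level optional forced transform level, overriding the energy rule
#' @return a nonnegative scalar, 0 iff the standardized series coincide
#' @export
wavelet_distance <- function(a, b, energy = 0.9, level = NULL) {
  if (length(a) != length(b)) stop("series lengths differ")
  if (length(a) < 8) stop("series too short (need length >= 8)")
  std <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s < 1e-12) {
      warning("constant series standardized to zero vector")
      return(rep(0, length(v)))
    }
    (v - mean(v)) / s
  }
  pa <- .pad_pow2(std(a))
  pb <- .pad_pow2(std(b))
  if (is.null(level)) level <- .energy_level(pa, energy)
  sqrt(sum((haar_approx(pa, level) - haar_approx(pb, level))^2))
}

#' Score a reconstruction against its original
#'
#' @param original,reconstruction equal-length series (e.g. the 100-point
#'   pattern and the spline-resampled drawing)
#' @return list with `absolute_error` and `wavelet_distance`
#' @export
distance_report <- function(original, reconstruction) {
  list(absolute_error = absolute_error(original, reconstruction),
       wavelet_distance = wavelet_distance(original, reconstruction))
}

## ---- drawing IO -----------------------------------------------------------

#' Write and read drawing files
#'
#' CSV layout: drawer_id, pattern_id, dot_index, x, y.
#'
#' @param drawings list of `"drawing"` objects
#' @param path CSV file path
#' @export
write_drawings <- function(drawings, path) {
  rows <- lapply(drawings, function(d) {
    data.frame(drawer_id = d$drawer_id, pattern_id = d$pattern_id,
               dot_index = seq_len(nrow(d$dots)) - 1L,
               x = d$dots$x, y = d$dots$y)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_drawings
#' @export
read_drawings <- function(path) {
  df <- utils::read.csv(path)
  keys <- interaction(df$drawer_id, df$pattern_id, drop = TRUE)
  lapply(split(df, keys), function(d) {
    d <- d[order(d$dot_index), ]
    drawing(d[, c("x", "y")], drawer_id = d$drawer_id[1],
            pattern_id = d$pattern_id[1])
  })
}
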