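#' Pattern generation and stimulus matching
#'
#' Patterns are functions observed at 100 equidistant points on \[0, 1\],
#' sampled as zero-mean multivariate normal draws under a generating kernel.
#' Compositional patterns draw their kernel uniformly from the 17-structure
#' grammar; noncompositional patterns use a spectral mixture whose component
#' count is uniform on 2..6.  Stimulus sets are balanced across the two
#' classes by matching on spectral entropy and Haar-wavelet distance.
#'
#' @name pattern_generation
NULL

#' The canonical input grid: 100 equidistant points on \[0, 1\]
#' @param n number of points
#' @export
pattern_grid <- function(n = 100) seq(0, 1, length.out = n)

#' Sample a function pattern from a kernel
#'
#' One draw from the zero-mean multivariate normal with covariance
#' `evaluate_kernel(spec, x, x)`, reproducible by seed.
#'
#' @param spec a `"kernel_spec"`
#' @param seed integer seed
#' @param x input grid (default 100 equidistant points on \[0, 1\])
#' @param pattern_id optional identifier
#' @return an object of class `"pattern"`: `pattern_id`, `x`, `y`,
#'   `source_class` (`"compositional"` or `"noncompositional"`),
#'   `generator` (the spec) and `seed`
#' @export
sample_pattern <- function(spec, seed = NULL, x = pattern_grid(),
                           pattern_id = NULL) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (!is.null(seed)) set.seed(seed)
  K <- evaluate_kernel(spec, x, x)
  y <- drop(mvn_sample(1, rep(0, length(x)), K))
  cls <- if (is_spectral_expr(spec$expr)) "noncompositional" else "compositional"
  structure(list(pattern_id = pattern_id, x = x, y = y,
                 source_class = cls, generator = spec, seed = seed),
            class = "pattern")
}

#' @export
print.pattern <- function(x, ...) {
  cat("<pattern", if (!is.null(x$pattern_id)) paste0(" ", x$pattern_id), "> ",
      x$source_class, ", ", length(x$y), " points, generator ",
      expr_label(x$generator$expr), "\n", sep = "")
  invisible(x)
}

#' @export
plot.pattern <- function(x, ...) {
  plot(x$x, x$y, type = "l", xlab = "x", ylab = "y",
       main = paste0(x$source_class, ": ", expr_label(x$generator$expr)), ...)
  invisible(x)
}

## stimulus-sampling priors.  Mostly the optimizer initialization ranges,
## except that frequency-like parameters are capped so that sampled stimuli
## stay drawable through the dot interface (at most 30 dots can carry at
## most ~8 oscillations over the canvas): period >= 0.1, spectral mean
## frequency <= 5 cycles, spectral bandwidth <= 2.
.sampling_range <- function(name) {
  base <- sub("[0-9]+$", "", name)
  if (name == "theta5") return(c(0.1, 1))
  if (base == "mu") return(c(0.5, 5))
  if (base == "v") return(c(0.1, 2))
  .param_info_one(name)$init
}

sample_params_for <- function(expr) {
  nms <- setdiff(flat_param_names(expr), "noise_var")
  vec <- vapply(nms, function(nm) {
    rng <- .sampling_range(nm)
    if (.param_info_one(nm)$transform == "log") {
      exp(stats::runif(1, log(rng[1]), log(rng[2])))
    } else {
      stats::runif(1, rng[1], rng[2])
    }
  }, numeric(1))
  params <- unflatten_params(expr, c(vec, noise_var = 0.01))
  params
}

#' Draw a random compositional kernel spec
#'
#' A uniform draw over the 17 grammar structures, with hyperparameters drawn
#' from the documented log-uniform priors (amplitudes and length-scales in
#' \[0.05, 5\], period in \[0.1, 1\] so stimuli stay drawable through the
#' dot interface, linear offset uniform on \[0, 1\]).
#'
#' @param seed optional integer seed
#' @return a `"kernel_spec"`
#' @export
sample_compositional_spec <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  structures <- enumerate_grammar()
  expr <- structures[[sample.int(length(structures), 1)]]
  kernel_spec(expr, sample_params_for(expr))
}

#' Draw a random spectral-mixture kernel spec
#'
#' Component count Q uniform on 2..6; weights log-uniform on \[0.05, 5\],
#' mean frequencies log-uniform on \[0.5, 5\] cycles and bandwidths
#' log-uniform on \[0.1, 2\], keeping the sampled stimuli drawable through
#' the dot interface.
#'
#' @param seed optional integer seed
#' @return a `"kernel_spec"`
#' @export
sample_spectral_spec <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- sample(2:6, 1)
  expr <- k_spectral(Q)
  kernel_spec(expr, sample_params_for(expr))
}

#' Normalized spectral entropy of a series
#'
#' Shannon entropy of the estimated spectral density of the mean-removed
#' series (periodogram smoothed with a 5-point modified Daniell window, the
#' usual variance-reduction step for entropy estimation), normalized to a
#' probability distribution over frequency bins and divided by the log of
#' the number of bins, so the result lies in \[0, 1\]: near 1 for white
#' noise (flat spectrum), near 0 for a pure sinusoid (concentrated
#' spectrum).  A constant series is defined to have entropy 0.
#'
#' @param y numeric series, length >= 8
#' @return entropy in \[0, 1\]
#' @export
spectral_entropy <- function(y) {
  n <- length(y)
  if (n < 8) stop("series too short for spectral entropy (need length >= 8)")
  z <- y - mean(y)
  if (all(abs(z) < 1e-14)) return(0)
  sp <- stats::spec.pgram(z, kernel = stats::kernel("modified.daniell", 2),
                          taper = 0, detrend = FALSE, demean = TRUE,
                          fast = FALSE, plot = FALSE)
  p <- sp$spec / sum(sp$spec)
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(sp$spec))
}

#' Build a matched compositional/noncompositional stimulus set
#'
#' Greedy nearest-pair matching across the two pools: each candidate
#' cross-class pair is scored by the z-scored absolute difference in
#' spectral entropy plus the z-scored Haar-wavelet distance (both z-scored
#' over all candidate pairs), and the globally cheapest pairs are taken
#' until `size_per_class` pairs are formed.  Deterministic given the pools.
#'
#' @param pool_comp,pool_noncomp lists of `"pattern"` objects
#' @param size_per_class patterns retained per class (default 20, i.e. a
#'   40-pattern set)
#' @return an object of class `"matched_set"`: `compositional`,
#'   `noncompositional`, and a `match_stats` data frame (entropies, wavelet
#'   distance and combined cost per matched pair)
#' @export
build_matched_set <- function(pool_comp, pool_noncomp, size_per_class = 20) {
  if (length(pool_comp) < size_per_class || length(pool_noncomp) < size_per_class) {
    stop("pools must each contain at least size_per_class patterns")
  }
  ec <- vapply(pool_comp, function(p) spectral_entropy(p$y), numeric(1))
  en <- vapply(pool_noncomp, function(p) spectral_entropy(p$y), numeric(1))
  nc <- length(pool_comp); nn <- length(pool_noncomp)
  de <- abs(outer(ec, en, "-"))
  wd <- matrix(0, nc, nn)
  for (i in seq_len(nc)) for (j in seq_len(nn)) {
    wd[i, j] <- wavelet_distance(pool_comp[[i]]$y, pool_noncomp[[j]]$y)
  }
  zs <- function(M) {
    s <- stats::sd(M)
    if (!is.finite(s) || s < 1e-12) return(M * 0)
    (M - mean(M)) / s
  }
  cost <- zs(de) + zs(wd)
  taken_c <- logical(nc); taken_n <- logical(nn)
  pairs <- matrix(NA_integer_, size_per_class, 2)
  stats_rows <- vector("list", size_per_class)
  for (k in seq_len(size_per_class)) {
    masked <- cost
    masked[taken_c, ] <- Inf
    masked[, taken_n] <- Inf
    idx <- arrayInd(which.min(masked), dim(masked))
    i <- idx[1]; j <- idx[2]
    taken_c[i] <- TRUE; taken_n[j] <- TRUE
    pairs[k, ] <- c(i, j)
    stats_rows[[k]] <- data.frame(
      pair = k, comp_index = i, noncomp_index = j,
      entropy_comp = ec[i], entropy_noncomp = en[j],
      entropy_diff = de[i, j], wavelet_distance = wd[i, j], cost = cost[i, j])
  }
  out <- list(compositional = pool_comp[pairs[, 1]],
              noncompositional = pool_noncomp[pairs[, 2]],
              match_stats = do.call(rbind, stats_rows))
  class(out) <- "matched_set"
  out
}

#' @export
print.matched_set <- function(x, ...) {
  cat("<matched set> ", length(x$compositional), " compositional + ",
      length(x$noncompositional), " noncompositional patterns\n", sep = "")
  cat("  mean |entropy diff| = ",
      signif(mean(x$match_stats$entropy_diff), 4),
      ", mean wavelet distance = ",
      signif(mean(x$match_stats$wavelet_distance), 4), "\n", sep = "")
  invisible(x)
}

## ---- pattern IO -----------------------------------------------------------

#' Write and read pattern files
#'
#' Patterns are stored as CSV rows (pattern_id, index, x, y) with a JSON
#' sidecar per pattern carrying the generator spec, seed and source class.
#'
#' @param patterns list of `"pattern"` objects
#' @param dir output directory (created if missing)
#' @export
write_patterns <- function(patterns, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(patterns, function(p) {
    data.frame(pattern_id = p$pattern_id, index = seq_along(p$x) - 1L,
               x = p$x, y = p$y)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "patterns.csv"),
                   row.names = FALSE)
  side <- lapply(patterns, function(p) {
    list(pattern_id = p$pattern_id, source_class = p$source_class,
         seed = p$seed,
         generator = jsonlite::fromJSON(spec_to_json(p$generator),
                                        simplifyVector = FALSE))
  })
  jsonlite::write_json(side, file.path(dir, "patterns.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, "patterns.csv"))
}

#' @rdname write_patterns
#' @export
read_patterns <- function(dir) {
  df <- utils::read.csv(file.path(dir, "patterns.csv"))
  side <- jsonlite::fromJSON(file.path(dir, "patterns.json"),
                             simplifyVector = FALSE)
  meta <- stats::setNames(side, vapply(side, function(s)
    as.character(s$pattern_id), character(1)))
  lapply(split(df, df$pattern_id), function(d) {
    d <- d[order(d$index), ]
    m <- meta[[as.character(d$pattern_id[1])]]
    gen <- kernel_spec(expr_from_list(m$generator$expr),
                       lapply(m$generator$params, function(p) unlist(p, use.names = FALSE)))
    structure(list(pattern_id = d$pattern_id[1], x = d$x, y = d$y,
                   source_class = m$source_class, generator = gen,
                   seed = m$seed), class = "pattern")
  })
}
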