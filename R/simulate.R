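#' Synthetic three-part communication game
#'
#' Simulates the describe -> redraw -> rate game with known ground truth.
#' Each describer sees half compositional, half noncompositional patterns
#' and emits a word-bag description keyed to the components of the
#' generating kernel (spectral generators have no components, so their
#' descriptions carry only filler words).  A drawer decodes the flagged
#' components into a SUM kernel (falling back to RBF when no component word
#' is present), reconstructs the pattern as the GP posterior mean through a
#' small set of noisy anchor points, and places noisy dots.  Raters score
#' drawings as a noisy decreasing function of the wavelet distance, clipped
#' to \[0, 100\].  The `dot-noise-only` channel skips decoding entirely
#' (dots are placed on the true pattern), which removes any
#' compositionality effect and so isolates the channel as its source.
#'
#' @name synthetic_data
NULL

#' Built-in component vocabularies and filler lexicon for the simulator
#' @export
component_lexicon <- function() {
  list(LIN = c("linear", "straight", "line", "steady", "slope", "rising",
               "incline", "diagonal", "trend", "constant"),
       RBF = c("smooth", "curve", "bump", "gradual", "hill", "curvy",
               "soft", "round", "gentle", "arc"),
       PER = c("wave", "peak", "repeat", "cycle", "period", "zigzag",
               "oscillating", "wavy", "valley", "mountain"))
}

filler_lexicon <- function() {
  c("the", "it", "then", "starts", "goes", "up", "down", "bottom", "top",
    "left", "right", "very", "bit", "pattern", "and", "ends", "middle")
}

#' Configuration for the simulated game
#'
#' @param n_describers,n_drawers,n_raters participant counts (drawers are
#'   paired with describers, cycling if counts differ)
#' @param patterns_per_participant patterns per describer, split half
#'   compositional / half noncompositional (default 6 = 3 + 3), drawn
#'   without replacement from the matched stimulus set
#' @param set_size matched stimulus patterns per class (default 20, i.e. a
#'   40-pattern set)
#' @param pool_size candidate patterns sampled per class before matching
#'   (default 60)
#' @param channel `"grammar-decoder"` (decode component words to a SUM
#'   kernel and reconstruct by GP posterior mean), `"spectral-decoder"`
#'   (reconstruct under a spectral-mixture kernel regardless of the
#'   description), or `"dot-noise-only"` (no decoding; dots on the true
#'   pattern)
#' @param dot_count_range dots per drawing, uniform over this range
#'   (default 5--30)
#' @param dot_noise_sd additive noise on dot y-values (standardized units)
#' @param emission_prob probability a present component emits its words
#' @param words_per_component how many vocabulary words an emitting
#'   component contributes
#' @param filler_rate Poisson mean of filler words per description
#' @param n_anchors,anchor_noise_sd anchor points through which the drawer
#'   reconstructs (its "memory" of the shape)
#' @param rating_slope,rating_noise_sd rating = clip(100 - slope * wavelet
#'   distance + noise, 0, 100)
#' @param ratings_per_rater drawings rated by each rater (default 30)
#' @param seed integer seed for the whole game
#' @return a `"game_config"` list
#' @export
game_config <- function(n_describers = 7, n_drawers = 7, n_raters = 10,
                        patterns_per_participant = 6,
                        set_size = 20, pool_size = 60,
                        channel = c("grammar-decoder", "spectral-decoder",
                                    "dot-noise-only"),
                        dot_count_range = c(5, 30), dot_noise_sd = 0.05,
                        emission_prob = 0.9, words_per_component = 2,
                        filler_rate = 5,
                        n_anchors = 10, anchor_noise_sd = 0.05,
                        rating_slope = 10, rating_noise_sd = 5,
                        ratings_per_rater = 30, seed = 1) {
  channel <- match.arg(channel)
  stopifnot(n_describers >= 1, n_drawers >= 1, n_raters >= 1,
            patterns_per_participant >= 2,
            dot_count_range[1] >= 5, dot_count_range[2] >= dot_count_range[1],
            emission_prob >= 0, emission_prob <= 1,
            dot_noise_sd >= 0, anchor_noise_sd >= 0, rating_noise_sd >= 0)
  structure(as.list(environment()), class = "game_config")
}

## sample candidate pools from both classes and match them
simulate_matched_set <- function(config) {
  pool <- function(cls, prefix) {
    lapply(seq_len(config$pool_size), function(i) {
      spec <- if (cls == "compositional") sample_compositional_spec()
              else sample_spectral_spec()
      sample_pattern(spec, pattern_id = sprintf("%s%02d", prefix, i))
    })
  }
  build_matched_set(pool("compositional", "comp"),
                    pool("noncompositional", "spec"),
                    size_per_class = config$set_size)
}

## decode a token bag to a kernel expression via the component vocabularies
decode_description <- function(tokens, lexicon = component_lexicon()) {
  flagged <- names(lexicon)[vapply(lexicon, function(ws) any(tokens %in% ws),
                                   logical(1))]
  if (length(flagged) == 0) return(k_base("RBF"))
  if (length(flagged) == 1) return(k_base(flagged))
  do.call(k_sum, lapply(flagged, k_base))
}

## drawer-side reconstruction of a pattern on its grid
.reconstruct <- function(pattern, tokens, channel, config) {
  if (channel == "dot-noise-only") return(pattern$y)
  expr <- if (channel == "spectral-decoder") k_spectral(3) else
    decode_description(tokens)
  idx <- round(seq(1, length(pattern$x), length.out = config$n_anchors))
  xa <- pattern$x[idx]
  ya <- pattern$y[idx] + stats::rnorm(length(idx), 0, config$anchor_noise_sd)
  fit <- gp_fit(xa, ya, expr, n_restarts = 2, standardize = TRUE)
  if (!fit$converged || is.na(fit$log_ml)) return(rep(mean(ya), length(pattern$x)))
  predict(fit, newdata = pattern$x)$mean
}

## emit dots from a reconstructed series.  Drawers adapt the dot count to
## the complexity of what they are drawing (total variation of the series,
## plus noise) and spread dots across the canvas (one per stratum), as
## people do; counts stay within dot_count_range.
.dotize <- function(x, recon, config) {
  n <- length(x)
  tv <- sum(abs(diff(recon)))
  n_dots <- round(5 + 1.5 * tv + stats::rnorm(1, 0, 2))
  n_dots <- min(max(n_dots, config$dot_count_range[1]), config$dot_count_range[2])
  ## anchor dots at the endpoints and at local extrema of the drawn shape,
  ## then spread the rest across the canvas
  d1 <- diff(recon)
  extrema <- which(d1[-1] * d1[-length(d1)] < 0) + 1L
  anchors <- unique(c(1L, extrema, n))
  if (length(anchors) > n_dots) {
    anchors <- anchors[round(seq(1, length(anchors), length.out = n_dots))]
  }
  idx <- anchors
  n_fill <- n_dots - length(idx)
  if (n_fill > 0) {
    breaks <- round(seq(0, n, length.out = n_fill + 1))
    fill <- vapply(seq_len(n_fill), function(b) {
      lo <- breaks[b] + 1L; hi <- breaks[b + 1]
      if (hi <= lo) lo else sample(lo:hi, 1L)
    }, integer(1))
    idx <- unique(sort(c(idx, fill)))
  }
  if (length(idx) < config$dot_count_range[1]) {
    extra <- sample(setdiff(seq_len(n), idx),
                    config$dot_count_range[1] - length(idx))
    idx <- sort(c(idx, extra))
  }
  data.frame(x = x[idx],
             y = recon[idx] + stats::rnorm(length(idx), 0, config$dot_noise_sd))
}

#' Simulate a full communication game
#'
#' @param config a `"game_config"`
#' @return an object of class `"game_dataset"`: `patterns` (named list of
#'   `"pattern"`), `descriptions` (list of `"description"`), `drawings`
#'   (list of `"drawing"`, each with its spline-resampled 100-point series
#'   in `$resampled`), `ratings` (data frame rater_id, pattern_id,
#'   drawer_id, score), and `ground_truth` (generator specs, channel,
#'   config)
#' @export
simulate_game <- function(config) {
  stopifnot(inherits(config, "game_config"))
  set.seed(config$seed)
  lexicon <- component_lexicon()
  fillers <- filler_lexicon()
  half <- config$patterns_per_participant %/% 2
  n_extra <- config$patterns_per_participant - half
  stopifnot(half <= config$set_size, n_extra <= config$set_size)

  ## matched stimulus set, as in the study: sample candidate pools from both
  ## model classes, then retain entropy/wavelet-matched patterns so the two
  ## classes do not differ in low-level drawability
  mset <- simulate_matched_set(config)
  patterns <- list()
  for (p in c(mset$compositional, mset$noncompositional)) {
    p$y <- zscore(p$y)
    patterns[[p$pattern_id]] <- p
  }
  comp_ids <- vapply(mset$compositional, `[[`, character(1), "pattern_id")
  noncomp_ids <- vapply(mset$noncompositional, `[[`, character(1), "pattern_id")

  descriptions <- list(); drawings <- list()
  for (d in seq_len(config$n_describers)) {
    describer_id <- sprintf("describer%02d", d)
    drawer <- ((d - 1) %% config$n_drawers) + 1
    drawer_id <- sprintf("drawer%02d", drawer)
    ids <- c(sample(comp_ids, half), sample(noncomp_ids, n_extra))
    for (pid in ids) {
      pat <- patterns[[pid]]
      spec <- pat$generator

      comps <- unique(expr_leaves(spec$expr))
      words <- character(0)
      for (comp in comps) {
        if (stats::runif(1) < config$emission_prob) {
          words <- c(words, sample(lexicon[[comp]], config$words_per_component))
        }
      }
      n_fill <- stats::rpois(1, config$filler_rate)
      words <- sample(c(words, sample(fillers, n_fill, replace = TRUE)))
      if (length(words) == 0) words <- sample(fillers, 1)
      desc <- description(paste(words, collapse = " "),
                          describer_id = describer_id, pattern_id = pid)
      descriptions[[length(descriptions) + 1]] <- desc

      recon <- .reconstruct(pat, desc$tokens, config$channel, config)
      dots <- .dotize(pat$x, recon, config)
      dr <- drawing(dots, drawer_id = drawer_id, pattern_id = pid)
      dr$resampled <- spline_resample(dr, pat$x)
      drawings[[length(drawings) + 1]] <- dr
    }
  }

  ## ratings: each rater scores a random sample of drawings
  n_dr <- length(drawings)
  wds <- vapply(drawings, function(dr)
    wavelet_distance(patterns[[dr$pattern_id]]$y, dr$resampled), numeric(1))
  rating_rows <- list()
  for (r in seq_len(config$n_raters)) {
    take <- sample(n_dr, min(config$ratings_per_rater, n_dr),
                   replace = config$ratings_per_rater > n_dr)
    for (i in take) {
      score <- 100 - config$rating_slope * wds[i] +
        stats::rnorm(1, 0, config$rating_noise_sd)
      rating_rows[[length(rating_rows) + 1]] <- data.frame(
        rater_id = sprintf("rater%03d", r),
        pattern_id = drawings[[i]]$pattern_id,
        drawer_id = drawings[[i]]$drawer_id,
        score = min(max(score, 0), 100))
    }
  }
  ground_truth <- list(
    generators = lapply(patterns, function(p) expr_label(p$generator$expr)),
    channel = config$channel, config = unclass(config))
  out <- list(patterns = patterns, descriptions = descriptions,
              drawings = drawings, ratings = do.call(rbind, rating_rows),
              ground_truth = ground_truth)
  class(out) <- "game_dataset"
  out
}

#' @export
print.game_dataset <- function(x, ...) {
  cat("<game dataset> ", length(x$patterns), " patterns, ",
      length(x$descriptions), " descriptions, ", length(x$drawings),
      " drawings, ", nrow(x$ratings), " ratings (channel: ",
      x$ground_truth$channel, ")\n", sep = "")
  invisible(x)
}

#' Per-pattern memorability scores from an immediate-redraw simulation
#'
#' No description channel: each redraw perturbs the pattern with additive
#' noise, dotizes and spline-resamples it, and the wavelet distances to the
#' original are averaged per pattern, giving an item-specific memorability
#' score.
#'
#' @param config a `"game_config"` (`dot_noise_sd` doubles as the memory
#'   noise)
#' @param patterns optional named list of `"pattern"` objects; generated
#'   from the config when missing
#' @param n_redraws redraws per pattern (default 5)
#' @return named numeric vector of mean wavelet distances, one per pattern
#' @export
simulate_memorability <- function(config, patterns = NULL, n_redraws = 5) {
  stopifnot(inherits(config, "game_config"))
  set.seed(config$seed + 1L)
  if (is.null(patterns)) {
    mset <- simulate_matched_set(config)
    patterns <- list()
    for (p in c(mset$compositional, mset$noncompositional)) {
      p$y <- zscore(p$y)
      patterns[[p$pattern_id]] <- p
    }
  }
  vapply(patterns, function(pat) {
    mean(vapply(seq_len(n_redraws), function(i) {
      recon <- pat$y + stats::rnorm(length(pat$y), 0, config$dot_noise_sd)
      dots <- .dotize(pat$x, recon, config)
      wavelet_distance(pat$y, spline_resample(drawing(dots), pat$x))
    }, numeric(1)))
  }, numeric(1))
}

#' Write a simulated game to disk
#'
#' Writes the four dataset files in the package's standard formats
#' (patterns CSV + JSON sidecar, descriptions JSON lines, drawings CSV,
#' ratings CSV) plus a ground-truth JSON.
#'
#' @param dataset a `"game_dataset"`
#' @param dir output directory
#' @export
write_game_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_patterns(dataset$patterns, dir)
  write_descriptions(dataset$descriptions, file.path(dir, "descriptions.jsonl"))
  write_drawings(dataset$drawings, file.path(dir, "drawings.csv"))
  utils::write.csv(dataset$ratings, file.path(dir, "ratings.csv"),
                   row.names = FALSE)
  jsonlite::write_json(dataset$ground_truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
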