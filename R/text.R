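#' Lexical metrics for pattern descriptions
#'
#' Descriptions are free text; tokenization lowercases, splits on
#' non-alphabetic characters and drops empty tokens (no stemming, no
#' stop-word removal, so inflected forms like "starts" survive).
#'
#' @name text_metrics
NULL

#' Tokenize description text
#'
#' @param text character scalar or vector (concatenated before splitting)
#' @return character vector of lowercase word tokens
#' @export
tokenize <- function(text) {
  toks <- unlist(strsplit(tolower(paste(text, collapse = " ")), "[^a-z]+"))
  toks[nzchar(toks)]
}

#' Construct a description record
#'
#' @param text free-text description
#' @param describer_id,pattern_id identifiers
#' @param judge_rating optional mean judge rating on the 1--5 scale (the
#'   study retains descriptions rated above 3)
#' @return an object of class `"description"` with a deterministic `tokens`
#'   field
#' @export
description <- function(text, describer_id = NULL, pattern_id = NULL,
                        judge_rating = NULL) {
  if (!is.null(judge_rating) && (judge_rating < 1 || judge_rating > 5)) {
    stop("judge_rating must lie in [1, 5]")
  }
  structure(list(describer_id = describer_id, pattern_id = pattern_id,
                 text = text, tokens = tokenize(text),
                 judge_rating = judge_rating),
            class = "description")
}

desc_tokens <- function(d) if (inherits(d, "description")) d$tokens else tokenize(d)

#' Lexical diversity (type-token ratio)
#'
#' Number of unique words divided by the total number of words.
#'
#' @param tokens character vector of tokens (or a `"description"`)
#' @return a value in (0, 1\]
#' @export
lexical_diversity <- function(tokens) {
  tokens <- desc_tokens(tokens)
  if (length(tokens) == 0) stop("no tokens")
  length(unique(tokens)) / length(tokens)
}

#' Words frequent in one corpus and absent from another
#'
#' Words used at least `min_count` times across the pooled descriptions of
#' corpus A ("more than twice" at the default of 3) and never in corpus B.
#'
#' @param descs_a,descs_b lists of descriptions (or token vectors / strings)
#' @param min_count minimum pooled count in A (default 3)
#' @return data frame with columns `word` and `count`, sorted by decreasing
#'   count then alphabetically
#' @export
differential_words <- function(descs_a, descs_b, min_count = 3) {
  stopifnot(length(descs_a) > 0, length(descs_b) > 0)
  ta <- unlist(lapply(descs_a, desc_tokens))
  tb <- unlist(lapply(descs_b, desc_tokens))
  counts <- table(ta)
  keep <- counts >= min_count & !(names(counts) %in% tb)
  out <- data.frame(word = names(counts)[keep],
                    count = as.integer(counts[keep]))
  out[order(-out$count, out$word), , drop = FALSE]
}

#' Extract component-specific vocabularies
#'
#' For each component (LIN, RBF, PER), words are ranked by the difference
#' between their relative frequency in that component's descriptions and
#' their maximal relative frequency in the other two components; the top
#' `k` are returned, ties broken alphabetically.  Relative frequencies are
#' used because corpus sizes differ across components.
#'
#' @param descs_by_component named list (`LIN`, `RBF`, `PER`), each a list
#'   of descriptions
#' @param k vocabulary size per component (default 10)
#' @return named list of data frames (`word`, `score`), flagged with
#'   attribute `short` if fewer than `k` words were eligible
#' @export
extract_component_words <- function(descs_by_component, k = 10) {
  comps <- BASE_KERNELS
  stopifnot(all(comps %in% names(descs_by_component)))
  relfreq <- lapply(descs_by_component[comps], function(descs) {
    if (length(descs) == 0) stop("at least one description per component required")
    toks <- unlist(lapply(descs, desc_tokens))
    tab <- table(toks)
    tab / sum(tab)
  })
  vocab <- sort(unique(unlist(lapply(relfreq, names))))
  freq_of <- function(rf, w) {
    v <- as.numeric(rf[w])
    v[is.na(v)] <- 0
    v
  }
  out <- list()
  for (comp in comps) {
    own <- freq_of(relfreq[[comp]], vocab)
    others <- do.call(pmax, lapply(relfreq[setdiff(comps, comp)], freq_of, w = vocab))
    score <- own - others
    ord <- order(-score, vocab)
    take <- utils::head(ord, k)
    df <- data.frame(word = vocab[take], score = score[take])
    if (all(score == 0)) attr(df, "degenerate") <- TRUE
    if (length(take) < k) attr(df, "short") <- TRUE
    out[[comp]] <- df
  }
  out
}

#' Probability that a word set appears in descriptions
#'
#' Fraction of descriptions containing at least one word from `word_set`.
#'
#' @param descriptions list of descriptions (or token vectors / strings)
#' @param word_set character vector of words
#' @return a probability in \[0, 1\]
#' @export
word_set_presence <- function(descriptions, word_set) {
  stopifnot(length(descriptions) > 0, length(word_set) > 0)
  mean(vapply(descriptions, function(d) any(desc_tokens(d) %in% word_set),
              logical(1)))
}

## ---- description IO -------------------------------------------------------

#' Write and read descriptions as JSON lines
#'
#' One JSON object per line: describer_id, pattern_id, text, judge_rating.
#'
#' @param descriptions list of `"description"` objects
#' @param path file path
#' @export
write_descriptions <- function(descriptions, path) {
  lines <- vapply(descriptions, function(d) {
    as.character(jsonlite::toJSON(
      list(describer_id = d$describer_id, pattern_id = d$pattern_id,
           text = d$text, judge_rating = d$judge_rating),
      auto_unbox = TRUE, null = "null", digits = NA))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_descriptions
#' @export
read_descriptions <- function(path) {
  lapply(readLines(path), function(ln) {
    x <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    description(x$text, describer_id = x$describer_id,
                pattern_id = x$pattern_id, judge_rating = x$judge_rating)
  })
}
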