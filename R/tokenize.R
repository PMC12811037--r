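#' Whitespace tokenization with character offsets
#'
#' Splits text into maximal runs of non-whitespace characters -- the token
#' definition underlying the error-rate metric. Offsets are 0-based,
#' half-open: `substr(text, start + 1, end)` recovers each token, and
#' concatenating tokens with the intervening whitespace reconstructs the text
#' losslessly.
#'
#' @param text A single string.
#' @return Tibble with columns `token`, `start`, `end`, `has_punctuation`
#'   (TRUE when the token contains any character outside `[A-Za-z0-9]`).
#' @export
whitespace_tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(text)) {
    return(tibble::tibble(token = character(), start = integer(),
                          end = integer(), has_punctuation = logical()))
  }
  m <- gregexpr("\\S+", text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(tibble::tibble(token = character(), start = integer(),
                          end = integer(), has_punctuation = logical()))
  }
  start1 <- as.integer(m)
  len <- attr(m, "match.length")
  tok <- substring(text, start1, start1 + len - 1L)
  tibble::tibble(
    token = tok,
    start = start1 - 1L,
    end = start1 + len - 1L,
    has_punctuation = grepl("[^A-Za-z0-9]", tok)
  )
}

#' Feature tokenization
#'
#' The tokenizer used for all feature building: matches the regular
#' expression `\b[a-zA-Z]+\b` (purely alphabetic runs delimited by word
#' boundaries) and lowercases the result. Digits and punctuation are
#' excluded; an alphabetic run glued to a digit (e.g. `"0400hrs"`) has no
#' word boundary and yields no token.
#'
#' @param text Character vector.
#' @return For length-1 input, a character vector of tokens; otherwise a list
#'   of token vectors.
#' @export
feature_tokenize <- function(text) {
  out <- lapply(text, function(s) {
    if (is.na(s) || !nzchar(s)) return(character())
    m <- regmatches(s, gregexpr("\\b[a-zA-Z]+\\b", s, perl = TRUE))[[1]]
    tolower(m)
  })
  if (length(text) == 1) out[[1]] else out
}

#' Token-level error rate
#'
#' The error rate of a note is the number of erroneous whitespace tokens
#' divided by the total number of whitespace tokens. Punctuation-only and
#' grammatical deviations are out of scope for the metric; an erroneous token
#' is one carrying a misspelling or a whitespace-merge.
#'
#' @param tokens A tokenization from [whitespace_tokenize()] (or any object
#'   with one row/element per token).
#' @param erroneous_indices Integer indices (1-based) of erroneous tokens.
#' @return Fraction in \[0, 1\].
#' @export
error_rate <- function(tokens, erroneous_indices) {
  n <- if (is.data.frame(tokens)) nrow(tokens) else length(tokens)
  if (n == 0) {
    abort("error rate is undefined for an empty token list",
          class = "noteqc_undefined_rate_error")
  }
  idx <- unique(as.integer(erroneous_indices))
  if (length(idx) > 0 && (min(idx) < 1 || max(idx) > n)) {
    abort("erroneous index out of range", class = "noteqc_index_error")
  }
  length(idx) / n
}

#' Corpus-level error report
#'
#' Computes the per-note error rate from token-level error annotations (or a
#' detector's flagged indices) and aggregates over the corpus. Notes shorter
#' than `min_tokens` whitespace tokens are excluded from the aggregate and
#' counted separately, mirroring the practice of dropping very short notes
#' from manual quality audits. The corpus summary is the mean and population
#' standard deviation of the remaining per-note rates.
#'
#' @param corpus A [note_corpus()].
#' @param annotations Tibble with columns `note_id` and `token_index` (one
#'   row per erroneous token), e.g. from [apply_corruption()] or
#'   [detect_errors_dictionary()] output bound over notes.
#' @param min_tokens Minimum whitespace-token count for inclusion (default 5).
#' @return An `error_report`: list with `per_note_rate` (named numeric),
#'   `mean_rate`, `sd_rate`, `n_notes`, `n_excluded_short`.
#' @export
corpus_error_report <- function(corpus, annotations, min_tokens = 5) {
  stopifnot(inherits(corpus, "note_corpus"))
  unknown <- setdiff(unique(annotations$note_id), corpus$note_id)
  if (length(unknown) > 0) {
    abort(paste0("annotations reference unknown note_id: ",
                 paste(head(unknown, 5), collapse = ", ")),
          class = "noteqc_alignment_error")
  }
  n_tok <- vapply(corpus$text,
                  function(s) nrow(whitespace_tokenize(s)), integer(1))
  names(n_tok) <- corpus$note_id
  keep <- n_tok >= min_tokens
  if (!any(keep)) {
    abort("all notes excluded by the min_tokens rule",
          class = "noteqc_empty_report_error")
  }
  ann <- dplyr::distinct(tibble::as_tibble(annotations)[, c("note_id", "token_index")])
  err_counts <- table(factor(ann$note_id, levels = corpus$note_id))
  rates <- as.numeric(err_counts[keep]) / n_tok[keep]
  names(rates) <- corpus$note_id[keep]
  structure(
    list(per_note_rate = rates,
         mean_rate = mean(rates),
         sd_rate = pop_sd(rates),
         n_notes = sum(keep),
         n_excluded_short = sum(!keep)),
    class = "error_report"
  )
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf(
    "<error_report> mean rate %.2f%% (SD %.2f%%) over %d notes (%d excluded as short)\n",
    100 * x$mean_rate, 100 * x$sd_rate, x$n_notes, x$n_excluded_short))
  invisible(x)
}
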