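#' Dictionary-based error detection
#'
#' Reference detector: flags every whitespace token whose punctuation-stripped,
#' lowercased form is non-empty and absent from the dictionary. On a
#' collision-free corpus (dictionary with large pairwise edit distance, all
#' clean tokens in-dictionary) this recovers injected errors exactly; on real
#' text it behaves like a classic spell checker, including its known blind
#' spots (valid-word substitutions) and false alarms (domain terms missing
#' from the dictionary).
#'
#' @param note One-row slice of a [note_corpus()] (or list with `note_id`,
#'   `text`).
#' @param dictionary Non-empty character vector of valid words (lowercase).
#' @return A `detection_result`: list with `note_id`, `flagged_indices`
#'   (1-based whitespace-token indices) and `backend_name`.
#' @export
detect_errors_dictionary <- function(note, dictionary) {
  if (length(dictionary) == 0) {
    abort("dictionary must be non-empty", class = "noteqc_config_error")
  }
  tokens <- whitespace_tokenize(note$text)
  norm <- normalize_token(tokens$token)
  flagged <- which(nzchar(norm) & !(norm %in% tolower(dictionary)))
  structure(list(note_id = note$note_id,
                 flagged_indices = as.integer(flagged),
                 backend_name = "dictionary"),
            class = "detection_result")
}

# Candidate split positions for undoing a whitespace merge: positions right
# after an internal punctuation run (the dominant merge pattern, e.g.
# "unwell.Resident"), falling back to every internal cut point.
split_positions <- function(token) {
  n <- nchar(token)
  if (n < 2) return(integer())
  chars <- strsplit(token, "", fixed = TRUE)[[1]]
  punct <- grepl("[^[:alnum:]]", chars)
  after_punct <- which(punct[-n] & !punct[-1])
  if (length(after_punct) > 0) after_punct else seq_len(n - 1L)
}

#' Dictionary-based correction of a note
#'
#' Best-effort corrector over the tokens flagged by
#' [detect_errors_dictionary()]. For each flagged token it tries, in order:
#' (a) a two-way split into two in-dictionary words, preferring a cut at an
#' internal punctuation boundary (undoes whitespace merges); (b) the unique
#' dictionary word at edit distance 1 from the stripped, lowercased form;
#' (c) the unique word at distance 2. If no rule yields a unique candidate
#' the token is left unchanged. Surrounding punctuation, first-letter case
#' and all unflagged text are preserved.
#'
#' @inheritParams detect_errors_dictionary
#' @return The corrected note text (single string).
#' @export
correct_note_dictionary <- function(note, dictionary) {
  if (length(dictionary) == 0) {
    abort("dictionary must be non-empty", class = "noteqc_config_error")
  }
  dict_lc <- tolower(dictionary)
  det <- detect_errors_dictionary(note, dictionary)
  if (length(det$flagged_indices) == 0) return(note$text)
  tokens <- whitespace_tokenize(note$text)
  text <- note$text
  # replace right-to-left so earlier offsets stay valid
  for (i in rev(det$flagged_indices)) {
    tok <- tokens$token[i]
    replacement <- NULL
    # (a) split search
    for (pos in split_positions(tok)) {
      left <- substr(tok, 1, pos)
      right <- substring(tok, pos + 1)
      if (normalize_token(left) %in% dict_lc &&
          normalize_token(right) %in% dict_lc) {
        replacement <- paste(left, right)
        break
      }
    }
    # (b)/(c) unique near-miss candidate on the stripped form
    if (is.null(replacement)) {
      core <- normalize_token(tok)
      if (nzchar(core)) {
        d <- as.integer(adist(core, dict_lc))
        for (radius in c(1L, 2L)) {
          hits <- which(d == radius)
          if (length(hits) == 1L) {
            word <- dict_lc[hits]
            lead <- sub("^([^[:alnum:]]*).*$", "\\1", tok)
            trail <- sub("^.*?([^[:alnum:]]*)$", "\\1", tok)
            stripped <- substr(tok, nchar(lead) + 1L,
                               nchar(tok) - nchar(trail))
            if (grepl("^[A-Z]", stripped)) {
              substr(word, 1, 1) <- toupper(substr(word, 1, 1))
            }
            replacement <- paste0(lead, word, trail)
            break
          }
          if (length(hits) > 1L) break # ambiguous: leave unchanged
        }
      }
    }
    if (!is.null(replacement)) {
      text <- paste0(substr(text, 1, tokens$start[i]), replacement,
                     substring(text, tokens$end[i] + 1L))
    }
  }
  text
}

#' Language-model backend adapter
#'
#' Transport-agnostic adapter for external completion services used to
#' detect or correct errors. The `transport` argument is any function
#' `function(prompt) -> completion string`; tests use scripted mocks, and a
#' production transport can wrap an HTTP client. Prompt templates live in
#' `inst/prompts/` and use the placeholders `{note}` (raw text) and
#' `{tokens}` (JSON array of whitespace tokens).
#'
#' For `mode = "detect"` the completion must be a JSON array of the flagged
#' token strings (subset of the note's whitespace tokens); for
#' `mode = "correct"` it must be the corrected note text.
#'
#' @param note One-row slice of a [note_corpus()].
#' @param mode `"detect"` or `"correct"`.
#' @param transport Function taking the rendered prompt, returning the raw
#'   completion.
#' @param prompt_template Template string; defaults to the packaged template
#'   for the mode.
#' @return A `detection_result` (detect) or corrected text (correct).
#' @export
llm_backend <- function(note, mode = c("detect", "correct"), transport,
                        prompt_template = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.function(transport))
  if (is.null(prompt_template)) {
    path <- system.file("prompts", paste0(mode, ".txt"), package = "noteqc")
    prompt_template <- paste(readLines(path, warn = FALSE), collapse = "\n")
  }
  tokens <- whitespace_tokenize(note$text)
  prompt <- gsub("{note}", note$text, prompt_template, fixed = TRUE)
  prompt <- gsub("{tokens}",
                 as.character(jsonlite::toJSON(tokens$token)),
                 prompt, fixed = TRUE)
  completion <- tryCatch(transport(prompt), error = function(e) {
    abort(paste0("transport failure for note ", note$note_id, ": ",
                 conditionMessage(e)),
          class = "noteqc_transport_error")
  })
  if (mode == "correct") {
    if (!is.character(completion) || length(completion) != 1) {
      abort(paste0("backend returned a non-text correction for note ",
                   note$note_id),
            class = "noteqc_backend_response_error")
    }
    return(completion)
  }
  parsed <- tryCatch(jsonlite::fromJSON(completion, simplifyVector = TRUE),
                     error = function(e) NULL)
  if (is.null(parsed) && !identical(completion, "[]")) {
    abort(paste0("unparseable detection completion for note ", note$note_id,
                 ": ", substr(completion, 1, 200)),
          class = "noteqc_backend_response_error")
  }
  flagged_tokens <- as.character(parsed %||% character())
  unknown <- setdiff(flagged_tokens, tokens$token)
  if (length(unknown) > 0) {
    abort(paste0("backend flagged token(s) absent from note ", note$note_id,
                 ": ", paste(head(unknown, 5), collapse = ", ")),
          class = "noteqc_backend_response_error")
  }
  structure(list(note_id = note$note_id,
                 flagged_indices = which(tokens$token %in% flagged_tokens),
                 backend_name = "llm"),
            class = "detection_result")
}

#' Run a detector over a corpus
#'
#' @param corpus A [note_corpus()].
#' @param detector Function `(note, ...) -> detection_result`, e.g.
#'   [detect_errors_dictionary()].
#' @param ... Passed to the detector.
#' @return Tibble with columns `note_id`, `token_index`.
#' @export
detect_corpus <- function(corpus, detector = detect_errors_dictionary, ...) {
  stopifnot(inherits(corpus, "note_corpus"))
  rows <- lapply(seq_len(nrow(corpus)), function(i) {
    res <- detector(corpus[i, ], ...)
    tibble::tibble(note_id = res$note_id,
                   token_index = as.integer(res$flagged_indices))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(note_id = character(), token_index = integer())
  }
  out
}

#' Evaluate error detection against ground truth
#'
#' Per note, compares the detector's flagged token indices with the
#' annotated truth: the absolute difference of the two error rates (in
#' percentage points) and the size of the symmetric difference of the index
#' sets. Aggregates give the mean/SD rate deviation, the mean mismatched
#' token count, and the fraction of notes detected exactly
#' (zero mismatches) or off by exactly one token.
#'
#' @param detections Tibble `note_id`, `token_index` (e.g. from
#'   [detect_corpus()]).
#' @param annotations Ground-truth annotations. When a
#'   `corrupted_token_index` column is present (as produced by
#'   [apply_corruption()]) it is used as the truth index set, since the
#'   detector and the annotations must refer to the same tokenization --
#'   that of the note the detector actually saw.
#' @param corpus The corpus the detector ran on.
#' @param min_tokens Notes with fewer whitespace tokens are excluded.
#' @return A `detection_eval`: list with `mean_abs_rate_deviation`,
#'   `sd_abs_rate_deviation` (percentage points), `mean_token_mismatch`,
#'   `pct_notes_exact`, `pct_notes_off_by_one`, `n_notes`.
#' @export
evaluate_detection <- function(detections, annotations, corpus,
                               min_tokens = 5) {
  stopifnot(inherits(corpus, "note_corpus"))
  ids <- unique(c(detections$note_id, annotations$note_id))
  unknown <- setdiff(ids, corpus$note_id)
  if (length(unknown) > 0) {
    abort(paste0("detections/annotations reference unknown notes: ",
                 paste(head(unknown, 5), collapse = ", ")),
          class = "noteqc_alignment_error")
  }
  truth_col <- if ("corrupted_token_index" %in% names(annotations)) {
    "corrupted_token_index"
  } else {
    "token_index"
  }
  dev <- numeric(0); mism <- integer(0)
  for (i in seq_len(nrow(corpus))) {
    id <- corpus$note_id[i]
    n <- nrow(whitespace_tokenize(corpus$text[i]))
    if (n < min_tokens) next
    det_idx <- unique(detections$token_index[detections$note_id == id])
    tru_idx <- unique(annotations[[truth_col]][annotations$note_id == id])
    dev <- c(dev, abs(length(det_idx) - length(tru_idx)) / n)
    mism <- c(mism, length(setdiff(det_idx, tru_idx)) +
                length(setdiff(tru_idx, det_idx)))
  }
  if (length(dev) == 0) {
    abort("no notes left to evaluate", class = "noteqc_empty_report_error")
  }
  structure(
    list(mean_abs_rate_deviation = 100 * mean(dev),
         sd_abs_rate_deviation = 100 * pop_sd(dev),
         mean_token_mismatch = mean(mism),
         pct_notes_exact = mean(mism == 0L),
         pct_notes_off_by_one = mean(mism == 1L),
         n_notes = length(dev)),
    class = "detection_eval"
  )
}

#' @export
print.detection_eval <- function(x, ...) {
  cat(sprintf(
    paste0("<detection_eval> rate deviation %.2f pp (SD %.2f), mean mismatched",
           " tokens %.2f; exact %.0f%%, off-by-one %.0f%% of %d notes\n"),
    x$mean_abs_rate_deviation, x$sd_abs_rate_deviation,
    x$mean_token_mismatch, 100 * x$pct_notes_exact,
    100 * x$pct_notes_off_by_one, x$n_notes))
  invisible(x)
}

# Error rate of a hypothesis corpus against a clean reference, by per-note
# token alignment. Tokens are compared on their punctuation-stripped,
# lowercased form; token-count changes (splits/merges introduced by a
# corrector) are handled by minimal edit alignment.
alignment_error_rate <- function(hypothesis_texts, reference_texts,
                                 min_tokens = 5) {
  stopifnot(length(hypothesis_texts) == length(reference_texts))
  rates <- numeric(0)
  for (i in seq_along(reference_texts)) {
    ref <- normalize_token(whitespace_tokenize(reference_texts[i])$token)
    ref <- ref[nzchar(ref)]
    if (length(ref) < min_tokens) next
    hyp <- normalize_token(whitespace_tokenize(hypothesis_texts[i])$token)
    hyp <- hyp[nzchar(hyp)]
    bad <- count_unmatched_reference_tokens(ref, hyp)
    rates <- c(rates, bad / length(ref))
  }
  if (length(rates) == 0) {
    abort("no notes long enough to score", class = "noteqc_empty_report_error")
  }
  mean(rates)
}

#' Evaluate error correction against a clean reference
#'
#' Scores a corrected corpus against the clean reference: the baseline error
#' rate (corrupted vs reference), the residual error rate (corrected vs
#' reference, tokens aligned by minimal edit alignment so splits/merges are
#' handled), and the fraction of the original errors removed,
#' `1 - residual / baseline`.
#'
#' @param corrected_texts,corrupted_texts,reference_texts Character vectors
#'   of aligned note texts (same order).
#' @param min_tokens Notes with fewer reference tokens are excluded.
#' @return A `correction_eval`: list with `baseline_error_rate`,
#'   `residual_error_rate`, `pct_errors_corrected`.
#' @export
evaluate_correction <- function(corrected_texts, corrupted_texts,
                                reference_texts, min_tokens = 5) {
  baseline <- alignment_error_rate(corrupted_texts, reference_texts,
                                   min_tokens = min_tokens)
  residual <- alignment_error_rate(corrected_texts, reference_texts,
                                   min_tokens = min_tokens)
  if (baseline == 0) {
    abort("baseline error rate is zero; pct_errors_corrected undefined",
          class = "noteqc_undefined_rate_error")
  }
  structure(
    list(baseline_error_rate = baseline,
         residual_error_rate = residual,
         pct_errors_corrected = 1 - residual / baseline),
    class = "correction_eval"
  )
}

#' @export
print.correction_eval <- function(x, ...) {
  cat(sprintf(
    "<correction_eval> error rate %.2f%% -> %.2f%% (%.0f%% of errors corrected)\n",
    100 * x$baseline_error_rate, 100 * x$residual_error_rate,
    100 * x$pct_errors_corrected))
  invisible(x)
}
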