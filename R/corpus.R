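#' Construct a note corpus
#'
#' A corpus is a tibble of free-text notes -- one row per note -- with a
#' `note_id` (unique), a `subject_id`, the raw `text`, and an optional
#' sortable `order_key` (timestamp or sequence number). Text is stored
#' byte-for-byte as given: no lowercasing or normalisation happens at I/O
#' time; all normalisation belongs to feature tokenization.
#'
#' @param notes Data frame with columns `note_id`, `subject_id`, `text`, and
#'   optionally `order_key`.
#' @param metadata Named list of free-form provenance (source, corruption
#'   config, ...), carried through reads and writes.
#' @return A `note_corpus` (tibble subclass) with a `metadata` attribute.
#' @export
note_corpus <- function(notes, metadata = list()) {
  notes <- tibble::as_tibble(notes)
  required <- c("note_id", "subject_id", "text")
  missing_cols <- setdiff(required, names(notes))
  if (length(missing_cols) > 0) {
    abort(
      paste0("corpus is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "noteqc_schema_error"
    )
  }
  notes$note_id <- as.character(notes$note_id)
  notes$subject_id <- as.character(notes$subject_id)
  notes$text <- as.character(notes$text)
  if (!"order_key" %in% names(notes)) notes$order_key <- seq_len(nrow(notes))
  if (anyDuplicated(notes$note_id)) {
    dup <- unique(notes$note_id[duplicated(notes$note_id)])
    abort(
      paste0("duplicate note_id: ", paste(head(dup, 5), collapse = ", ")),
      class = "noteqc_integrity_error"
    )
  }
  notes <- notes[, c("note_id", "subject_id", "text", "order_key")]
  structure(notes,
            metadata = metadata,
            class = c("note_corpus", class(tibble::tibble())))
}

#' @export
print.note_corpus <- function(x, ...) {
  meta <- attr(x, "metadata")
  cat("<note_corpus> ", nrow(x), " notes, ",
      length(unique(x$subject_id)), " subjects\n", sep = "")
  if (length(meta) > 0) {
    cat("metadata: ", paste(names(meta), collapse = ", "), "\n", sep = "")
  }
  NextMethod()
}

#' Corpus metadata
#' @param corpus A `note_corpus`.
#' @return Named list of metadata.
#' @export
corpus_metadata <- function(corpus) attr(corpus, "metadata") %||% list()

#' Read a note corpus from disk
#'
#' Native format is JSONL (one JSON object per note: `note_id`, `subject_id`,
#' `text`, optional `order_key`), because note text routinely contains commas
#' and newlines. CSV (RFC-4180 quoting, columns `note_id,subject_id,text`
#' with optional `order_key`) is supported for NOTEEVENTS-style exports.
#' Corpus metadata written by [write_corpus()] is recovered from a
#' `<path>.meta.json` sidecar when present.
#'
#' @param path File path.
#' @param format `"jsonl"` or `"csv"`.
#' @param allow_empty_text Permit empty note text (default FALSE).
#' @return A [note_corpus()].
#' @export
read_corpus <- function(path, format = c("jsonl", "csv"),
                        allow_empty_text = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "noteqc_io_error")
  }
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) {
      notes <- tibble::tibble(note_id = character(), subject_id = character(),
                              text = character())
    } else {
      recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
      notes <- dplyr::bind_rows(lapply(recs, tibble::as_tibble))
    }
  } else {
    notes <- readr::read_csv(path, col_types = readr::cols(
      .default = readr::col_character()
    ), trim_ws = FALSE, progress = FALSE)
  }
  required <- c("note_id", "subject_id", "text")
  missing_cols <- setdiff(required, names(notes))
  if (length(missing_cols) > 0) {
    abort(
      paste0("corpus file is missing column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "noteqc_schema_error"
    )
  }
  if (!allow_empty_text && nrow(notes) > 0 &&
      any(is.na(notes$text) | notes$text == "")) {
    abort("corpus contains empty note text (set allow_empty_text = TRUE to permit)",
          class = "noteqc_schema_error")
  }
  meta_path <- paste0(path, ".meta.json")
  metadata <- if (file.exists(meta_path)) {
    jsonlite::fromJSON(meta_path, simplifyVector = TRUE)
  } else {
    list()
  }
  note_corpus(notes, metadata = as.list(metadata))
}

#' Write a note corpus to disk
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(c))` reproduces `c`
#' exactly (ids, order, text). Non-empty metadata goes to a
#' `<path>.meta.json` sidecar.
#'
#' @param corpus A [note_corpus()].
#' @param path Destination file.
#' @param format `"jsonl"` or `"csv"`.
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(corpus, "note_corpus"))
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(corpus)), function(i) {
      jsonlite::toJSON(as.list(corpus[i, , drop = FALSE]),
                       auto_unbox = TRUE, digits = NA)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    readr::write_csv(tibble::as_tibble(corpus), path, progress = FALSE)
  }
  meta <- corpus_metadata(corpus)
  if (length(meta) > 0) {
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Assemble per-subject labeled documents
#'
#' Concatenates each subject's note texts -- in `order_key` order, ties broken
#' by `note_id` -- into a single document joined with single spaces, and
#' attaches the subject's binary outcome label. This mirrors pooling all of a
#' patient's progress notes into one prediction instance.
#'
#' @param corpus A [note_corpus()].
#' @param labels Named vector (names = subject_id) or data frame with columns
#'   `subject_id`, `label`; labels must be 0/1.
#' @return Tibble with columns `subject_id`, `text`, `label`, one row per
#'   subject with at least one note.
#' @export
assemble_documents <- function(corpus, labels) {
  stopifnot(inherits(corpus, "note_corpus"))
  if (is.data.frame(labels)) {
    lab <- stats::setNames(labels$label, as.character(labels$subject_id))
  } else {
    lab <- labels
  }
  if (!all(lab %in% c(0, 1))) {
    abort("labels must be 0/1", class = "noteqc_label_error")
  }
  subjects <- unique(corpus$subject_id)
  missing_subj <- setdiff(subjects, names(lab))
  if (length(missing_subj) > 0) {
    abort(
      paste0("subjects missing from labels: ",
             paste(head(missing_subj, 10), collapse = ", ")),
      class = "noteqc_label_error"
    )
  }
  ord <- order(corpus$subject_id, corpus$order_key, corpus$note_id,
               method = "radix")
  sorted <- corpus[ord, ]
  docs <- sorted |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(text = paste(.data$text, collapse = " "),
                     .groups = "drop")
  docs$label <- as.integer(lab[docs$subject_id])
  docs
}
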