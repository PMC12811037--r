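# Document-term counting shared by fit and transform: feature_tokenize each
# text, keep tokens in `keep` (or all), return a sparse doc x term count
# matrix over `vocab` (or the observed vocabulary, sorted).
count_matrix <- function(texts, vocab = NULL) {
  token_lists <- feature_tokenize(texts)
  if (length(texts) == 1) token_lists <- list(token_lists)
  doc_idx <- rep.int(seq_along(token_lists),
                     vapply(token_lists, length, integer(1)))
  toks <- unlist(token_lists, use.names = FALSE)
  if (is.null(vocab)) {
    vocab <- sort(unique(toks))
  }
  keep <- toks %in% vocab
  toks <- toks[keep]
  doc_idx <- doc_idx[keep]
  j <- match(toks, vocab)
  Matrix::sparseMatrix(
    i = doc_idx, j = j, x = 1,
    dims = c(length(texts), length(vocab)),
    dimnames = list(NULL, vocab)
  )
}

#' Fit a TF-IDF model
#'
#' Tokenizes with [feature_tokenize()] (unigrams only), removes stop words,
#' applies the vocabulary filter, and computes smoothed inverse document
#' frequencies `idf(t) = ln((1 + N) / (1 + df_t)) + 1`. Three vocabulary
#' variants are supported: `"top_k"` keeps the `k` most frequent tokens by
#' total corpus count (ties broken lexicographically), `"min_freq"` keeps
#' tokens whose total count is strictly greater than `min_freq`, and
#' `"unfiltered"` keeps everything.
#'
#' @param texts Character vector of document texts.
#' @param variant `"min_freq"`, `"top_k"` or `"unfiltered"`.
#' @param k Vocabulary cap for `top_k` (default 5000).
#' @param min_freq Strict total-count threshold for `min_freq` (default 5,
#'   i.e. keep tokens occurring more than 5 times).
#' @param stop_words Stop-word list (default [noteqc_stopwords()]).
#' @return A `tfidf_model`: list with `vocabulary` (sorted), `idf`,
#'   `total_count`, `doc_freq`, `variant`, `stop_words`.
#' @export
fit_tfidf <- function(texts, variant = c("min_freq", "top_k", "unfiltered"),
                      k = 5000, min_freq = 5,
                      stop_words = noteqc_stopwords()) {
  variant <- match.arg(variant)
  if (length(texts) < 1) {
    abort("need at least one document", class = "noteqc_fit_error")
  }
  counts <- count_matrix(texts)
  vocab <- colnames(counts)
  drop <- vocab %in% stop_words
  counts <- counts[, !drop, drop = FALSE]
  vocab <- colnames(counts)
  total <- Matrix::colSums(counts)
  if (variant == "min_freq") {
    sel <- total > min_freq
  } else if (variant == "top_k") {
    if (length(vocab) > k) {
      ord <- order(-total, vocab, method = "radix")
      sel <- seq_along(vocab) %in% ord[seq_len(k)]
    } else {
      sel <- rep(TRUE, length(vocab))
    }
  } else {
    sel <- rep(TRUE, length(vocab))
  }
  if (!any(sel)) {
    abort("vocabulary is empty after filtering", class = "noteqc_fit_error")
  }
  counts <- counts[, sel, drop = FALSE]
  vocab <- colnames(counts)
  n_docs <- length(texts)
  df <- Matrix::colSums(counts > 0)
  idf <- log((1 + n_docs) / (1 + df)) + 1
  structure(
    list(vocabulary = vocab, idf = stats::setNames(idf, vocab),
         total_count = stats::setNames(total[sel], vocab),
         doc_freq = stats::setNames(as.numeric(df), vocab),
         n_docs = n_docs, variant = variant, k = k, min_freq = min_freq,
         stop_words = stop_words),
    class = "tfidf_model"
  )
}

#' @export
print.tfidf_model <- function(x, ...) {
  cat(sprintf("<tfidf_model> %s variant, %d terms over %d documents\n",
              x$variant, length(x$vocabulary), x$n_docs))
  invisible(x)
}

#' Transform documents into TF-IDF features
#'
#' Entries are raw term counts times the model's idf weights, with each row
#' scaled to unit L2 norm (rows with no in-vocabulary tokens stay zero).
#' Out-of-vocabulary tokens are ignored.
#'
#' @param model A [fit_tfidf()] model.
#' @param texts Character vector of documents.
#' @param doc_ids Optional row names.
#' @return Sparse `dgCMatrix` (documents x terms) with a
#'   `representation_tag` attribute.
#' @export
transform_tfidf <- function(model, texts, doc_ids = NULL) {
  stopifnot(inherits(model, "tfidf_model"))
  tf <- count_matrix(texts, vocab = model$vocabulary)
  x <- tf %*% Matrix::Diagonal(x = unname(model$idf[model$vocabulary]))
  norms <- sqrt(Matrix::rowSums(x^2))
  norms[norms == 0] <- 1
  x <- Matrix::Diagonal(x = 1 / norms) %*% x
  x <- methods::as(x, "CsparseMatrix")
  dimnames(x) <- list(doc_ids, model$vocabulary)
  attr(x, "representation_tag") <- paste0("tfidf_", model$variant)
  x
}

#' Serialize / restore a TF-IDF model
#'
#' @param model A `tfidf_model`.
#' @param path JSON file path.
#' @export
write_tfidf <- function(model, path) {
  stopifnot(inherits(model, "tfidf_model"))
  payload <- list(
    vocabulary = model$vocabulary,
    idf = unname(model$idf[model$vocabulary]),
    total_count = unname(model$total_count[model$vocabulary]),
    doc_freq = unname(model$doc_freq[model$vocabulary]),
    n_docs = model$n_docs, variant = model$variant, k = model$k,
    min_freq = model$min_freq, stop_words = model$stop_words)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tfidf
#' @export
read_tfidf <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  x$idf <- stats::setNames(as.numeric(x$idf), x$vocabulary)
  x$total_count <- stats::setNames(as.numeric(x$total_count), x$vocabulary)
  x$doc_freq <- stats::setNames(as.numeric(x$doc_freq), x$vocabulary)
  structure(x, class = "tfidf_model")
}
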