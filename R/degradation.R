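#' Representation specifications
#'
#' A representation spec bundles a tag, a fit step (run on the training
#' documents only, so nothing leaks from the test split) and a transform
#' step. `rep_tfidf()` wraps [fit_tfidf()]/[transform_tfidf()];
#' `rep_embedding()` wraps a fixed (pretrained-style) backend, whose "fit"
#' is a no-op.
#'
#' @param variant,k,min_freq,stop_words Passed to [fit_tfidf()].
#' @param tag Override the representation tag.
#' @return A `representation_spec`.
#' @export
rep_tfidf <- function(variant = "min_freq", k = 5000, min_freq = 5,
                      stop_words = noteqc_stopwords(), tag = NULL) {
  structure(
    list(tag = tag %||% paste0("tfidf_", variant),
         fit = function(texts) fit_tfidf(texts, variant = variant, k = k,
                                         min_freq = min_freq,
                                         stop_words = stop_words),
         transform = function(state, texts) transform_tfidf(state, texts)),
    class = "representation_spec"
  )
}

#' @param backend An `embedding_backend`, e.g. [hash_embedding_backend()].
#' @rdname rep_tfidf
#' @export
rep_embedding <- function(backend, tag = NULL) {
  structure(
    list(tag = tag %||% paste0("embed_", backend$name),
         fit = function(texts) backend,
         transform = function(state, texts) embed_documents(texts, state)),
    class = "representation_spec"
  )
}

#' Run the quality-degradation experiment
#'
#' The end-to-end benchmark: for every target error rate, corrupt the corpus
#' (rate 0 is the clean baseline), assemble per-subject documents, and for
#' every seed draw a stratified 2/3-1/3 split, fit each representation on
#' the training documents only, train each model, and evaluate on the test
#' documents. By default the whole corpus is corrupted before splitting
#' (`corrupt_scope = "all"`); `"test_only"` corrupts only test documents,
#' for the regime where a model trained on clean text meets noisy input.
#'
#' @param corpus Clean [note_corpus()].
#' @param labels Named 0/1 vector by subject_id (or data frame).
#' @param rates Error-rate levels; must include 0.
#' @param representations List of `representation_spec`s.
#' @param models List of [model_spec()]s.
#' @param seeds Integer vector of evaluation seeds.
#' @param base_seed Master seed for corruption streams.
#' @param forbidden Dictionary for the misspelling generator.
#' @param corrupt_scope `"all"` or `"test_only"`.
#' @param min_tokens Corruption floor for short notes.
#' @return A `degradation_curve`: list with `results` (long tibble: rate,
#'   representation, family, seed, roc_auc, precision, recall, f1),
#'   `summary` (mean/SD ROC-AUC per rate x representation x family), and
#'   `provenance`.
#' @export
run_degradation_experiment <- function(corpus, labels,
                                       rates = c(0, 0.05, 0.10, 0.15, 0.20),
                                       representations = list(rep_tfidf()),
                                       models = list(model_spec("logistic")),
                                       seeds = 1:5,
                                       base_seed = 20260101L,
                                       forbidden = character(),
                                       corrupt_scope = c("all", "test_only"),
                                       min_tokens = 5) {
  corrupt_scope <- match.arg(corrupt_scope)
  stopifnot(inherits(corpus, "note_corpus"))
  if (!any(rates == 0)) {
    abort("rates must include 0 (the clean baseline)",
          class = "noteqc_config_error")
  }
  rates <- sort(unique(rates))
  versions <- corrupt_corpus(corpus, rates = rates, base_seed = base_seed,
                             forbidden = forbidden, min_tokens = min_tokens)
  clean_docs <- assemble_documents(corpus, labels)
  results <- list()
  for (rate in rates) {
    docs <- assemble_documents(versions[[as.character(rate)]]$corpus, labels)
    for (seed in seeds) {
      sp_idx <- split_train_test(clean_docs, seed = seed)
      train_ids <- sp_idx$train$subject_id
      test_ids <- sp_idx$test$subject_id
      if (corrupt_scope == "all") {
        train_docs <- docs[match(train_ids, docs$subject_id), ]
      } else {
        train_docs <- clean_docs[match(train_ids, clean_docs$subject_id), ]
      }
      test_docs <- docs[match(test_ids, docs$subject_id), ]
      for (rep_spec in representations) {
        state <- rep_spec$fit(train_docs$text)
        x_train <- rep_spec$transform(state, train_docs$text)
        x_test <- rep_spec$transform(state, test_docs$text)
        for (spec in models) {
          row <- train_and_eval(x_train, train_docs$label,
                                x_test, test_docs$label, spec, seed = seed)
          row$rate <- rate
          row$representation <- rep_spec$tag
          results[[length(results) + 1L]] <- row
        }
      }
    }
  }
  results <- dplyr::bind_rows(results)
  results <- results[, c("rate", "representation", "family", "seed",
                         "roc_auc", "precision", "recall", "f1")]
  summary <- results |>
    dplyr::group_by(.data$rate, .data$representation, .data$family) |>
    dplyr::summarise(mean_roc_auc = mean(.data$roc_auc),
                     sd_roc_auc = stats::sd(.data$roc_auc),
                     n_seeds = dplyr::n(), .groups = "drop")
  structure(
    list(results = results, summary = summary,
         provenance = list(rates = rates, seeds = seeds,
                           base_seed = base_seed,
                           corrupt_scope = corrupt_scope)),
    class = "degradation_curve"
  )
}

#' @export
print.degradation_curve <- function(x, ...) {
  cat("<degradation_curve> rates:",
      paste(x$provenance$rates, collapse = ", "),
      "| seeds:", length(x$provenance$seeds), "\n")
  print(tidyr_pivot(x$summary))
  invisible(x)
}

# Compact rate-by-cell view without importing tidyr for one call.
tidyr_pivot <- function(summary) {
  cells <- paste(summary$representation, summary$family, sep = "/")
  rates <- sort(unique(summary$rate))
  out <- sapply(sort(unique(cells)), function(cell) {
    vapply(rates, function(r) {
      v <- summary$mean_roc_auc[cells == cell & summary$rate == r]
      if (length(v) == 1) round(v, 3) else NA_real_
    }, numeric(1))
  })
  out <- matrix(out, nrow = length(rates),
                dimnames = list(paste0("rate=", rates), sort(unique(cells))))
  out
}

#' Plot degradation curves
#'
#' Mean ROC-AUC against error rate, one line per model, faceted by
#' representation. Requires ggplot2.
#'
#' @param curve A `degradation_curve`.
#' @return A ggplot object.
#' @export
plot_degradation <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("ggplot2 is required for plotting", class = "noteqc_config_error")
  }
  ggplot2::ggplot(curve$summary,
                  ggplot2::aes(x = .data$rate, y = .data$mean_roc_auc,
                               colour = .data$family)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_roc_auc - .data$sd_roc_auc,
                   ymax = .data$mean_roc_auc + .data$sd_roc_auc),
      width = 0.005) +
    ggplot2::facet_wrap(~representation) +
    ggplot2::labs(x = "injected token error rate", y = "ROC-AUC",
                  colour = "model") +
    ggplot2::theme_minimal()
}
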