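#' Stratified train/test split
#'
#' Splits labeled documents two-thirds/one-third (by default), stratified by
#' label so the rare positive class is represented proportionally in both
#' parts -- important for low-prevalence outcomes. Deterministic given the
#' seed.
#'
#' @param documents Tibble with a `label` column (0/1), e.g. from
#'   [assemble_documents()].
#' @param train_fraction Fraction of each class assigned to training
#'   (default 2/3).
#' @param seed Integer seed.
#' @return List with `train` and `test` tibbles (disjoint, exhaustive).
#' @export
split_train_test <- function(documents, train_fraction = 2 / 3, seed = 1L) {
  stopifnot(is.data.frame(documents), "label" %in% names(documents))
  classes <- sort(unique(documents$label))
  if (length(classes) < 2) {
    abort("both classes must be present to stratify",
          class = "noteqc_stratification_error")
  }
  idx_train <- withr::with_seed(as.integer(seed), {
    unlist(lapply(classes, function(cl) {
      rows <- which(documents$label == cl)
      if (length(rows) < 2) {
        abort(sprintf("class %s has fewer than 2 documents", cl),
              class = "noteqc_stratification_error")
      }
      n_train <- round(length(rows) * train_fraction)
      rows[sample.int(length(rows), n_train)]
    }))
  })
  list(train = documents[sort(idx_train), ],
       test = documents[sort(setdiff(seq_len(nrow(documents)), idx_train)), ])
}

#' ROC-AUC by the rank-sum formulation
#'
#' The probability that a randomly chosen positive document scores higher
#' than a randomly chosen negative one, with ties counted one half --
#' computed exactly via midranks (equivalent to the Mann-Whitney U
#' statistic scaled to \[0, 1\]).
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) {
    abort("ROC-AUC is undefined with a single class",
          class = "noteqc_undefined_metric_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Model specification
#'
#' One point of a hyperparameter grid for one classifier family. Families:
#' `"logistic"` (ridge logistic regression via glmnet), `"svm"` (RBF SVM via
#' e1071 with probability outputs), `"random_forest"` (ranger probability
#' forest), `"gradient_boosting"` (xgboost binary logistic) and `"mlp"`
#' (single-hidden-layer perceptron via nnet).
#'
#' @param family One of the five family names.
#' @param ... Hyperparameters (see [default_model_grid()] for the knobs each
#'   family understands).
#' @return A `model_spec`.
#' @export
model_spec <- function(family = c("logistic", "svm", "random_forest",
                                  "gradient_boosting", "mlp"), ...) {
  family <- match.arg(family)
  structure(list(family = family, hyperparams = list(...)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  hp <- if (length(x$hyperparams) > 0) {
    paste(names(x$hyperparams), unlist(x$hyperparams),
          sep = "=", collapse = ", ")
  } else "defaults"
  cat("<model_spec> ", x$family, " (", hp, ")\n", sep = "")
  invisible(x)
}

#' Default hyperparameter grids
#'
#' Small per-family grids for [grid_search()]: regularization strength for
#' the linear models, cost for the SVM, tree count/depth for the ensembles,
#' hidden width and weight decay for the MLP. These are artifact defaults
#' chosen for desk-scale corpora, not tuned settings.
#'
#' @param family Classifier family.
#' @return List of [model_spec()] objects.
#' @export
default_model_grid <- function(family) {
  switch(family,
    logistic = lapply(c(1e-3, 1e-2, 1e-1), function(l)
      model_spec("logistic", lambda = l)),
    svm = lapply(c(0.5, 1, 4), function(cst)
      model_spec("svm", cost = cst)),
    random_forest = lapply(c(200L, 500L), function(nt)
      model_spec("random_forest", num_trees = nt)),
    gradient_boosting = list(
      model_spec("gradient_boosting", nrounds = 50L, max_depth = 3L, eta = 0.3),
      model_spec("gradient_boosting", nrounds = 100L, max_depth = 4L, eta = 0.1)),
    mlp = lapply(c(8L, 16L), function(h)
      model_spec("mlp", size = h, decay = 1e-3, maxit = 150L)),
    abort(paste0("unknown family: ", family), class = "noteqc_config_error")
  )
}

as_dense <- function(x) {
  out <- as.matrix(x)
  if (is.null(colnames(out))) {
    colnames(out) <- paste0("f", seq_len(ncol(out)))
  }
  out
}

fit_predict <- function(x_train, y_train, x_test, spec, seed) {
  hp <- spec$hyperparams
  withr::with_seed(as.integer(seed), {
    switch(spec$family,
      logistic = {
        fit <- glmnet::glmnet(x_train, factor(y_train), family = "binomial",
                              alpha = 0, lambda = hp$lambda %||% 1e-2,
                              standardize = FALSE)
        as.numeric(predict(fit, newx = x_test, type = "response"))
      },
      svm = {
        fit <- e1071::svm(as_dense(x_train), factor(y_train),
                          kernel = "radial", cost = hp$cost %||% 1,
                          probability = TRUE, scale = FALSE)
        pr <- predict(fit, as_dense(x_test), probability = TRUE)
        attr(pr, "probabilities")[, "1"]
      },
      random_forest = {
        fit <- ranger::ranger(
          x = as_dense(x_train), y = factor(y_train),
          num.trees = hp$num_trees %||% 500L,
          mtry = hp$mtry, probability = TRUE,
          seed = as.integer(seed), num.threads = 1)
        predict(fit, as_dense(x_test),
                num.threads = 1)$predictions[, "1"]
      },
      gradient_boosting = {
        dtrain <- xgboost::xgb.DMatrix(methods::as(x_train, "CsparseMatrix"),
                                       label = y_train)
        fit <- xgboost::xgb.train(
          params = list(objective = "binary:logistic",
                        max_depth = hp$max_depth %||% 3L,
                        eta = hp$eta %||% 0.3,
                        nthread = 1, seed = as.integer(seed)),
          data = dtrain, nrounds = hp$nrounds %||% 50L, verbose = 0)
        predict(fit, xgboost::xgb.DMatrix(methods::as(x_test, "CsparseMatrix")))
      },
      mlp = {
        fit <- nnet::nnet(as_dense(x_train), y_train,
                          size = hp$size %||% 8L,
                          decay = hp$decay %||% 1e-3,
                          maxit = hp$maxit %||% 150L,
                          entropy = TRUE, trace = FALSE,
                          MaxNWts = 200000L)
        as.numeric(predict(fit, as_dense(x_test)))
      }
    )
  })
}

#' Train one model and evaluate it on held-out documents
#'
#' Fits the specified family, scores the test set, and reports ROC-AUC
#' (primary) plus precision/recall/F1 at a 0.5 probability threshold
#' (secondary). All stochastic fits are seeded.
#'
#' @param x_train,x_test Feature matrices (sparse or dense).
#' @param y_train,y_test 0/1 label vectors.
#' @param spec A [model_spec()].
#' @param seed Integer seed.
#' @return One-row tibble: `family`, `roc_auc`, `precision`, `recall`, `f1`,
#'   `seed`.
#' @export
train_and_eval <- function(x_train, y_train, x_test, y_test, spec,
                           seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  if (nrow(x_train) != length(y_train) || nrow(x_test) != length(y_test)) {
    abort("feature/label shapes do not align",
          class = "noteqc_validation_error")
  }
  all_finite <- function(x) {
    if (inherits(x, "sparseMatrix")) all(is.finite(x@x)) else all(is.finite(x))
  }
  if (!all_finite(x_train) || !all_finite(x_test)) {
    abort("non-finite feature values", class = "noteqc_validation_error")
  }
  scores <- fit_predict(x_train, y_train, x_test, spec, seed)
  pred <- as.integer(scores >= 0.5)
  tp <- sum(pred == 1L & y_test == 1L)
  fp <- sum(pred == 1L & y_test == 0L)
  fn <- sum(pred == 0L & y_test == 1L)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble::tibble(family = spec$family,
                 roc_auc = roc_auc(scores, y_test),
                 precision = precision, recall = recall, f1 = f1,
                 seed = as.integer(seed))
}

#' Hyperparameter grid search by inner-split ROC-AUC
#'
#' Evaluates each grid point on an inner stratified split of the training
#' documents and returns the point with the highest ROC-AUC (ties broken by
#' grid order), together with the full per-point results table.
#'
#' @param x_train,y_train Training features/labels.
#' @param grid List of [model_spec()] objects (same family).
#' @param inner_fraction Inner training fraction (default 2/3).
#' @param seed Seed for the inner split and fits.
#' @return List with `best` (a `model_spec`), `results` (tibble: one row per
#'   grid point with its inner ROC-AUC and secondary metrics).
#' @export
grid_search <- function(x_train, y_train, grid, inner_fraction = 2 / 3,
                        seed = 1L) {
  if (length(grid) == 0) {
    abort("empty hyperparameter grid", class = "noteqc_config_error")
  }
  docs <- tibble::tibble(row = seq_along(y_train), label = y_train)
  sp <- split_train_test(docs, train_fraction = inner_fraction, seed = seed)
  xi <- x_train[sp$train$row, , drop = FALSE]
  yi <- y_train[sp$train$row]
  xv <- x_train[sp$test$row, , drop = FALSE]
  yv <- y_train[sp$test$row]
  rows <- lapply(seq_along(grid), function(g) {
    res <- train_and_eval(xi, yi, xv, yv, grid[[g]], seed = seed)
    res$grid_index <- g
    res$hyperparams <- paste(names(grid[[g]]$hyperparams),
                             unlist(grid[[g]]$hyperparams),
                             sep = "=", collapse = ",")
    res
  })
  results <- dplyr::bind_rows(rows)
  best_idx <- results$grid_index[which.max(results$roc_auc)]
  list(best = grid[[best_idx]], results = results)
}
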