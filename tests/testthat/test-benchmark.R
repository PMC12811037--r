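make_docs <- function(n, prevalence, seed) {
  withr::with_seed(seed, tibble::tibble(
    subject_id = sprintf("s%03d", 1:n),
    text = "placeholder",
    label = rbinom(n, 1, prevalence)))
}

test_that("stratified split is exact, disjoint and deterministic", {
  docs <- tibble::tibble(subject_id = sprintf("s%03d", 1:300),
                         text = "x",
                         label = rep(c(1, 0), c(30, 270)))
  sp <- split_train_test(docs, seed = 4)
  expect_equal(nrow(sp$train), 200)
  expect_equal(nrow(sp$test), 100)
  expect_equal(sum(sp$train$label), 20)
  expect_equal(sum(sp$test$label), 10)
  expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0)
  expect_setequal(c(sp$train$subject_id, sp$test$subject_id),
                  docs$subject_id)
  sp2 <- split_train_test(docs, seed = 4)
  expect_identical(sp, sp2)
  expect_error(split_train_test(docs[docs$label == 0, ], seed = 1),
               class = "noteqc_stratification_error")
})

test_that("roc auc equals the positive-negative pair probability", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_equal(roc_auc(c(0.5, 0.5, 0.5, 0.5), c(1, 1, 0, 0)), 0.5)
  withr::with_seed(8, {
    for (i in 1:50) {
      s <- sample(0:6, 30, replace = TRUE) + rnorm(30, 0, 1e-3)
      y <- rbinom(30, 1, 0.4)
      if (length(unique(y)) < 2) next
      brute <- mean(outer(s[y == 1], s[y == 0],
                          function(a, b) (a > b) + 0.5 * (a == b)))
      expect_equal(roc_auc(s, y), brute, tolerance = 1e-12)
      # complement symmetry under tie-free scores
      expect_equal(roc_auc(s, y) + roc_auc(-s, y), 1, tolerance = 1e-12)
    }
  })
  expect_error(roc_auc(1:3, c(1, 1, 1)),
               class = "noteqc_undefined_metric_error")
})

test_that("every model family separates a separable fixture and is seeded", {
  withr::with_seed(5, {
    x <- rbind(matrix(rnorm(160, 2), 80), matrix(rnorm(160, -2), 80))
    y <- rep(c(1, 0), each = 80)
  })
  tr <- c(1:60, 81:140)
  te <- setdiff(1:160, tr)
  xs <- Matrix::Matrix(x, sparse = TRUE)
  for (fam in c("logistic", "svm", "random_forest", "gradient_boosting",
                "mlp")) {
    r <- train_and_eval(xs[tr, ], y[tr], xs[te, ], y[te],
                        model_spec(fam), seed = 2)
    expect_gte(r$roc_auc, 0.95)
    r2 <- train_and_eval(xs[tr, ], y[tr], xs[te, ], y[te],
                         model_spec(fam), seed = 2)
    expect_identical(r, r2)
  }
})

test_that("label-independent features score at chance level", {
  aucs <- vapply(1:10, function(s) {
    withr::with_seed(1000 + s, {
      x <- matrix(rnorm(1000 * 6), 1000)
      y <- rbinom(1000, 1, 0.3)
    })
    train_and_eval(x[1:660, ], y[1:660], x[661:1000, ], y[661:1000],
                   model_spec("logistic"), seed = s)$roc_auc
  }, numeric(1))
  expect_true(all(aucs > 0.4 & aucs < 0.6))
})

test_that("grid search returns the auc argmax with a full report", {
  # XOR-style labels: a depth-1 stump provably cannot separate them, a
  # deeper boosted model can, so the dominant grid point is known
  withr::with_seed(6, {
    x <- matrix(rnorm(400 * 2), 400)
    y <- as.integer(xor(x[, 1] > 0, x[, 2] > 0))
  })
  one <- grid_search(x, y, list(model_spec("logistic", lambda = 0.01)),
                     seed = 3)
  expect_equal(one$best$hyperparams$lambda, 0.01)
  expect_equal(nrow(one$results), 1)

  grid <- list(
    model_spec("gradient_boosting", nrounds = 1L, max_depth = 1L, eta = 0.3),
    model_spec("gradient_boosting", nrounds = 80L, max_depth = 4L, eta = 0.3))
  gs <- grid_search(x, y, grid, seed = 3)
  expect_equal(gs$best$hyperparams$nrounds, 80L)
  expect_equal(nrow(gs$results), 2)
  expect_true(all(c("roc_auc", "grid_index", "hyperparams") %in%
                    names(gs$results)))
  expect_error(grid_search(x, y, list(), seed = 1),
               class = "noteqc_config_error")
})

test_that("degradation experiment is reproducible and anchored at rate 0", {
  bundle <- small_bundle()
  reps <- list(rep_tfidf("min_freq", min_freq = 2))
  curve <- run_degradation_experiment(
    bundle$corpus, bundle$labels, rates = c(0, 0.2),
    representations = reps, models = list(model_spec("logistic")),
    seeds = 1:2, base_seed = 31, forbidden = bundle$dictionary)
  expect_equal(sort(unique(curve$results$rate)), c(0, 0.2))
  expect_equal(nrow(curve$results), 4) # 2 rates x 2 seeds x 1 rep x 1 model

  curve2 <- run_degradation_experiment(
    bundle$corpus, bundle$labels, rates = c(0, 0.2),
    representations = reps, models = list(model_spec("logistic")),
    seeds = 1:2, base_seed = 31, forbidden = bundle$dictionary)
  expect_identical(curve$results, curve2$results)

  # the rate-0 cell equals a direct clean-corpus run
  docs <- assemble_documents(bundle$corpus, bundle$labels)
  sp <- split_train_test(docs, seed = 1)
  st <- fit_tfidf(sp$train$text, variant = "min_freq", min_freq = 2)
  direct <- train_and_eval(transform_tfidf(st, sp$train$text),
                           sp$train$label,
                           transform_tfidf(st, sp$test$text),
                           sp$test$label,
                           model_spec("logistic"), seed = 1)
  got <- curve$results[curve$results$rate == 0 & curve$results$seed == 1, ]
  expect_equal(got$roc_auc, direct$roc_auc, tolerance = 1e-12)

  expect_error(
    run_degradation_experiment(bundle$corpus, bundle$labels,
                               rates = c(0.1, 0.2),
                               representations = reps,
                               models = list(model_spec("logistic"))),
    class = "noteqc_config_error")
})
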