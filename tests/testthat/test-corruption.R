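test_that("corruption plans allocate the budget per the target rate", {
  spans <- whitespace_tokenize(paste(rep("token", 20), collapse = " "))
  cfg <- corruption_config(0.10)
  plan <- withr::with_seed(1, plan_corruption(spans, cfg))
  expect_equal(plan$k_total, 2)
  expect_equal(plan$k_misspell + plan$k_merge, 2)

  # fixed 40/60 split at a 10% rate on 100 tokens: 4 misspellings, 6 merges
  spans100 <- whitespace_tokenize(paste(rep("token", 100), collapse = " "))
  cfg_fixed <- corruption_config(0.10, type_split = "fixed",
                                 misspell_fraction = 0.4)
  plan100 <- withr::with_seed(1, plan_corruption(spans100, cfg_fixed))
  expect_equal(plan100$k_misspell, 4)
  expect_equal(plan100$k_merge, 6)

  # disjoint index sets; merge sites stay inside the note
  expect_length(intersect(plan100$misspell_idx, plan100$merge_idx), 0)
  expect_true(all(plan100$merge_idx < 100))

  # below the floor: refuse
  expect_error(plan_corruption(whitespace_tokenize("a b c"), cfg),
               class = "noteqc_capacity_error")
})

test_that("misspelling is one seeded edit avoiding the forbidden set", {
  out <- withr::with_seed(7, misspell_token("overnight"))
  expect_false(out == "overnight")
  expect_lte(adist("overnight", out), 2) # one edit (transpose counts 2)

  dict <- c("cat", "dog", "resident")
  out2 <- withr::with_seed(3, misspell_token("cat", forbidden = dict))
  expect_false(tolower(out2) %in% dict)

  # determinism and first-letter case preservation
  expect_identical(withr::with_seed(11, misspell_token("Resident")),
                   withr::with_seed(11, misspell_token("Resident")))
  expect_match(withr::with_seed(11, misspell_token("Resident")), "^[A-Z]")

  expect_error(misspell_token("ab"), class = "noteqc_generation_error")
})

test_that("applying a plan realizes exactly the planned errors", {
  note <- list(note_id = "n1", text = "feeling unwell. Resident wanted toast")
  spans <- whitespace_tokenize(note$text)
  plan <- structure(list(n_tokens = 5L, k_total = 1L, k_misspell = 0L,
                         k_merge = 1L, misspell_idx = integer(),
                         merge_idx = 2L),
                    class = "corruption_plan")
  res <- apply_corruption(note, plan)
  expect_equal(res$text, "feeling unwell.Resident wanted toast")
  expect_equal(res$annotations$error_type, "whitespace_merge")
  expect_equal(res$annotations$corrupted, "unwell.Resident")

  # empty plan is the identity
  plan0 <- structure(list(n_tokens = 5L, k_total = 0L, k_misspell = 0L,
                          k_merge = 0L, misspell_idx = integer(),
                          merge_idx = integer()),
                     class = "corruption_plan")
  res0 <- apply_corruption(note, plan0)
  expect_identical(res0$text, note$text)
  expect_equal(nrow(res0$annotations), 0)

  # plan/note mismatch refused
  expect_error(apply_corruption(list(note_id = "x", text = "a b"), plan),
               class = "noteqc_consistency_error")
})

test_that("unselected text survives corruption unchanged", {
  bundle <- small_bundle()
  version <- corrupt_corpus(bundle$corpus[1:15, ], rates = 0.15,
                            base_seed = 5, forbidden = bundle$dictionary)[[1]]
  for (i in 1:15) {
    clean <- whitespace_tokenize(bundle$corpus$text[i])
    ann <- version$annotations[version$annotations$note_id ==
                                 bundle$corpus$note_id[i], ]
    corrupted <- whitespace_tokenize(version$corpus$text[i])
    # clean tokens not named in any annotation must reappear verbatim
    touched <- sort(unique(c(ann$token_index,
                             ann$token_index[ann$error_type ==
                                               "whitespace_merge"] + 1L)))
    untouched <- setdiff(seq_len(nrow(clean)), touched)
    expect_true(all(clean$token[untouched] %in% corrupted$token))
  }
})

test_that("corpus corruption is reproducible and rate-faithful", {
  bundle <- small_bundle()
  corpus <- bundle$corpus[1:25, ]
  v1 <- corrupt_corpus(corpus, rates = c(0, 0.1), base_seed = 99,
                       forbidden = bundle$dictionary)
  v2 <- corrupt_corpus(corpus, rates = c(0, 0.1), base_seed = 99,
                       forbidden = bundle$dictionary)
  expect_identical(v1[["0.1"]]$corpus$text, v2[["0.1"]]$corpus$text)
  expect_identical(v1[["0.1"]]$annotations, v2[["0.1"]]$annotations)
  # rate 0 leaves the corpus untouched
  expect_identical(v1[["0"]]$corpus$text, corpus$text)
  # per-note annotation count equals round(rate * n_tokens)
  n_tok <- n_ws_tokens(corpus$text)
  counts <- table(factor(v1[["0.1"]]$annotations$note_id,
                         levels = corpus$note_id))
  expect_equal(as.integer(counts), as.integer(round(0.1 * n_tok)))
  # corruption provenance lands in metadata
  expect_equal(corpus_metadata(v1[["0.1"]]$corpus)$corruption$target_rate,
               0.1)
})

test_that("merge-site sampling respects the punctuation weight ratio", {
  # two candidate sites, one punctuation-bearing: selection odds 1.5 : 1
  note_text <- "alpha, beta gamma"
  spans <- whitespace_tokenize(note_text)
  cfg <- corruption_config(1 / 3, type_split = "fixed",
                           misspell_fraction = 0, min_tokens = 3)
  picks <- withr::with_seed(42, {
    vapply(1:4000, function(i) plan_corruption(spans, cfg)$merge_idx,
           integer(1))
  })
  p_hat <- mean(picks == 1L) # site 1 involves "alpha," (punctuation)
  se <- sqrt(0.6 * 0.4 / 4000)
  expect_lt(abs(p_hat - 0.6), 3 * se)
})
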