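dict <- c("resident", "ate", "breakfast", "unwell", "wanted", "toast",
          "feeling", "stable", "overnight", "pain")

test_that("dictionary detector flags out-of-dictionary tokens only", {
  note <- list(note_id = "n", text = "resident ate bfast")
  expect_equal(detect_errors_dictionary(note, dict)$flagged_indices, 3L)

  clean <- list(note_id = "n", text = "Resident ate breakfast, stable.")
  expect_length(detect_errors_dictionary(clean, dict)$flagged_indices, 0)

  merged <- list(note_id = "n", text = "feeling unwell.Resident wanted toast")
  expect_equal(detect_errors_dictionary(merged, dict)$flagged_indices, 2L)

  expect_error(detect_errors_dictionary(note, character()),
               class = "noteqc_config_error")
})

test_that("dictionary corrector splits merges and fixes unique near-misses", {
  merged <- list(note_id = "n", text = "feeling unwell.Resident wanted toast")
  expect_equal(correct_note_dictionary(merged, dict),
               "feeling unwell. Resident wanted toast")

  clean <- list(note_id = "n", text = "resident ate breakfast")
  expect_identical(correct_note_dictionary(clean, dict), clean$text)

  typo <- list(note_id = "n", text = "resident was unwel overnight")
  expect_equal(correct_note_dictionary(typo, c(dict, "was")),
               "resident was unwell overnight")

  # two equally-near candidates: leave the token unchanged
  ambiguous <- list(note_id = "n", text = "the cat sat")
  expect_identical(
    correct_note_dictionary(ambiguous, c("the", "sat", "bat", "hat")),
    ambiguous$text)
})

test_that("llm adapter parses detect/correct completions and validates them", {
  note <- list(note_id = "n1", text = "resident ate bfast")

  det <- llm_backend(note, "detect", transport = function(prompt) "[\"bfast\"]")
  expect_equal(det$flagged_indices, 3L)
  expect_equal(det$backend_name, "llm")

  none <- llm_backend(note, "detect", transport = function(prompt) "[]")
  expect_length(none$flagged_indices, 0)

  echo <- llm_backend(note, "correct", transport = function(prompt) note$text)
  expect_identical(echo, note$text)

  expect_error(
    llm_backend(note, "detect",
                transport = function(prompt) "[\"hallucinated\"]"),
    class = "noteqc_backend_response_error")
  expect_error(
    llm_backend(note, "detect", transport = function(prompt) "not json {"),
    class = "noteqc_backend_response_error")
  expect_error(
    llm_backend(note, "detect", transport = function(prompt) stop("boom")),
    class = "noteqc_transport_error")
})

test_that("detection evaluation aggregates rate deviation and mismatches", {
  corpus <- note_corpus(tibble::tibble(
    note_id = c("n1", "n2"), subject_id = "s",
    text = c(paste(rep("w", 20), collapse = " "),
             paste(rep("w", 10), collapse = " "))))
  truth <- tibble::tibble(note_id = c("n1", "n2"), token_index = c(3L, 4L))

  perfect <- evaluate_detection(truth, truth, corpus)
  expect_equal(perfect$mean_abs_rate_deviation, 0)
  expect_equal(perfect$pct_notes_exact, 1)

  # one extra flag on the 20-token note: 5 percentage points, off by one
  det <- tibble::tibble(note_id = c("n1", "n1", "n2"),
                        token_index = c(3L, 7L, 4L))
  ev <- evaluate_detection(det, truth, corpus)
  expect_equal(ev$mean_abs_rate_deviation, 2.5) # mean of 5pp and 0pp
  expect_equal(ev$mean_token_mismatch, 0.5)
  expect_equal(ev$pct_notes_exact, 0.5)
  expect_equal(ev$pct_notes_off_by_one, 0.5)

  # symmetric in detector and truth
  ev_sw <- evaluate_detection(truth, det, corpus)
  expect_equal(ev_sw$mean_abs_rate_deviation, ev$mean_abs_rate_deviation)

  expect_error(
    evaluate_detection(tibble::tibble(note_id = "ghost", token_index = 1L),
                       truth, corpus),
    class = "noteqc_alignment_error")
})

test_that("correction evaluation scores residual errors by token alignment", {
  reference <- c("resident ate breakfast then rested quietly today ok fine",
                 "pain was stable overnight and reviewed by staff twice")
  corrupted <- c("resident ate bfast then rsted quietly today ok fine",
                 "pain was stble overnight and reviewed by staff twice")
  half_fixed <- c("resident ate breakfast then rsted quietly today ok fine",
                  "pain was stble overnight and reviewed by staff twice")

  perfect <- evaluate_correction(reference, corrupted, reference)
  expect_equal(perfect$residual_error_rate, 0)
  expect_equal(perfect$pct_errors_corrected, 1)

  identity <- evaluate_correction(corrupted, corrupted, reference)
  expect_equal(identity$pct_errors_corrected, 0)
  expect_equal(identity$residual_error_rate, identity$baseline_error_rate)

  # 1 of 3 corrupted tokens fixed: residual 2/3 of baseline
  partial <- evaluate_correction(half_fixed, corrupted, reference)
  expect_equal(partial$pct_errors_corrected, 1 / 3, tolerance = 1e-12)

  expect_error(evaluate_correction(reference, reference, reference),
               class = "noteqc_undefined_rate_error")
})

test_that("corrector never hurts collision-free corpora", {
  bundle <- small_bundle()
  pair <- generate_ground_truth_pair(
    synthetic_config(n_subjects = 25, vocab_background = 120,
                     vocab_signal = 10, note_length_mean = 25,
                     note_length_sd = 5, seed = 17L),
    target_rate = 0.12)
  corrected <- vapply(seq_len(nrow(pair$corrupted)), function(i) {
    correct_note_dictionary(pair$corrupted[i, ], pair$bundle$dictionary)
  }, character(1))
  ev <- evaluate_correction(corrected, pair$corrupted$text,
                            pair$bundle$corpus$text)
  expect_lte(ev$residual_error_rate, ev$baseline_error_rate)
  expect_gt(ev$pct_errors_corrected, 0.5)
})
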