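#' Synthetic corpus configuration
#'
#' Describes the note generator: cohort size, binary outcome prevalence
#' (default 0.118, matching an ICU mortality cohort), vocabulary sizes,
#' class-conditional inclusion probabilities for the signal words, the
#' note-length distribution and the punctuation rate. The generator draws
#' bag-of-words notes -- deliberately without grammar, since the downstream
#' representations (TF-IDF, mean-pooled embeddings) are order-insensitive.
#'
#' @param n_subjects Number of subjects.
#' @param notes_per_subject Integer range `c(lo, hi)`: notes drawn uniformly
#'   per subject (default `c(1, 1)`, one concatenated window per subject).
#' @param prevalence Positive-class probability (default 0.118).
#' @param vocab_background Number of background pseudo-words (default 600).
#' @param vocab_signal Number of class-informative words (default 20).
#' @param signal_prob_case,signal_prob_control Per-note inclusion
#'   probability of each signal word for cases/controls (defaults 0.6/0.2).
#' @param note_length_mean,note_length_sd Token-count distribution (normal,
#'   rounded, floored at `note_length_min`); defaults 60/20. The `"long"`
#'   preset uses mean 2000 for stress tests.
#' @param note_length_min Minimum tokens per note (default 5).
#' @param punctuation_rate Fraction of tokens given a trailing `.` or `,`
#'   (default 0.15).
#' @param seed Integer seed.
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 1000,
                             notes_per_subject = c(1, 1),
                             prevalence = 0.118,
                             vocab_background = 600,
                             vocab_signal = 20,
                             signal_prob_case = 0.6,
                             signal_prob_control = 0.2,
                             note_length_mean = 60,
                             note_length_sd = 20,
                             note_length_min = 5,
                             punctuation_rate = 0.15,
                             seed = 1L) {
  stopifnot(prevalence > 0, prevalence < 1,
            note_length_min >= 5,
            punctuation_rate >= 0, punctuation_rate <= 1,
            length(notes_per_subject) == 2,
            notes_per_subject[1] >= 1,
            notes_per_subject[2] >= notes_per_subject[1])
  structure(
    list(n_subjects = as.integer(n_subjects),
         notes_per_subject = as.integer(notes_per_subject),
         prevalence = prevalence,
         vocab_background = as.integer(vocab_background),
         vocab_signal = as.integer(vocab_signal),
         signal_prob_case = signal_prob_case,
         signal_prob_control = signal_prob_control,
         note_length_mean = note_length_mean,
         note_length_sd = note_length_sd,
         note_length_min = as.integer(note_length_min),
         punctuation_rate = punctuation_rate,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Preset synthetic configurations
#'
#' `"reference"` is the corpus used throughout the benchmark tests:
#' n=1000 subjects, prevalence 0.118, 20 signal words at 0.6/0.2
#' case/control inclusion. `"null"` sets the two inclusion probabilities
#' equal (no signal; calibration checks). `"long"` uses ~2000-token notes
#' for stress tests.
#'
#' @param preset `"reference"`, `"null"` or `"long"`.
#' @param seed Integer seed.
#' @param ... Overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
synthetic_preset <- function(preset = c("reference", "null", "long"),
                             seed = 1L, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    reference = list(),
    null = list(signal_prob_case = 0.4, signal_prob_control = 0.4),
    long = list(note_length_mean = 2000, note_length_sd = 400)
  )
  do.call(synthetic_config, c(args, list(seed = seed), list(...)))
}

# A fixed clinical-register seed list; the rest of the vocabulary is
# pronounceable CV-syllable pseudo-words.
clinical_seed_words <- function() {
  c("resident", "assisted", "pain", "staff", "shower", "breakfast",
    "mobility", "transfer", "medication", "continent", "overnight",
    "settled", "wandering", "appetite", "toilet", "family", "review",
    "dressing", "wound", "observations")
}

cv_syllables <- function() {
  consonants <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s",
                  "t", "v", "z")
  vowels <- c("a", "e", "i", "o", "u")
  as.vector(outer(consonants, vowels, paste0))
}

# TRUE if word can be split into two words both in `vocab` -- used to keep
# whitespace-merge fusions out of the dictionary.
is_concatenation <- function(word, vocab) {
  n <- nchar(word)
  for (cut in 3:(n - 3)) {
    if (cut < 3 || n - cut < 3) next
    if (substr(word, 1, cut) %in% vocab &&
        substring(word, cut + 1) %in% vocab) {
      return(TRUE)
    }
  }
  FALSE
}

#' Generate a collision-free vocabulary
#'
#' Builds `n_background` pronounceable pseudo-words plus `n_signal`
#' class-informative words (drawn from a fixed clinical-register list,
#' extended with pseudo-words if more are requested). All words are unique,
#' lowercase, length >= 3, pairwise Levenshtein distance >= 3, and no word
#' is the concatenation of two others. The distance floor guarantees that a
#' single-edit misspelling is out-of-dictionary *and* has a unique
#' dictionary word within edit distance 1 (its original), so dictionary
#' detection and correction are exactly recoverable.
#'
#' @param n_background,n_signal Word counts.
#' @param seed Integer seed.
#' @param min_distance Pairwise edit-distance floor (default 3).
#' @param max_attempts Sampling budget before a capacity error.
#' @return List with `background` and `signal` character vectors.
#' @export
generate_vocabulary <- function(n_background, n_signal, seed = 1L,
                                min_distance = 3, max_attempts = 200000) {
  stopifnot(n_background >= 1, n_signal >= 1)
  syll <- cv_syllables()
  withr::with_seed(as.integer(seed), {
    accepted <- character()
    admit <- function(word) {
      if (word %in% accepted) return(FALSE)
      if (length(accepted) > 0 &&
          min(adist(word, accepted)) < min_distance) {
        return(FALSE)
      }
      if (length(accepted) > 0 && nchar(word) >= 6 &&
          is_concatenation(word, accepted)) {
        return(FALSE)
      }
      TRUE
    }
    seeds <- clinical_seed_words()
    signal <- character()
    for (w in seeds) {
      if (length(signal) >= n_signal) break
      if (admit(w)) {
        accepted <- c(accepted, w)
        signal <- c(signal, w)
      }
    }
    need <- n_background + (n_signal - length(signal))
    attempts <- 0L
    while (need > 0 && attempts < max_attempts) {
      attempts <- attempts + 1L
      word <- paste(syll[sample.int(length(syll),
                                    sample(2:4, 1), replace = TRUE)],
                    collapse = "")
      if (admit(word)) {
        accepted <- c(accepted, word)
        if (length(signal) < n_signal) signal <- c(signal, word)
        need <- need - 1L
      }
    }
    if (need > 0) {
      abort(sprintf(
        "could not build %d words at pairwise distance >= %d (got %d)",
        n_background + n_signal, min_distance, length(accepted)),
        class = "noteqc_capacity_error")
    }
    background <- setdiff(accepted, signal)
    list(background = background, signal = signal)
  })
}

#' Generate a synthetic clinical-note corpus
#'
#' Draws subject labels Bernoulli(prevalence), then per note: a token count
#' from the length distribution; each signal word included once with its
#' class-conditional probability; background words (uniform) filling the
#' remaining slots; token order shuffled; a `punctuation_rate` fraction of
#' tokens given a trailing `.` or `,`. Every token's punctuation-stripped
#' lowercase form is in the returned dictionary.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_bundle`: list with `corpus` ([note_corpus()]),
#'   `labels` (named 0/1 vector), `dictionary` (clean vocabulary),
#'   `signal_words`, `generation_log` (per-note realized composition).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  vocab <- generate_vocabulary(config$vocab_background, config$vocab_signal,
                               seed = derive_seed(config$seed, "vocab"))
  withr::with_seed(derive_seed(config$seed, "corpus"), {
    labels <- rbinom(config$n_subjects, 1L, config$prevalence)
    subject_ids <- sprintf("s%04d", seq_len(config$n_subjects))
    names(labels) <- subject_ids
    rows <- list()
    log_rows <- list()
    for (s in seq_len(config$n_subjects)) {
      p_sig <- if (labels[s] == 1L) config$signal_prob_case else
        config$signal_prob_control
      n_notes <- sample(config$notes_per_subject[1]:config$notes_per_subject[2], 1L)
      for (k in seq_len(n_notes)) {
        len <- max(config$note_length_min,
                   as.integer(round(rnorm(1, config$note_length_mean,
                                          config$note_length_sd))))
        sig <- vocab$signal[runif(length(vocab$signal)) < p_sig]
        if (length(sig) > len) sig <- sig[seq_len(len)]
        n_bg <- len - length(sig)
        bg <- vocab$background[sample.int(length(vocab$background), n_bg,
                                          replace = TRUE)]
        tokens <- c(sig, bg)
        tokens <- tokens[sample.int(length(tokens))]
        punct <- runif(length(tokens)) < config$punctuation_rate
        tokens[punct] <- paste0(tokens[punct],
                                sample(c(".", ","), sum(punct),
                                       replace = TRUE))
        note_id <- sprintf("%s_n%02d", subject_ids[s], k)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          note_id = note_id, subject_id = subject_ids[s],
          text = paste(tokens, collapse = " "), order_key = k)
        log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
          note_id = note_id, n_tokens = length(tokens),
          n_signal = length(sig), label = labels[s])
      }
    }
    corpus <- note_corpus(dplyr::bind_rows(rows),
                          metadata = list(source = "noteqc synthetic",
                                          seed = config$seed))
    structure(
      list(corpus = corpus, labels = labels,
           dictionary = c(vocab$background, vocab$signal),
           signal_words = vocab$signal,
           generation_log = dplyr::bind_rows(log_rows),
           config = config),
      class = "synthetic_bundle"
    )
  })
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(
    "<synthetic_bundle> %d notes / %d subjects, prevalence %.3f, %d dictionary words\n",
    nrow(x$corpus), length(x$labels), mean(x$labels), length(x$dictionary)))
  invisible(x)
}

#' Generate an aligned clean/corrupted ground-truth pair
#'
#' Generates a clean corpus and corrupts it with the bundle's own dictionary
#' as the forbidden set, so every injected misspelling is out-of-dictionary
#' (collision-free). This is the synthetic analogue of a manually corrected
#' audit sample: an aligned (clean, corrupted, annotations) triple for
#' evaluating detectors and correctors.
#'
#' @param config A [synthetic_config()].
#' @param target_rate Corruption rate (default 0.075, a realistic observed
#'   error level).
#' @param type_split,misspell_fraction,punctuation_weight Passed to
#'   [corrupt_corpus()].
#' @return List with `bundle` (clean `synthetic_bundle`), `corrupted`
#'   ([note_corpus()]) and `annotations`.
#' @export
generate_ground_truth_pair <- function(config, target_rate = 0.075,
                                       type_split = "random",
                                       misspell_fraction = NULL,
                                       punctuation_weight = 1.5) {
  bundle <- generate_corpus(config)
  version <- corrupt_corpus(
    bundle$corpus, rates = target_rate,
    base_seed = derive_seed(config$seed, "corruption"),
    forbidden = bundle$dictionary,
    type_split = type_split, misspell_fraction = misspell_fraction,
    punctuation_weight = punctuation_weight,
    min_tokens = config$note_length_min)[[1]]
  list(bundle = bundle, corrupted = version$corpus,
       annotations = version$annotations)
}
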