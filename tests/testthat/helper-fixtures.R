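# Shared fixtures, built in code at test time.

tiny_corpus <- function() {
  note_corpus(tibble::tibble(
    note_id = c("a", "b", "c"),
    subject_id = c("s1", "s1", "s2"),
    text = c("pt stable", "pt improving", "Resident settled overnight, no pain."),
    order_key = c(1, 2, 1)
  ), metadata = list(source = "fixture"))
}

# Small synthetic bundle cached per session: generation is seeded, so every
# test sees the same corpus.
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_corpus(synthetic_config(
        n_subjects = 60, vocab_background = 120, vocab_signal = 10,
        note_length_mean = 30, note_length_sd = 8, seed = 301L))
    }
    cache
  }
})

n_ws_tokens <- function(texts) {
  vapply(texts, function(s) nrow(whitespace_tokenize(s)), integer(1),
         USE.NAMES = FALSE)
}
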