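# Shared internal helpers: deterministic seed derivation, punctuation
# normalisation, and token-sequence alignment.

# Deterministic 31-bit hash of a character key, folded with an integer seed.
# Used to give every (seed, rate, note_id) combination its own RNG stream so
# corpus corruption is reproducible note-by-note. Arithmetic stays below 2^53
# so doubles are exact; result is in [0, 2^31 - 2].
derive_seed <- function(base_seed, ...) {
  mod <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(base_seed) %% mod
  for (part in list(...)) {
    key <- as.character(part)
    for (cp in utf8ToInt(paste(key, collapse = "\037"))) {
      h <- (h * 31 + cp) %% mod
    }
    h <- (h * 31 + 7) %% mod
  }
  as.integer(h)
}

# Strip leading/trailing non-alphanumeric characters and lowercase: the
# normal form used when a token is looked up in a dictionary or compared
# across clean/corrupted/corrected versions (the error metric disregards
# punctuation).
normalize_token <- function(tokens) {
  tolower(gsub("^[^[:alnum:]]+|[^[:alnum:]]+$", "", tokens))
}

has_punctuation_chr <- function(tokens) {
  grepl("[^[:alnum:][:space:]]", tokens)
}

# Minimal-edit alignment of two token sequences (unit substitution/indel
# costs). Returns the number of reference tokens that are not matched
# exactly under an optimal alignment -- the erroneous-token count used when
# re-scoring corrected text against a clean reference.
count_unmatched_reference_tokens <- function(reference, hypothesis) {
  n <- length(reference)
  m <- length(hypothesis)
  if (n == 0L) return(0L)
  if (m == 0L) return(n)
  # dp over (n+1) x (m+1); keep full matrix for traceback
  dp <- matrix(0L, n + 1L, m + 1L)
  dp[, 1L] <- 0:n
  dp[1L, ] <- 0:m
  for (i in seq_len(n)) {
    ref_i <- reference[i]
    sub_cost <- ifelse(hypothesis == ref_i, 0L, 1L)
    for (j in seq_len(m)) {
      dp[i + 1L, j + 1L] <- min(
        dp[i, j] + sub_cost[j],
        dp[i, j + 1L] + 1L,
        dp[i + 1L, j] + 1L
      )
    }
  }
  # traceback: count reference tokens aligned to a different token or deleted
  i <- n; j <- m; bad <- 0L
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        dp[i + 1L, j + 1L] == dp[i, j] + (reference[i] != hypothesis[j])) {
      if (reference[i] != hypothesis[j]) bad <- bad + 1L
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && dp[i + 1L, j + 1L] == dp[i, j + 1L] + 1L) {
      bad <- bad + 1L # reference token deleted
      i <- i - 1L
    } else {
      j <- j - 1L # insertion in hypothesis
    }
  }
  bad
}

# Population standard deviation (divisor n), the estimator used in all
# corpus-level reports so replications are bit-stable.
pop_sd <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  mu <- mean(x)
  sqrt(sum((x - mu)^2) / n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
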