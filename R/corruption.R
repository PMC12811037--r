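#' Corruption configuration
#'
#' Describes how errors are injected into a note: the target token-level
#' error rate, how the budget is split between misspellings and
#' whitespace merges, how strongly punctuation-bearing merge sites are
#' favoured, and the seed. The number of tokens to corrupt is
#' `round(target_rate * n_tokens)` (round-half-to-even), computed on the
#' note's original whitespace-token total.
#'
#' @param target_rate Target fraction of erroneous tokens, in \[0, 1\].
#' @param type_split `"random"` (misspelling count drawn uniformly from
#'   `0..k_total`) or `"fixed"` (use `misspell_fraction`).
#' @param misspell_fraction With `type_split = "fixed"`: fraction of the
#'   error budget allocated to misspellings (e.g. 0.4 gives the 4%/6% split
#'   at a 10% rate).
#' @param punctuation_weight Sampling-weight multiplier for merge sites where
#'   either adjacent token carries punctuation (default 1.5, i.e. 50% more
#'   likely than a plain site).
#' @param min_tokens Notes with fewer whitespace tokens pass through
#'   uncorrupted (default 5).
#' @param seed Integer seed recorded in provenance and used by
#'   [corrupt_corpus()] to derive per-note streams.
#' @return A `corruption_config`.
#' @export
corruption_config <- function(target_rate,
                              type_split = c("random", "fixed"),
                              misspell_fraction = NULL,
                              punctuation_weight = 1.5,
                              min_tokens = 5,
                              seed = 1L) {
  type_split <- match.arg(type_split)
  stopifnot(target_rate >= 0, target_rate <= 1, punctuation_weight > 0)
  if (type_split == "fixed") {
    if (is.null(misspell_fraction) ||
        misspell_fraction < 0 || misspell_fraction > 1) {
      abort("fixed type_split requires misspell_fraction in [0, 1]",
            class = "noteqc_config_error")
    }
  }
  structure(
    list(target_rate = target_rate, type_split = type_split,
         misspell_fraction = misspell_fraction,
         punctuation_weight = punctuation_weight,
         min_tokens = min_tokens, seed = as.integer(seed)),
    class = "corruption_config"
  )
}

# Misspelling requires a purely alphabetic token of length >= 3 so a single
# character edit is well defined and never degenerate.
misspellable <- function(tokens) {
  grepl("^[A-Za-z]{3,}$", tokens)
}

#' Plan the corruption of one note
#'
#' Allocates the error budget `k_total = round(target_rate * n)` between the
#' two error types and samples the token indices to corrupt. Merge sites
#' (token i fused with token i+1) are sampled without replacement, weighting
#' a site by `punctuation_weight` when either adjacent token carries
#' punctuation and 1 otherwise. Misspelling targets are then sampled
#' uniformly from the remaining eligible tokens (alphabetic, length >= 3, not
#' adjacent to a chosen merge site), keeping the two index sets disjoint and
#' the annotations unambiguous.
#'
#' @param tokens Tokenization of the clean note from [whitespace_tokenize()].
#' @param config A [corruption_config()].
#' @return A `corruption_plan`: list with `n_tokens`, `k_total`,
#'   `k_misspell`, `k_merge`, `misspell_idx`, `merge_idx` (merge index i
#'   fuses tokens i and i+1).
#' @export
plan_corruption <- function(tokens, config) {
  stopifnot(inherits(config, "corruption_config"))
  n <- nrow(tokens)
  if (n < config$min_tokens) {
    abort(sprintf("note has %d tokens, below min_tokens = %d", n,
                  config$min_tokens),
          class = "noteqc_capacity_error")
  }
  k_total <- round(config$target_rate * n)
  if (k_total == 0) {
    return(structure(list(n_tokens = n, k_total = 0L, k_misspell = 0L,
                          k_merge = 0L, misspell_idx = integer(),
                          merge_idx = integer()),
                     class = "corruption_plan"))
  }
  k_misspell <- switch(config$type_split,
    random = sample(0:k_total, 1L),
    fixed = as.integer(round(config$misspell_fraction * k_total))
  )
  k_merge <- k_total - k_misspell

  # merge sites: i in 1..n-1, fusing token i with i+1
  merge_sites <- seq_len(n - 1L)
  site_weight <- ifelse(tokens$has_punctuation[merge_sites] |
                          tokens$has_punctuation[merge_sites + 1L],
                        config$punctuation_weight, 1.0)
  merge_idx <- integer()
  if (k_merge > 0) {
    if (length(merge_sites) < k_merge) {
      abort(sprintf("cannot place %d merges in a %d-token note (achievable: %d)",
                    k_merge, n, length(merge_sites)),
            class = "noteqc_capacity_error")
    }
    merge_idx <- sort(merge_sites[sample.int(length(merge_sites), k_merge,
                                             prob = site_weight)])
  }

  blocked <- unique(c(merge_idx, merge_idx + 1L))
  eligible <- setdiff(which(misspellable(tokens$token)), blocked)
  if (k_misspell > length(eligible)) {
    abort(sprintf(
      "only %d tokens eligible for misspelling, %d requested (achievable k_total: %d)",
      length(eligible), k_misspell, length(eligible) + k_merge),
      class = "noteqc_capacity_error")
  }
  misspell_idx <- sort(eligible[sample.int(length(eligible), k_misspell)])
  structure(
    list(n_tokens = n, k_total = as.integer(k_total),
         k_misspell = as.integer(k_misspell), k_merge = as.integer(k_merge),
         misspell_idx = as.integer(misspell_idx),
         merge_idx = as.integer(merge_idx)),
    class = "corruption_plan"
  )
}

#' Misspell a single token by one seeded character edit
#'
#' Applies one random edit -- substitute, delete, insert or transpose at a
#' random position -- producing a variant that differs from the original and
#' is outside `forbidden` (typically the corpus dictionary, so injected
#' misspellings are guaranteed out-of-dictionary). A candidate is also
#' rejected when some *other* forbidden word is at least as close to it
#' (by Levenshtein distance) as the original: a misspelling must still
#' resemble its own source word more than any dictionary word, which is
#' what keeps collision-free corruption uniquely correctable. The case of
#' the first character is preserved. Retries with fresh edits up to
#' `max_attempts`.
#'
#' @param token Alphabetic token, nchar >= 3.
#' @param forbidden Character vector of words the output must avoid
#'   (compared case-insensitively); the original is always avoided.
#' @param max_attempts Retry budget (default 25).
#' @return The corrupted token.
#' @export
misspell_token <- function(token, forbidden = character(), max_attempts = 25) {
  if (!grepl("^[A-Za-z]{3,}$", token)) {
    abort("misspell_token requires an alphabetic token of length >= 3",
          class = "noteqc_generation_error")
  }
  forbidden_lc <- tolower(forbidden)
  first_upper <- grepl("^[A-Z]", token)
  base <- tolower(token)
  for (attempt in seq_len(max_attempts)) {
    chars <- strsplit(base, "", fixed = TRUE)[[1]]
    L <- length(chars)
    op <- sample(c("substitute", "delete", "insert", "transpose"), 1L)
    out <- switch(op,
      substitute = {
        i <- sample(L, 1L)
        chars[i] <- sample(setdiff(letters, chars[i]), 1L)
        paste(chars, collapse = "")
      },
      delete = {
        i <- sample(L, 1L)
        paste(chars[-i], collapse = "")
      },
      insert = {
        i <- sample(L + 1L, 1L)
        paste(c(chars[seq_len(i - 1L)], sample(letters, 1L),
                chars[seq_len(L)[seq_len(L) >= i]]), collapse = "")
      },
      transpose = {
        if (L < 2L) base else {
          i <- sample(L - 1L, 1L)
          tmp <- chars[i]; chars[i] <- chars[i + 1L]; chars[i + 1L] <- tmp
          paste(chars, collapse = "")
        }
      }
    )
    ok <- nzchar(out) && out != base && !(out %in% forbidden_lc)
    if (ok && length(forbidden_lc) > 0) {
      others <- forbidden_lc[forbidden_lc != base]
      if (length(others) > 0) {
        ok <- min(adist(out, others)) > as.integer(adist(out, base))
      }
    }
    if (ok) {
      if (first_upper) {
        substr(out, 1, 1) <- toupper(substr(out, 1, 1))
      }
      return(out)
    }
  }
  abort(sprintf("could not produce a non-forbidden misspelling of '%s' in %d attempts",
                token, max_attempts),
        class = "noteqc_generation_error")
}

#' Apply a corruption plan to a note
#'
#' Realises a [plan_corruption()] plan on the note text: misspelling indices
#' are replaced by [misspell_token()] output; each merge site deletes the
#' whitespace between tokens i and i+1 (rightward fusion). All other text,
#' including original whitespace runs, is preserved byte-for-byte. Each
#' planned error yields one annotation, so the annotation count equals
#' `k_total` exactly and the target rate holds on the original token basis.
#'
#' @param note One-row slice of a [note_corpus()] (or list with `note_id`,
#'   `text`).
#' @param plan A `corruption_plan` for this note's tokens.
#' @param forbidden Dictionary passed to [misspell_token()].
#' @return List with `text` (corrupted) and `annotations` (tibble:
#'   `note_id`, `token_index` -- index into the clean note's whitespace
#'   tokens, `error_type`, `original`, `corrupted`, and
#'   `corrupted_token_index` -- the same error located in the corrupted
#'   note's own tokenization, the basis detectors operate on).
#' @export
apply_corruption <- function(note, plan, forbidden = character()) {
  stopifnot(inherits(plan, "corruption_plan"))
  text <- note$text
  tokens <- whitespace_tokenize(text)
  if (nrow(tokens) != plan$n_tokens) {
    abort("plan does not match note tokenization",
          class = "noteqc_consistency_error")
  }
  tok_text <- tokens$token
  new_tok <- tok_text
  for (i in plan$misspell_idx) {
    new_tok[i] <- misspell_token(tok_text[i], forbidden = forbidden)
  }
  # whitespace runs between consecutive tokens (and surrounding text)
  n <- plan$n_tokens
  prefix <- substr(text, 1, tokens$start[1])
  suffix <- substring(text, tokens$end[n] + 1L)
  gaps <- if (n > 1) {
    substring(text, tokens$end[seq_len(n - 1L)] + 1L,
              tokens$start[seq_len(n - 1L) + 1L])
  } else {
    character()
  }
  gaps[plan$merge_idx] <- "" # fuse rightward
  # index of each erroneous token in the corrupted note's own whitespace
  # tokenization: every merge before position j removes one token, and all
  # tokens of a merged run collapse onto one corrupted index
  shift_index <- function(j) {
    j - sum(plan$merge_idx < j)
  }
  pieces <- character(2L * n - 1L)
  pieces[seq(1L, 2L * n - 1L, by = 2L)] <- new_tok
  if (n > 1) pieces[seq(2L, 2L * n - 2L, by = 2L)] <- gaps
  corrupted_text <- paste0(prefix, paste(pieces, collapse = ""), suffix)
  idx <- c(plan$misspell_idx, plan$merge_idx)
  annotations <- tibble::tibble(
    note_id = rep(note$note_id, length(idx)),
    token_index = idx,
    error_type = rep(c("misspelling", "whitespace_merge"),
                     c(plan$k_misspell, plan$k_merge)),
    original = tok_text[idx],
    corrupted = c(new_tok[plan$misspell_idx],
                  if (plan$k_merge > 0) {
                    paste0(new_tok[plan$merge_idx],
                           new_tok[plan$merge_idx + 1L])
                  } else {
                    character()
                  }),
    corrupted_token_index = vapply(idx, shift_index, 1) |> as.integer()
  )
  annotations <- annotations[order(annotations$token_index), ]
  list(text = corrupted_text, annotations = annotations)
}

#' Corrupt a corpus at one or more target error rates
#'
#' Produces one independently corrupted corpus version per rate. Each note
#' gets its own RNG stream derived from `(base_seed, rate, note_id)`, so any
#' version or note can be regenerated independently and byte-identically.
#' Notes shorter than the config's `min_tokens` pass through uncorrupted.
#'
#' @param corpus A [note_corpus()].
#' @param rates Numeric vector of target error rates (e.g.
#'   `c(0.05, 0.10, 0.15, 0.20)`).
#' @param base_seed Integer master seed.
#' @param forbidden Dictionary of words misspellings must avoid.
#' @param type_split,misspell_fraction,punctuation_weight,min_tokens Passed
#'   to [corruption_config()].
#' @return Named list (names = rates) of lists with elements `corpus` (the
#'   corrupted [note_corpus()], metadata recording config and seed) and
#'   `annotations` (tibble of all injected errors).
#' @export
corrupt_corpus <- function(corpus, rates, base_seed,
                           forbidden = character(),
                           type_split = "random", misspell_fraction = NULL,
                           punctuation_weight = 1.5, min_tokens = 5) {
  stopifnot(inherits(corpus, "note_corpus"))
  stopifnot(all(rates >= 0), all(rates <= 1))
  out <- lapply(rates, function(rate) {
    config <- corruption_config(rate, type_split = type_split,
                                misspell_fraction = misspell_fraction,
                                punctuation_weight = punctuation_weight,
                                min_tokens = min_tokens, seed = base_seed)
    texts <- corpus$text
    ann_all <- vector("list", nrow(corpus))
    for (i in seq_len(nrow(corpus))) {
      note <- list(note_id = corpus$note_id[i], text = corpus$text[i])
      tokens <- whitespace_tokenize(note$text)
      if (nrow(tokens) < min_tokens || rate == 0) next
      note_seed <- derive_seed(base_seed, sprintf("%.6f", rate), note$note_id)
      res <- withr::with_seed(note_seed, {
        plan <- plan_corruption(tokens, config)
        apply_corruption(note, plan, forbidden = forbidden)
      })
      texts[i] <- res$text
      ann_all[[i]] <- res$annotations
    }
    corrupted <- corpus
    corrupted$text <- texts
    meta <- corpus_metadata(corpus)
    meta$corruption <- list(target_rate = rate, type_split = type_split,
                            misspell_fraction = misspell_fraction,
                            punctuation_weight = punctuation_weight,
                            min_tokens = min_tokens, seed = base_seed)
    attr(corrupted, "metadata") <- meta
    annotations <- dplyr::bind_rows(ann_all)
    if (nrow(annotations) == 0) {
      annotations <- tibble::tibble(note_id = character(),
                                    token_index = integer(),
                                    error_type = character(),
                                    original = character(),
                                    corrupted = character(),
                                    corrupted_token_index = integer())
    }
    list(corpus = corrupted, annotations = annotations)
  })
  names(out) <- as.character(rates)
  out
}
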