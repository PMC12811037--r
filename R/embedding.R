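#' Deterministic hash embedding backend
#'
#' A static embedding backend whose token vectors are seeded pseudo-random
#' unit vectors derived from a hash of the token, stable across processes
#' and platforms. It reproduces the *geometry* that matters for robustness
#' experiments -- distinct tokens map to near-orthogonal directions, so
#' corrupted variants share no mass with their originals -- without any
#' pretrained model download. `"closed"` vocabulary mode returns no vector
#' for out-of-vocabulary tokens (word2vec-style OOV skipping); `"open"` mode
#' embeds any token (subword-style coverage).
#'
#' @param dimension Vector dimension (default 300, the classic static
#'   word-vector size).
#' @param seed Integer seed folded into every token hash.
#' @param vocabulary `NULL` for open mode, or a character vector for closed
#'   mode.
#' @return An `embedding_backend`: list with `name`, `dimension`, `mode`,
#'   and `lookup(tokens)` returning a `length(tokens) x dimension` matrix
#'   with NA rows for unmatched tokens.
#' @export
hash_embedding_backend <- function(dimension = 300, seed = 1L,
                                   vocabulary = NULL) {
  stopifnot(dimension >= 1)
  vocab_lc <- if (!is.null(vocabulary)) tolower(vocabulary)
  cache <- new.env(parent = emptyenv())
  token_vector <- function(tok) {
    v <- cache[[tok]]
    if (is.null(v)) {
      v <- withr::with_seed(derive_seed(seed, tok), rnorm(dimension))
      v <- v / sqrt(sum(v^2))
      cache[[tok]] <- v
    }
    v
  }
  lookup <- function(tokens) {
    out <- matrix(NA_real_, nrow = length(tokens), ncol = dimension)
    for (i in seq_along(tokens)) {
      tok <- tolower(tokens[i])
      if (!is.null(vocab_lc) && !(tok %in% vocab_lc)) next
      out[i, ] <- token_vector(tok)
    }
    out
  }
  structure(
    list(name = if (is.null(vocabulary)) "hash_open" else "hash_closed",
         dimension = as.integer(dimension),
         mode = "static",
         lookup = lookup),
    class = "embedding_backend"
  )
}

#' Embedding backend from an explicit token -> vector table
#'
#' Wraps a named list or matrix of pretrained vectors (e.g. word2vec
#' exports) in the backend contract. Closed-vocabulary by construction.
#'
#' @param vectors Named list of numeric vectors, or a matrix with token
#'   rownames; all the same length.
#' @param name Backend name.
#' @return An `embedding_backend`.
#' @export
table_embedding_backend <- function(vectors, name = "table") {
  if (is.matrix(vectors)) {
    vectors <- stats::setNames(
      lapply(seq_len(nrow(vectors)), function(i) vectors[i, ]),
      rownames(vectors))
  }
  dims <- unique(vapply(vectors, length, integer(1)))
  if (length(dims) != 1) {
    abort("all vectors must share one dimension",
          class = "noteqc_contract_error")
  }
  names(vectors) <- tolower(names(vectors))
  lookup <- function(tokens) {
    out <- matrix(NA_real_, nrow = length(tokens), ncol = dims)
    hit <- match(tolower(tokens), names(vectors))
    for (i in which(!is.na(hit))) out[i, ] <- vectors[[hit[i]]]
    out
  }
  structure(list(name = name, dimension = as.integer(dims), mode = "static",
                 lookup = lookup),
            class = "embedding_backend")
}

#' Mean-pooled document embedding
#'
#' Tokenizes with [feature_tokenize()], looks every token up in the backend,
#' skips unmatched tokens, and returns the arithmetic mean of the matched
#' token vectors -- the standard recipe for representing documents far longer
#' than any transformer context window. A document with no matched tokens
#' maps to the zero vector.
#'
#' @param text Document text (single string).
#' @param backend An `embedding_backend`.
#' @return Numeric vector of length `backend$dimension`.
#' @export
embed_document <- function(text, backend) {
  stopifnot(inherits(backend, "embedding_backend"))
  tokens <- feature_tokenize(text)
  if (length(tokens) == 0) return(numeric(backend$dimension))
  vecs <- backend$lookup(tokens)
  if (!is.matrix(vecs) || ncol(vecs) != backend$dimension) {
    abort("backend returned vectors of the wrong dimension",
          class = "noteqc_contract_error")
  }
  matched <- !is.na(vecs[, 1])
  if (!any(matched)) return(numeric(backend$dimension))
  colMeans(vecs[matched, , drop = FALSE])
}

#' Embed a set of documents
#'
#' @param texts Character vector of documents.
#' @param backend An `embedding_backend`.
#' @param doc_ids Optional row names.
#' @return Dense matrix (documents x dimensions) with a
#'   `representation_tag` attribute.
#' @export
embed_documents <- function(texts, backend, doc_ids = NULL) {
  out <- t(vapply(texts, embed_document, numeric(backend$dimension),
                  backend = backend, USE.NAMES = FALSE))
  rownames(out) <- doc_ids
  colnames(out) <- paste0("dim", seq_len(backend$dimension))
  attr(out, "representation_tag") <- paste0("embed_", backend$name)
  out
}
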