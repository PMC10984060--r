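# Greedy-matching embedding F-score (BERTScore-style) over pluggable
# embedding providers.  A provider supplies a tokenizer and a token
# embedder; the clinical models this emulates (SapBERT-, clinicalBERT-,
# PubMedBERT-style encoders) plug in through the same contract.

#' Construct an embedding provider
#'
#' The contract behind the greedy-matching score: a deterministic
#' `tokenize(text)` and an `embed(tokens)` returning one fixed-dimension
#' numeric row per token.
#'
#' @param tokenize Function: text -> character vector of tokens.
#' @param embed Function: character vector of tokens -> numeric matrix with
#'   one row per token.
#' @param id Backend identifier recorded in metric rows.
#' @param dim Embedding dimension (checked against `embed` output).
#' @return An `embedding_provider` list.
#' @export
embedding_provider <- function(tokenize, embed, id, dim) {
  stopifnot(is.function(tokenize), is.function(embed),
            is.character(id), is_scalar_number(dim))
  structure(list(tokenize = tokenize, embed = embed, id = id, dim = dim),
            class = "embedding_provider")
}

#' One-hot embedding provider over a fixed vocabulary
#'
#' Each vocabulary token gets its own indicator dimension;
#' out-of-vocabulary tokens embed to the zero vector.  With this provider
#' the greedy-matching score reduces exactly to type-level token overlap,
#' which makes it the reference backend for testing.
#'
#' @param vocab Character vector of known tokens.
#' @param tokenizer Tokenizer used by the provider.
#' @return An [embedding_provider()].
#' @export
onehot_provider <- function(vocab, tokenizer = tokenize) {
  vocab <- unique(as.character(vocab))
  if (length(vocab) == 0) stop("vocab must be non-empty")
  embed <- function(tokens) {
    m <- matrix(0, nrow = length(tokens), ncol = length(vocab))
    idx <- match(tokens, vocab)
    hit <- which(!is.na(idx))
    m[cbind(hit, idx[hit])] <- 1
    m
  }
  embedding_provider(tokenizer, embed, paste0("onehot-", length(vocab)),
                     length(vocab))
}

#' Hashed random-projection embedding provider
#'
#' Deterministic toy stand-in for a learned encoder: each token type is
#' mapped to a unit-norm Gaussian vector seeded from a hash of the token,
#' so identical tokens always agree, distinct tokens are near-orthogonal
#' in expectation, and the provider is reproducible across sessions.
#'
#' @param dim Embedding dimension.
#' @param seed Base seed mixed into every token hash.
#' @param tokenizer Tokenizer used by the provider.
#' @return An [embedding_provider()].
#' @export
hash_embedding_provider <- function(dim = 32, seed = 0, tokenizer = tokenize) {
  stopifnot(is_scalar_number(dim), dim >= 2)
  cache <- new.env(parent = emptyenv())
  embed_one <- function(token) {
    if (!exists(token, envir = cache, inherits = FALSE)) {
      v <- with_seed(string_seed(token, offset = seed), rnorm(dim))
      assign(token, v / sqrt(sum(v^2)), envir = cache)
    }
    get(token, envir = cache, inherits = FALSE)
  }
  embed <- function(tokens) {
    if (length(tokens) == 0) return(matrix(0, 0, dim))
    do.call(rbind, lapply(tokens, embed_one))
  }
  embedding_provider(tokenizer, embed,
                     paste0("hash-embed-d", dim, "-s", seed), dim)
}

row_normalize <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nz <- nrm > 0
  m[nz, ] <- m[nz, , drop = FALSE] / nrm[nz]
  m  # zero rows stay zero: cosine against a zero vector is defined as 0
}

greedy_match_prf <- function(emb_cand, emb_ref) {
  s <- row_normalize(emb_cand) %*% t(row_normalize(emb_ref))
  p <- mean(apply(s, 1, max))
  r <- mean(apply(s, 2, max))
  list(p = p, r = r, f = f_beta1(p, r))
}

#' Greedy-matching embedding F-score
#'
#' For every candidate token, the maximum cosine similarity to any
#' reference token is averaged into precision; the symmetric average over
#' reference tokens gives recall; the value is their harmonic mean.  With
#' unit-norm embeddings individual similarities lie in `[-1, 1]`, so the
#' score can be negative for adversarial embeddings; no baseline rescaling
#' or IDF weighting is applied.
#'
#' @inheritParams rouge_l
#' @param provider An [embedding_provider()].
#' @return One-row metric tibble.
#' @examples
#' prov <- onehot_provider(c("a", "b", "c"))
#' greedy_match_fscore("a b", "a c", prov)
#' @export
greedy_match_fscore <- function(candidate, reference, provider,
                                pair_id = "pair") {
  stopifnot(inherits(provider, "embedding_provider"))
  ct <- provider$tokenize(candidate)
  rt <- provider$tokenize(reference)
  name <- "embed_greedy"
  if (length(ct) == 0L || length(rt) == 0L) {
    warning("empty token sequence in pair ", pair_id, "; reporting 0")
    return(metric_score(pair_id, name, 0, 0, 0, provider$id))
  }
  ec <- provider$embed(ct)
  er <- provider$embed(rt)
  if (!is.matrix(ec) || !is.matrix(er) || ncol(ec) != ncol(er)) {
    stop("embedding dimension mismatch for pair ", pair_id)
  }
  g <- greedy_match_prf(ec, er)
  metric_score(pair_id, name, g$f, g$p, g$r, provider$id)
}
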