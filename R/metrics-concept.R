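# Concept-identifier metrics: set F-score over extracted concept IDs
# (CUI-style) and a greedy-matching F-score over concept embeddings
# (knowledge-graph-embedding style).  Real terminology services plug in
# through the same extractor contract; a longest-match dictionary
# extractor is bundled for tests and synthetic cohorts.

#' Construct a concept extractor
#'
#' Contract: a deterministic `extract(text)` returning a set (unique
#' character vector) of concept identifiers.
#'
#' @param extract Function: text -> character vector of unique concept IDs.
#' @param id Backend identifier recorded in metric rows.
#' @return A `concept_extractor` list.
#' @export
concept_extractor <- function(extract, id) {
  stopifnot(is.function(extract), is.character(id))
  structure(list(extract = extract, id = id), class = "concept_extractor")
}

#' Longest-match dictionary concept extractor
#'
#' Scans the tokenized text left to right, consuming at each position the
#' longest n-gram present in the lexicon, and returns the set of matched
#' concept IDs.  Surfaces are matched after applying the same tokenizer as
#' the text.
#'
#' @param lexicon Data frame with columns `surface` and `cui` (one row per
#'   surface variant), e.g. from [generate_lexicon()].
#' @param tokenizer Tokenizer shared by dictionary and text.
#' @return A [concept_extractor()].
#' @export
dictionary_extractor <- function(lexicon, tokenizer = tokenize) {
  stopifnot(all(c("surface", "cui") %in% names(lexicon)))
  keys <- vapply(lexicon$surface,
                 function(s) paste(tokenizer(s), collapse = " "), character(1))
  ngram_len <- vapply(strsplit(keys, " ", fixed = TRUE), length, integer(1))
  keep <- ngram_len > 0
  dict <- setNames(as.character(lexicon$cui[keep]), keys[keep])
  max_n <- if (any(keep)) max(ngram_len[keep]) else 1L
  extract <- function(text) {
    toks <- tokenizer(text)
    found <- character(0)
    i <- 1L
    while (i <= length(toks)) {
      hit_len <- 0L
      for (n in seq(min(max_n, length(toks) - i + 1L), 1L)) {
        key <- paste(toks[i:(i + n - 1L)], collapse = " ")
        if (!is.na(dict[key])) {
          found <- c(found, unname(dict[key]))
          hit_len <- n
          break
        }
      }
      i <- i + max(hit_len, 1L)
    }
    unique(found)
  }
  concept_extractor(extract, paste0("dict-", sum(keep)))
}

#' Concept-identifier F-score
#'
#' Set precision, recall and F over the concept IDs extracted from
#' candidate and reference.  Depends only on the extracted sets, so it is
#' invariant to token order and duplication.  Undefined ratios (an empty
#' set on either side) are reported as 0 with a warning.
#'
#' @inheritParams rouge_l
#' @param extractor A [concept_extractor()].
#' @return One-row metric tibble.
#' @export
concept_fscore <- function(candidate, reference, extractor, pair_id = "pair") {
  stopifnot(inherits(extractor, "concept_extractor"))
  cs <- extractor$extract(candidate)
  rs <- extractor$extract(reference)
  name <- "concept_f"
  if (length(cs) == 0L || length(rs) == 0L) {
    warning("empty concept set in pair ", pair_id, "; reporting 0")
    return(metric_score(pair_id, name, 0, 0, 0, extractor$id))
  }
  inter <- length(intersect(cs, rs))
  p <- inter / length(cs)
  r <- inter / length(rs)
  metric_score(pair_id, name, f_beta1(p, r), p, r, extractor$id)
}

#' One-hot concept embedder over a fixed concept universe
#'
#' @param universe Character vector of concept IDs.
#' @return Function: concept IDs -> indicator matrix (unknown IDs embed to
#'   zero rows).
#' @export
onehot_concept_embedder <- function(universe) {
  universe <- unique(as.character(universe))
  function(ids) {
    m <- matrix(0, nrow = length(ids), ncol = length(universe))
    idx <- match(ids, universe)
    hit <- which(!is.na(idx))
    m[cbind(hit, idx[hit])] <- 1
    m
  }
}

#' Hashed concept embedder
#'
#' Deterministic unit-norm Gaussian vector per concept ID, mirroring
#' [hash_embedding_provider()] at the concept level; a toy stand-in for
#' knowledge-graph embeddings.
#'
#' @param dim Embedding dimension.
#' @param seed Base seed mixed into the per-ID hash.
#' @return Function: concept IDs -> numeric matrix.
#' @export
hash_concept_embedder <- function(dim = 32, seed = 0) {
  cache <- new.env(parent = emptyenv())
  function(ids) {
    if (length(ids) == 0) return(matrix(0, 0, dim))
    do.call(rbind, lapply(ids, function(id) {
      if (!exists(id, envir = cache, inherits = FALSE)) {
        v <- with_seed(string_seed(id, offset = seed), rnorm(dim))
        assign(id, v / sqrt(sum(v^2)), envir = cache)
      }
      get(id, envir = cache, inherits = FALSE)
    }))
  }
}

#' Greedy-matching F-score over concept embeddings
#'
#' Extracts concept IDs from both sides, embeds them, and applies the same
#' greedy maximum-cosine matching as [greedy_match_fscore()], but over
#' concepts instead of tokens.  Concepts without an embedding back off to
#' the zero vector (cosine 0) with a warning.
#'
#' @inheritParams concept_fscore
#' @param concept_embedder Function: character vector of concept IDs ->
#'   numeric matrix with one row per ID.
#' @return One-row metric tibble.
#' @export
graph_embedding_fscore <- function(candidate, reference, extractor,
                                   concept_embedder, pair_id = "pair") {
  stopifnot(inherits(extractor, "concept_extractor"),
            is.function(concept_embedder))
  cs <- sort(extractor$extract(candidate))
  rs <- sort(extractor$extract(reference))
  name <- "graph_embed_f"
  backend <- paste0(extractor$id, "+graph")
  if (length(cs) == 0L || length(rs) == 0L) {
    warning("empty concept set in pair ", pair_id, "; reporting 0")
    return(metric_score(pair_id, name, 0, 0, 0, backend))
  }
  ec <- concept_embedder(cs)
  er <- concept_embedder(rs)
  if (!is.matrix(ec) || !is.matrix(er) || ncol(ec) != ncol(er)) {
    stop("concept embedding dimension mismatch for pair ", pair_id)
  }
  if (any(rowSums(abs(ec)) == 0) || any(rowSums(abs(er)) == 0)) {
    warning("concept(s) without embedding in pair ", pair_id,
            "; backing off to zero vectors")
  }
  g <- greedy_match_prf(ec, er)
  metric_score(pair_id, name, g$f, g$p, g$r, backend)
}
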