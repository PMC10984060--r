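# Longest-common-subsequence overlap metric (ROUGE-L dialect: single
# sequence LCS, beta = 1; candidate and reference are short diagnosis
# strings, so no summary-level union-LCS is used).

metric_score <- function(pair_id, metric_name, value,
                         precision = NA_real_, recall = NA_real_,
                         backend_id = NA_character_) {
  tibble::tibble(
    pair_id = as.character(pair_id), metric_name = metric_name,
    precision = precision, recall = recall, value = value,
    backend_id = backend_id
  )
}

f_beta1 <- function(p, r) {
  if (is.na(p) || is.na(r) || p + r == 0) 0 else 2 * p * r / (p + r)
}

#' Length of the longest common subsequence
#'
#' Classic dynamic program over two token vectors.  Symmetric, and never
#' larger than the shorter input.
#'
#' @param a,b Character (or atomic) vectors of tokens.
#' @return Integer LCS length.
#' @examples
#' lcs_length(c("a", "b", "c", "d"), c("a", "c", "e"))
#' @export
lcs_length <- function(a, b) {
  n <- length(a)
  m <- length(b)
  if (n == 0L || m == 0L) return(0L)
  prev <- integer(m + 1L)
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    match_i <- a[i] == b
    for (j in seq_len(m)) {
      cur[j + 1L] <- if (match_i[j]) prev[j] + 1L else max(cur[j], prev[j + 1L])
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' ROUGE-L: longest-common-subsequence F-score
#'
#' Precision is the LCS length over the candidate token count, recall the
#' LCS length over the reference token count, and the value their harmonic
#' mean (beta = 1).  When either side has no tokens the undefined ratio is
#' reported as 0 with a warning.
#'
#' @param candidate,reference Character scalars to compare.
#' @param pair_id Identifier carried into the result row.
#' @param tokenizer Function mapping text to a token vector.
#' @return One-row metric tibble: `pair_id`, `metric_name`, `precision`,
#'   `recall`, `value`, `backend_id`.
#' @examples
#' rouge_l("a b c d", "a c e")
#' @export
rouge_l <- function(candidate, reference, pair_id = "pair", tokenizer = tokenize) {
  ct <- tokenizer(candidate)
  rt <- tokenizer(reference)
  if (length(ct) == 0L || length(rt) == 0L) {
    warning("empty token sequence in pair ", pair_id, "; reporting 0")
    return(metric_score(pair_id, "rouge_l", 0, 0, 0, "lcs"))
  }
  l <- lcs_length(ct, rt)
  p <- l / length(ct)
  r <- l / length(rt)
  metric_score(pair_id, "rouge_l", f_beta1(p, r), p, r, "lcs")
}
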