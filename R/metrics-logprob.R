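# Conditional log-probability metric (BARTScore-style): the sum of token
# log-probabilities of the candidate given the reference under a sequence
# model.  Real encoder-decoder models plug in through the scorer contract;
# a bigram model estimated from the reference and a uniform model are
# bundled for tests.

#' Construct a conditional scorer
#'
#' Contract: a deterministic `logprob(candidate, reference)` returning the
#' summed token log-probability of the candidate conditioned on the
#' reference (non-positive for proper models).
#'
#' @param logprob Function `(candidate, reference) -> numeric scalar`.
#' @param id Backend identifier recorded in metric rows.
#' @return A `conditional_scorer` list.
#' @export
conditional_scorer <- function(logprob, id) {
  stopifnot(is.function(logprob), is.character(id))
  structure(list(logprob = logprob, id = id), class = "conditional_scorer")
}

#' Bigram conditional scorer
#'
#' Estimates an add-one-smoothed bigram model from the reference tokens at
#' call time (vocabulary = reference tokens plus an unknown symbol) and
#' sums the candidate's token log-probabilities under it, including a
#' start transition.  Among candidates of equal length, a candidate that
#' reproduces the reference scores maximally.
#'
#' @param tokenizer Tokenizer shared by candidate and reference.
#' @param smoothing Additive smoothing constant (default 1).
#' @return A [conditional_scorer()].
#' @export
bigram_scorer <- function(tokenizer = tokenize, smoothing = 1) {
  logprob <- function(candidate, reference) {
    rt <- tokenizer(reference)
    ct <- tokenizer(candidate)
    if (length(ct) == 0) stop("candidate has no tokens")
    vocab <- c(unique(rt), "<unk>")
    v <- length(vocab)
    bos <- "<s>"
    counts <- new.env(parent = emptyenv())
    bump <- function(key) {
      assign(key, (if (exists(key, envir = counts)) get(key, envir = counts) else 0) + 1,
             envir = counts)
    }
    prev <- c(bos, rt[-length(rt)])
    if (length(rt) > 0) {
      for (k in seq_along(rt)) {
        bump(paste0(prev[k], "\r", rt[k]))
        bump(paste0("ctx\r", prev[k]))
      }
    }
    get0c <- function(key) if (exists(key, envir = counts)) get(key, envir = counts) else 0
    map <- function(tok) if (tok %in% vocab) tok else "<unk>"
    ctx <- bos
    total <- 0
    for (tok in ct) {
      w <- map(tok)
      num <- get0c(paste0(ctx, "\r", w)) + smoothing
      den <- get0c(paste0("ctx\r", ctx)) + smoothing * v
      total <- total + log(num / den)
      ctx <- w
    }
    total
  }
  conditional_scorer(logprob, paste0("bigram-a", smoothing))
}

#' Uniform conditional scorer
#'
#' Assigns every candidate token probability `1 / vocab_size`; the score
#' for an n-token candidate is `n * log(1 / vocab_size)`.  Useful as a
#' closed-form baseline.
#'
#' @param vocab_size Vocabulary size (> 1).
#' @param tokenizer Tokenizer applied to the candidate.
#' @return A [conditional_scorer()].
#' @export
uniform_scorer <- function(vocab_size, tokenizer = tokenize) {
  stopifnot(is_scalar_number(vocab_size), vocab_size > 1)
  conditional_scorer(
    function(candidate, reference) {
      n <- length(tokenizer(candidate))
      n * log(1 / vocab_size)
    },
    paste0("uniform-V", vocab_size)
  )
}

#' Conditional log-probability score
#'
#' Value is `scorer$logprob(candidate, reference)`; higher (closer to 0)
#' is better.  Unlike the F-type metrics the score is unbounded below, so
#' downstream paired tests rescale it before comparison with human scores.
#'
#' @inheritParams rouge_l
#' @param scorer A [conditional_scorer()].
#' @return One-row metric tibble (precision/recall are `NA`).
#' @export
logprob_score <- function(candidate, reference, scorer, pair_id = "pair") {
  stopifnot(inherits(scorer, "conditional_scorer"))
  value <- tryCatch(
    scorer$logprob(candidate, reference),
    error = function(e) {
      stop("conditional scorer failed for pair ", pair_id, ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  metric_score(pair_id, "logprob", value, backend_id = scorer$id)
}
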