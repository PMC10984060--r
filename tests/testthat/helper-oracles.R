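# Independent oracles: deliberately different algorithms from the package
# implementations, used to cross-check them.

# Flat recomputation of the composite scores straight from the raw record,
# with its own inline imputation and inversion.
oracle_score_record <- function(rec) {
  p <- s <- numeric(0)
  for (d in rec$diagnoses) {
    pl <- d$plausibility
    sp <- d$specificity
    p <- c(p, if (is.na(pl)) 0 else pl)
    s <- c(s, if (is.na(sp)) 0 else sp)
  }
  unc <- if (is.na(rec$uncertainty)) 0 else rec$uncertainty
  o_bar <- (rec$omission + unc) / 2
  p_bar <- if (length(p) > 0) sum(p) / length(p) else 0
  s_bar <- if (length(s) > 0) sum(s) / length(s) else 0
  D <- (p_bar + s_bar + o_bar) / 15
  ns <- length(rec$reasoning_sentences)
  if (ns > 0) {
    cc <- ee <- aa <- 0
    for (x in rec$reasoning_sentences) {
      cc <- cc + (6 - x$comprehension)
      ee <- ee + (6 - x$recall)
      aa <- aa + (6 - x$rationale)
    }
    R <- (cc / ns + ee / ns + aa / ns) / 15
  } else {
    R <- NA_real_
  }
  list(D = D, R = R, p_bar = p_bar, s_bar = s_bar, o_bar = o_bar)
}

# Exhaustive LCS: enumerate every subsequence of a (as index masks) and
# keep the longest that is also a subsequence of b.
oracle_lcs <- function(a, b) {
  is_subseq <- function(s, t) {
    if (length(s) == 0) return(TRUE)
    j <- 1L
    for (tok in t) {
      if (tok == s[j]) {
        j <- j + 1L
        if (j > length(s)) return(TRUE)
      }
    }
    FALSE
  }
  best <- 0L
  n <- length(a)
  if (n == 0) return(0L)
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(idx) <= best) next
    if (is_subseq(a[idx], b)) best <- length(idx)
  }
  best
}

# Type-level token-overlap P/R/F (set semantics).
oracle_set_prf <- function(cand_tokens, ref_tokens) {
  cs <- unique(cand_tokens)
  rs <- unique(ref_tokens)
  inter <- length(intersect(cs, rs))
  p <- if (length(cs) > 0) inter / length(cs) else 0
  r <- if (length(rs) > 0) inter / length(rs) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(p = p, r = r, f = f)
}

# Brute-force tau-b: explicit enumeration of all pairs i < j.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  ij <- utils::combn(n, 2)
  dx <- x[ij[1, ]] - x[ij[2, ]]
  dy <- y[ij[1, ]] - y[ij[2, ]]
  conc <- sum(dx * dy > 0)
  disc <- sum(dx * dy < 0)
  n0 <- n * (n - 1) / 2
  tx <- table(x)
  ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  den <- sqrt((n0 - n1) * (n0 - n2))
  if (den == 0) NA_real_ else (conc - disc) / den
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments
# over the observed midranks (same two-sided rule as the implementation,
# computed by a different algorithm).
oracle_wilcoxon_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  p_le <- mean(vs <= v_obs)
  p_ge <- mean(vs >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}
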