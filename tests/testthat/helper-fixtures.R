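# Programmatic fixtures (no data files): random branch-consistent records
# and small building blocks.  All draw from the current RNG stream, so
# tests seed it explicitly.

random_valid_record <- function(id = "R1", cfg = framework_config(),
                                n_diag = sample(1:5, 1),
                                n_sent = sample(0:5, 1)) {
  diagnoses <- lapply(seq_len(n_diag), function(i) {
    acc <- sample(1:5, 1)
    pl <- if (acc >= cfg$accuracy_gate) sample(1:5, 1) else NA_real_
    sp <- if (!is.na(pl) && pl >= cfg$plausibility_gate) sample(0:5, 1)
          else NA_real_
    diagnosis_item(paste0("dx ", i), acc, pl, sp)
  })
  om <- sample(0:5, 1)
  unc <- if (om < 5) sample(0:5, 1) else NA_real_
  sents <- lapply(seq_len(n_sent), function(j) {
    reasoning_sentence_item(paste0("sentence ", j),
                            sample(1:5, 1), sample(1:5, 1), sample(1:5, 1))
  })
  record_annotation(id, diagnoses, om, unc, sents, sample(0:1, 1))
}

# The hand-arithmetic scoring fixture: p_bar = 4, s_bar = 3, o_bar = 2.5.
fixture_record_9p5 <- function() {
  record_annotation(
    "FIX1",
    diagnoses = list(
      diagnosis_item("dx a", 5, 4, 3),
      diagnosis_item("dx b", 4, 4, 3),
      diagnosis_item("dx c", 5, 4, 3)
    ),
    omission = 1, uncertainty = 4,
    reasoning_sentences = list(
      reasoning_sentence_item("s1", 2, 3, 1)
    )
  )
}

random_token_list <- function(max_len = 8, vocab = letters[1:5]) {
  n <- sample(0:max_len, 1)
  sample(vocab, n, replace = TRUE)
}
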