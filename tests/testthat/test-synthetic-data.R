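test_that("lexicon generation is deterministic with the requested shape", {
  l1 <- generate_lexicon(50, seed = 0)
  l2 <- generate_lexicon(50, seed = 0)
  expect_identical(l1, l2)
  expect_equal(length(unique(l1$cui)), 50)
  expect_true(all(table(l1$cui) >= 1 & table(l1$cui) <= 3))
  expect_error(generate_lexicon(5), "at least|>= 10|lexicon_size")
})

test_that("every surface variant extracts back to its own concept id", {
  lex <- generate_lexicon(40, seed = 3)
  ex <- dictionary_extractor(lex)
  for (k in seq_len(nrow(lex))) {
    expect_identical(ex$extract(lex$surface[k]), lex$cui[k])
  }
})

test_that("noiseless extremes pin down the generated record", {
  cfg <- generator_config(seed = 1, noise_sd = 0)
  lex <- generate_lexicon(60, seed = 2)
  ex <- dictionary_extractor(lex)

  set.seed(11)
  out <- generate_record(cfg, lex, q = 1, record_id = "Q1")
  # candidate concepts are a permutation of the reference concepts
  cand_cuis <- unlist(lapply(out$generation$candidate_diagnoses,
                             function(s) ex$extract(s)))
  ref_cuis <- unlist(lapply(out$generation$reference_diagnoses,
                            function(s) ex$extract(s)))
  expect_setequal(cand_cuis, ref_cuis)
  expect_equal(out$overlap_realized, 1)
  # all item ratings at their maxima; uncertainty branched out
  for (d in out$annotation$diagnoses) {
    expect_equal(d$accuracy, 5)
    expect_equal(d$plausibility, 5)
    expect_equal(d$specificity, 5)
  }
  expect_equal(out$annotation$omission, 5)
  expect_true(is.na(out$annotation$uncertainty))
  sc <- score_record(out$annotation)
  expect_equal(sc$D, 12.5 / 15)  # imputed uncertainty caps D below 1
  expect_equal(sc$R, 1)

  set.seed(12)
  out <- generate_record(cfg, lex, q = 0, record_id = "Q0")
  cand_cuis <- unlist(lapply(out$generation$candidate_diagnoses,
                             function(s) ex$extract(s)))
  ref_cuis <- unlist(lapply(out$generation$reference_diagnoses,
                            function(s) ex$extract(s)))
  expect_length(intersect(cand_cuis, ref_cuis), 0)
  sc <- score_record(out$annotation)
  expect_equal(sc$D, 0)

  # determinism at fixed seed and mid quality
  set.seed(13)
  a <- generate_record(cfg, lex, q = 0.5, record_id = "QH")
  set.seed(13)
  b <- generate_record(cfg, lex, q = 0.5, record_id = "QH")
  expect_identical(a, b)
})

test_that("generated cohorts validate cleanly and match the configured shape", {
  cfg <- generator_config(seed = 7)
  cohort <- generate_cohort(cfg)
  expect_equal(length(cohort$records), 186)
  expect_equal(nrow(cohort$truth), 186)

  n_diag <- vapply(cohort$records, function(r) length(r$diagnoses), integer(1))
  n_sent <- vapply(cohort$records,
                   function(r) length(r$reasoning_sentences), integer(1))
  expect_true(all(n_diag >= 3 & n_diag <= 5))
  expect_true(all(n_sent >= 3 & n_sent <= 6))
  expect_true(sum(n_diag) >= 186 * 3 && sum(n_diag) <= 186 * 5)

  violations <- vapply(cohort$records,
                       function(r) nrow(validate_record(r)), integer(1))
  expect_true(all(violations == 0))
})

test_that("cohort generation is deterministic down to the emitted files", {
  cfg <- generator_config(seed = 123, n_records = 25)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(cfg), d1)
  write_cohort(generate_cohort(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
  # and cohorts round-trip through the annotation format
  back <- read_annotations(file.path(d1, "annotations.csv"))
  cohort <- generate_cohort(cfg)
  for (i in seq_along(back)) expect_identical(back[[i]], cohort$records[[i]])
})

test_that("rho_star controls the quality/overlap coupling", {
  overlap_cor <- function(rho, seed) {
    cohort <- generate_cohort(generator_config(seed = seed, rho_star = rho))
    cor(cohort$truth$q, cohort$truth$overlap_realized, method = "spearman")
  }
  # at rho* = 0 overlap is independent of q
  expect_lt(abs(overlap_cor(0, 31)), 0.15)
  # coupling strengthens with rho*
  lo <- mean(vapply(1:5, function(s) overlap_cor(0.2, s), numeric(1)))
  hi <- mean(vapply(1:5, function(s) overlap_cor(0.8, s), numeric(1)))
  expect_gt(hi, lo)
})
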