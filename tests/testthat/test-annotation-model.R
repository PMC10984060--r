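test_that("validate_record flags branching violations and accepts compliant records", {
  cfg <- framework_config()

  # specificity present although the plausibility gate failed
  rec <- record_annotation("V1", list(diagnosis_item("dx", 5, 2, 3)),
                           omission = 5)
  v <- validate_record(rec, cfg)
  expect_equal(nrow(v), 1)
  expect_equal(v$component, "specificity")

  # uncertainty present although omission says nothing was omitted
  rec <- record_annotation("V2", list(diagnosis_item("dx", 2)),
                           omission = 5, uncertainty = 3)
  v <- validate_record(rec, cfg)
  expect_equal(nrow(v), 1)
  expect_equal(v$component, "uncertainty")

  # fully compliant record
  rec <- record_annotation(
    "V3",
    list(diagnosis_item("dx", 5, 5, 4), diagnosis_item("dx2", 1)),
    omission = 3, uncertainty = 2,
    reasoning_sentences = list(reasoning_sentence_item("s", 1, 1, 2))
  )
  expect_equal(nrow(validate_record(rec, cfg)), 0)

  # out-of-scale and missing mandatory values are caught
  rec <- record_annotation("V4", list(diagnosis_item("dx", 7)), omission = 5)
  expect_gte(nrow(validate_record(rec, cfg)), 1)
  rec <- record_annotation("V5", list(), omission = 5)
  expect_equal(validate_record(rec, cfg)$component, "diagnoses")
})

test_that("impute_branching fills gated-out values with zero and only those", {
  cfg <- framework_config()
  rec <- record_annotation("I1", list(diagnosis_item("dx", 2)), omission = 5)
  imp <- impute_branching(rec, cfg)
  expect_equal(imp$diagnoses[[1]]$plausibility, 0)
  expect_equal(imp$diagnoses[[1]]$specificity, 0)
  expect_equal(imp$uncertainty, 0)

  # plausibility below gate: specificity imputed, plausibility untouched
  rec <- record_annotation("I2", list(diagnosis_item("dx", 5, 2)),
                           omission = 2, uncertainty = 3)
  imp <- impute_branching(rec, cfg)
  expect_equal(imp$diagnoses[[1]]$plausibility, 2)
  expect_equal(imp$diagnoses[[1]]$specificity, 0)
  expect_equal(imp$uncertainty, 3)

  # fully branched-in record is unchanged, and imputation is idempotent
  rec <- record_annotation("I3", list(diagnosis_item("dx", 5, 5, 4)),
                           omission = 2, uncertainty = 1)
  expect_identical(impute_branching(rec, cfg), rec)
  set.seed(42)
  for (k in 1:25) {
    r <- random_valid_record(paste0("I", k))
    expect_identical(impute_branching(impute_branching(r, cfg), cfg),
                     impute_branching(r, cfg))
  }

  # an absent value branching cannot explain is a corrupt export
  rec <- record_annotation("I4", list(diagnosis_item("dx", 5)), omission = 5)
  expect_error(impute_branching(rec, cfg), "plausibility absent")
  rec <- record_annotation("I5", list(diagnosis_item("dx", 2)), omission = 2)
  expect_error(impute_branching(rec, cfg), "uncertainty absent")
})

test_that("invert_reasoning applies 6 - x and is an involution", {
  rec <- record_annotation(
    "N1", list(diagnosis_item("dx", 2)), omission = 5,
    reasoning_sentences = list(
      reasoning_sentence_item("s1", 1, 5, 3),
      reasoning_sentence_item("s2", 2, 4, 1)
    )
  )
  inv <- invert_reasoning(rec)
  expect_equal(inv$reasoning_sentences[[1]]$comprehension, 5)
  expect_equal(inv$reasoning_sentences[[1]]$rationale, 1)
  expect_equal(inv$reasoning_sentences[[1]]$recall, 3)
  expect_identical(invert_reasoning(inv), rec)

  bad <- record_annotation(
    "N2", list(diagnosis_item("dx", 2)), omission = 5,
    reasoning_sentences = list(reasoning_sentence_item("s", 0, 3, 3))
  )
  expect_error(invert_reasoning(bad), "1\\.\\.5")
})

test_that("score_record reproduces hand arithmetic and the extreme cases", {
  # p_bar = 4, s_bar = 3, o_bar = 2.5 -> D = 9.5/15
  sc <- score_record(fixture_record_9p5())
  expect_equal(sc$p_bar, 4)
  expect_equal(sc$s_bar, 3)
  expect_equal(sc$o_bar, 2.5)
  expect_equal(sc$D, 9.5 / 15)
  # sentence (2, 3, 1) inverted -> c = 4, a = 3, e = 5
  expect_equal(sc$R, 12 / 15)

  # arithmetic maximum (value combination scored mechanically)
  rec <- record_annotation("M1",
                           list(diagnosis_item("dx", 5, 5, 5)),
                           omission = 5, uncertainty = 5)
  expect_equal(score_record(rec, validate = FALSE)$D, 1)

  # best-reasoning case: all raw evidence ratings at 1 -> R = 1
  rec <- record_annotation(
    "M2", list(diagnosis_item("dx", 2)), omission = 2, uncertainty = 3,
    reasoning_sentences = list(reasoning_sentence_item("s", 1, 1, 1))
  )
  expect_equal(score_record(rec)$R, 1)

  # zero diagnoses need the explicit empty-output flag
  expect_error(score_record(record_annotation("M3", list(), omission = 2,
                                              uncertainty = 0)),
               "empty_output")
  sc <- score_record(record_annotation("M4", list(), omission = 0,
                                       uncertainty = 0, empty_output = TRUE))
  expect_equal(sc$D, 0)
  expect_true(is.na(sc$R))
})

test_that("scores equal the flat oracle and stay in [0, 1] on random records", {
  set.seed(101)
  for (k in 1:200) {
    rec <- random_valid_record(paste0("F", k))
    sc <- score_record(rec)
    orc <- oracle_score_record(rec)
    expect_equal(sc$D, orc$D, tolerance = 1e-14)
    expect_true(sc$D >= 0 && sc$D <= 1)
    if (is.na(orc$R)) {
      expect_true(is.na(sc$R))
    } else {
      expect_equal(sc$R, orc$R, tolerance = 1e-14)
      expect_true(sc$R >= 0 && sc$R <= 1)
    }
  }
})

test_that("score_cohort summarises medians, IQR and component frequencies", {
  cfg <- framework_config()
  rec <- fixture_record_9p5()
  cs <- score_cohort(list(rec, rec, rec), cfg)
  expect_equal(nrow(cs$scores), 3)
  d_sum <- cs$summary[cs$summary$score == "diagnostic_accuracy", ]
  expect_equal(d_sum$median, 9.5 / 15)
  expect_equal(d_sum$q75 - d_sum$q25, 0)

  # median follows the definition on distinct scores
  set.seed(5)
  recs <- replicate(7, random_valid_record(), simplify = FALSE)
  for (i in seq_along(recs)) recs[[i]]$record_id <- paste0("C", i)
  cs <- score_cohort(recs, cfg)
  expect_equal(cs$summary$median[1], median(cs$scores$D))

  # frequency table covers all instrument components
  expect_setequal(
    cs$components$component,
    c("accurate", "plausible", "specific", "no_omission",
      "epistemic_uncertainty", "comprehension_clean", "rationale_clean",
      "recall_clean", "reasoning_omitted")
  )
  # all fixture diagnoses are accurate and plausible
  cf <- score_cohort(list(rec), cfg)$components
  expect_equal(cf$fraction[cf$component == "accurate"], 1)
  expect_equal(cf$fraction[cf$component == "plausible"], 1)

  # per-record failures carry the record id
  bad <- record_annotation("BAD", list(diagnosis_item("dx", 9)), omission = 5)
  expect_error(score_cohort(list(bad), cfg), "BAD")
})

test_that("records without reasoning sentences are excluded from the R summary", {
  rec_no_sent <- record_annotation("S0", list(diagnosis_item("dx", 2)),
                                   omission = 5)
  rec_sent <- fixture_record_9p5()
  expect_message(cs <- score_cohort(list(rec_no_sent, rec_sent)),
                 "no reasoning sentences")
  r_sum <- cs$summary[cs$summary$score == "diagnostic_reasoning", ]
  expect_equal(r_sum$n, 1)
  expect_equal(r_sum$median, 12 / 15)
})
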