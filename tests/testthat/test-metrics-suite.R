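suite_pairs <- function() {
  tibble::tibble(
    pair_id = c("P1", "P2"),
    candidate = c("sepsis ; anemia", "pneumonia ; fever"),
    reference = c("sepsis ; fever", "influenza pneumonia ; fever")
  )
}

test_that("the suite emits one row per pair and metric", {
  reg <- metric_registry()[c("rouge_l", "embed_greedy")]
  out <- run_metric_suite(suite_pairs(), reg)
  expect_equal(nrow(out), 4)
  expect_setequal(out$metric_name, c("rouge_l", "embed_greedy"))
  expect_setequal(out$pair_id, c("P1", "P2"))
})

test_that("a suite restricted to rouge_l reproduces rouge_l exactly", {
  pairs <- suite_pairs()
  out <- run_metric_suite(pairs, metric_registry(), metrics = "rouge_l")
  for (k in seq_len(nrow(pairs))) {
    direct <- rouge_l(pairs$candidate[k], pairs$reference[k], pairs$pair_id[k])
    expect_equal(out$value[k], direct$value)
    expect_equal(out$precision[k], direct$precision)
  }
})

test_that("unknown metric names raise an error listing the available ones", {
  expect_error(run_metric_suite(suite_pairs(), metric_registry(),
                                metrics = "bleu"),
               "available:.*rouge_l")
})

test_that("unavailable adapters are skipped with a warning, never zeroed", {
  reg <- metric_registry(extra = list(comet_like = adapter_metric("comet_like")))
  expect_warning(out <- run_metric_suite(suite_pairs(), reg), "comet_like")
  expect_false("comet_like" %in% out$metric_name)
  expect_equal(nrow(out), 2 * 3)  # the three bundled metrics still ran

  # a bound adapter participates like any other metric
  reg$comet_like <- adapter_metric("comet_like",
                                   fn = function(c, r) nchar(c) / 100)
  out <- run_metric_suite(suite_pairs(), reg)
  expect_true("comet_like" %in% out$metric_name)
})

test_that("scoring the same pairs twice is deterministic", {
  cohort <- generate_cohort(generator_config(seed = 0, n_records = 12))
  pairs <- generation_pairs(cohort$generations)
  reg <- metric_registry(lexicon = cohort$lexicon)
  expect_identical(run_metric_suite(pairs, reg), run_metric_suite(pairs, reg))
})

test_that("a registry can be loaded from YAML and JSON configs", {
  lex_path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(surface = c("sepsis", "anemia"), cui = c("C1", "C2")),
            lex_path, row.names = FALSE)
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "overlap:",
    "  type: rouge_l",
    "concepts:",
    "  type: concept",
    paste0("  lexicon: ", lex_path),
    "external:",
    "  type: adapter"
  ), yml)
  reg <- read_metric_registry(yml)
  expect_setequal(names(reg), c("overlap", "concepts", "external"))
  expect_false(reg$external$available)
  out <- suppressWarnings(run_metric_suite(suite_pairs(), reg))
  expect_setequal(unique(out$metric_name), c("rouge_l", "concept_f"))

  jsn <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(overlap = list(type = "rouge_l"),
                            lp = list(type = "logprob_uniform", vocab_size = 10)),
                       jsn, auto_unbox = TRUE)
  reg2 <- read_metric_registry(jsn)
  out2 <- run_metric_suite(suite_pairs(), reg2)
  expect_setequal(unique(out2$metric_name), c("rouge_l", "logprob"))
})
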