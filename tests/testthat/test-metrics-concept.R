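toy_lexicon <- function() {
  tibble::tibble(
    surface = c("sepsis", "severe sepsis", "pneumonia", "influenza pneumonia",
                "kidney injury", "anemia"),
    cui = c("C1", "C1", "C2", "C3", "C4", "C5")
  )
}

test_that("dictionary extraction is longest-match and returns a set", {
  ex <- dictionary_extractor(toy_lexicon())
  # "influenza pneumonia" must win over the shorter "pneumonia"
  expect_setequal(ex$extract("possible influenza pneumonia today"), "C3")
  expect_setequal(ex$extract("pneumonia with severe sepsis"), c("C2", "C1"))
  # duplicates collapse to one id
  expect_equal(ex$extract("sepsis and sepsis and Sepsis"), "C1")
  expect_length(ex$extract("no concepts here"), 0)
})

test_that("concept_fscore matches set arithmetic", {
  ex <- dictionary_extractor(toy_lexicon())
  # candidate {C1, C2}, reference {C2, C4}
  m <- concept_fscore("sepsis # pneumonia", "pneumonia # kidney injury", ex)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$value, 0.5)

  expect_equal(concept_fscore("sepsis # anemia", "severe sepsis # anemia", ex)$value, 1)
  expect_warning(m <- concept_fscore("nothing known", "sepsis", ex), "empty")
  expect_equal(m$value, 0)
})

test_that("concept_fscore depends only on the extracted sets", {
  ex <- dictionary_extractor(toy_lexicon())
  a <- concept_fscore("sepsis # pneumonia # sepsis", "anemia # pneumonia", ex)
  b <- concept_fscore("pneumonia # sepsis", "pneumonia # anemia # anemia", ex)
  expect_equal(a$value, b$value)
  expect_equal(a$precision, b$precision)
})

test_that("graph embedding score follows the greedy similarity matrix", {
  ex <- dictionary_extractor(toy_lexicon())
  emb <- onehot_concept_embedder(c("C1", "C2", "C3", "C4", "C5"))

  expect_equal(graph_embedding_fscore("sepsis # pneumonia",
                                      "severe sepsis # pneumonia", ex, emb)$value, 1)
  expect_equal(graph_embedding_fscore("sepsis", "anemia", ex, emb)$value, 0)

  # overlapping sets {C1,C2,C5} vs {C2,C4,C5}: one-hot greedy matching
  # reduces to set overlap, here 2/3 on both sides
  m <- graph_embedding_fscore("sepsis # pneumonia # anemia",
                              "pneumonia # kidney injury # anemia", ex, emb)
  orc <- oracle_set_prf(c("C1", "C2", "C5"), c("C2", "C4", "C5"))
  expect_equal(m$precision, orc$p, tolerance = 1e-12)
  expect_equal(m$value, orc$f, tolerance = 1e-12)

  # with arbitrary toy embeddings the score equals a direct computation
  # over the full pairwise cosine matrix
  hemb <- hash_concept_embedder(6, seed = 4)
  m <- graph_embedding_fscore("sepsis # pneumonia # anemia",
                              "pneumonia # kidney injury # anemia", ex, hemb)
  ec <- hemb(sort(c("C1", "C2", "C5")))
  er <- hemb(sort(c("C2", "C4", "C5")))
  s <- (ec / sqrt(rowSums(ec^2))) %*% t(er / sqrt(rowSums(er^2)))
  p <- mean(apply(s, 1, max))
  r <- mean(apply(s, 2, max))
  expect_equal(m$precision, p, tolerance = 1e-12)
  expect_equal(m$recall, r, tolerance = 1e-12)
  expect_equal(m$value, 2 * p * r / (p + r), tolerance = 1e-12)

  # unknown concepts back off to zero vectors with a warning
  small <- onehot_concept_embedder(c("C1"))
  expect_warning(graph_embedding_fscore("sepsis # pneumonia", "sepsis", ex, small),
                 "without embedding")
})
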