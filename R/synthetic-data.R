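# Synthetic cohort generator.  Emulates the shape of a clinician-annotated
# diagnosis-generation study -- 186 note-level records, 3-5 diagnoses and
# 3-6 reasoning sentences per record (about 768 diagnoses and 828
# sentences in expectation) -- with a known latent structure: each record
# carries a latent quality q in [0,1] that drives both the human Likert
# responses and, through a tunable mixing rate rho_star, the concept
# overlap between candidate and reference diagnoses.  This gives every
# downstream module a ground truth to recover.

#' Generator configuration
#'
#' @param seed Integer seed; mandatory, every draw flows from it.
#' @param n_records Number of note-level records (default 186).
#' @param diagnoses_min,diagnoses_max Uniform range of diagnoses per
#'   record (default 3--5).
#' @param sentences_min,sentences_max Uniform range of reasoning sentences
#'   per record (default 3--6).
#' @param rho_star Target correlation, in `[-1, 1]`, between latent
#'   quality and candidate/reference concept overlap.  0 makes text
#'   overlap independent of the human scores; 1 ties them deterministically.
#' @param noise_sd Standard deviation of the discretized-normal Likert
#'   response noise, in scale points (default 0.7, under one Likert step).
#' @param lexicon_size Number of concepts in the toy lexicon (>= 10).
#' @param beta_a,beta_b Beta distribution parameters of latent quality
#'   (default 2, 2: symmetric, mid-heavy).
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed, n_records = 186,
                             diagnoses_min = 3, diagnoses_max = 5,
                             sentences_min = 3, sentences_max = 6,
                             rho_star = 0.5, noise_sd = 0.7,
                             lexicon_size = 120, beta_a = 2, beta_b = 2) {
  if (missing(seed) || !is_scalar_number(seed)) {
    stop("seed is mandatory: cohorts must be reproducible")
  }
  stopifnot(n_records >= 1, diagnoses_min >= 1,
            diagnoses_max >= diagnoses_min,
            sentences_min >= 0, sentences_max >= sentences_min,
            rho_star >= -1, rho_star <= 1, noise_sd >= 0,
            lexicon_size >= 10)
  structure(
    list(seed = as.integer(seed), n_records = as.integer(n_records),
         diagnoses_min = as.integer(diagnoses_min),
         diagnoses_max = as.integer(diagnoses_max),
         sentences_min = as.integer(sentences_min),
         sentences_max = as.integer(sentences_max),
         rho_star = rho_star, noise_sd = noise_sd,
         lexicon_size = as.integer(lexicon_size),
         beta_a = beta_a, beta_b = beta_b),
    class = "generator_config"
  )
}

lexicon_prefixes <- c(
  "cardi", "nephr", "hepat", "pneumon", "dermat", "neur", "gastr", "arthr",
  "hemat", "oste", "encephal", "bronch", "col", "cyst", "glomerul",
  "myocardi", "pancreat", "pericardi", "rhin", "vascul"
)
lexicon_suffixes <- c(
  "itis", "osis", "opathy", "emia", "algia", "oma", "omegaly",
  "osclerosis", "odystrophy", "ostenosis", "orrhage", "oplegia"
)
lexicon_modifiers <- c("acute", "chronic", "severe", "recurrent", "secondary")

#' Generate a toy diagnosis lexicon
#'
#' Builds pseudo-medical concept entries: each concept has a unique
#' CUI-like identifier, a specificity tier (1--3) and 1--3 surface
#' variants (base term, a modified term, and a "syndrome" form) so that
#' paraphrase, dictionary extraction and concept-level metrics all have
#' something to work with.  Deterministic under the seed.
#'
#' @param lexicon_size Number of distinct concepts (10--240).
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (as when called inside [generate_cohort()]).
#' @return Tibble with columns `cui`, `surface`, `tier`, `variant`.
#' @export
generate_lexicon <- function(lexicon_size = 120, seed = NULL) {
  stopifnot(lexicon_size >= 10)
  combos <- expand.grid(prefix = lexicon_prefixes, suffix = lexicon_suffixes,
                        stringsAsFactors = FALSE)
  if (lexicon_size > nrow(combos)) {
    stop("lexicon_size must be at most ", nrow(combos))
  }
  build <- function() {
    pick <- combos[sample.int(nrow(combos), lexicon_size), , drop = FALSE]
    base <- paste0(pick$prefix, pick$suffix)
    rows <- list()
    for (i in seq_len(lexicon_size)) {
      cui <- sprintf("C%07d", 13 * i + 5)
      tier <- sample.int(3, 1)
      n_var <- sample.int(3, 1)
      surfaces <- base[i]
      if (n_var >= 2) {
        surfaces <- c(surfaces, paste(resample(lexicon_modifiers, 1), base[i]))
      }
      if (n_var >= 3) surfaces <- c(surfaces, paste(base[i], "syndrome"))
      rows[[i]] <- tibble::tibble(cui = cui, surface = surfaces,
                                  tier = tier,
                                  variant = seq_along(surfaces))
    }
    do.call(rbind, rows)
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

draw_likert <- function(mean, sd, lo, hi) {
  clamp(round(rnorm(1, mean, sd)), lo, hi)
}

#' Generate one synthetic record
#'
#' Draws a reference diagnosis list from the lexicon and a candidate list
#' sharing a `round(overlap * n_candidate)` subset of its concepts, the
#' remainder replaced by "hallucinations" (concepts outside the
#' reference).  Human judgments follow the branching instrument with
#' means monotone in `q`: accuracy means are high for overlapping
#' concepts and low for hallucinations, plausibility and specificity
#' means rise with `q`, omission severity and raw
#' comprehension/rationale/recall evidence fall with `q`.  Branching is
#' respected by construction, so every emitted record validates cleanly.
#'
#' Uses the current RNG stream: seed the stream (or call through
#' [generate_cohort()]) for reproducibility.
#'
#' @param cfg A [generator_config()].
#' @param lexicon Lexicon tibble from [generate_lexicon()].
#' @param q Latent quality in `[0, 1]`.
#' @param overlap Target candidate/reference concept-overlap fraction
#'   (defaults to `q`; [generate_cohort()] passes the rho_star-mixed
#'   value).
#' @param record_id Identifier for the record.
#' @return List with elements `generation` (record_id, candidate and
#'   reference diagnosis vectors, reasoning text, raw generation string),
#'   `annotation` (a [record_annotation()]) and `overlap_realized`.
#' @export
generate_record <- function(cfg, lexicon, q, overlap = q, record_id = "R001") {
  stopifnot(q >= 0, q <= 1, overlap >= 0, overlap <= 1)
  concepts <- unique(lexicon$cui)
  # one length per record: at overlap 1 the candidate is then exactly a
  # permutation of the reference concepts
  n_ref <- resample(cfg$diagnoses_min:cfg$diagnoses_max, 1)
  n_cand <- n_ref
  ref_cuis <- resample(concepts, n_ref)
  n_shared <- clamp(round(overlap * n_cand), 0, min(n_cand, n_ref))
  shared <- resample(ref_cuis, n_shared)
  pool <- setdiff(concepts, ref_cuis)
  halluc <- resample(pool, n_cand - n_shared)
  cand_cuis <- resample(c(shared, halluc), n_cand)  # permuted

  surface_of <- function(cui) {
    variants <- lexicon$surface[lexicon$cui == cui]
    resample(variants, 1)
  }
  ref_surfaces <- vapply(ref_cuis, function(cui) {
    lexicon$surface[lexicon$cui == cui][1]  # canonical variant
  }, character(1))
  cand_surfaces <- vapply(cand_cuis, surface_of, character(1))

  sd <- cfg$noise_sd
  diagnoses <- vector("list", n_cand)
  for (i in seq_len(n_cand)) {
    # response means depend on latent quality only; text overlap is coupled
    # to the judgments solely through the rho_star mixing in the cohort.
    # The affine maps are calibrated so mid-quality cohorts show the
    # marginals typical of clinician-rated LLM diagnoses (most outputs
    # accurate and plausible, under half specific) while the noiseless
    # extremes stay exact: every component at its maximum at q = 1, all
    # gates failed and omission at its worst at q = 0.
    accuracy <- draw_likert(3.4 + 1.6 * q, sd, 1, 5)
    plausibility <- NA_real_
    specificity <- NA_real_
    if (accuracy >= 4) {
      plausibility <- draw_likert(3.4 + 1.6 * q, sd, 1, 5)
      if (plausibility >= 4) {
        specificity <- draw_likert(2 + 3 * q, sd, 0, 5)
      }
    }
    diagnoses[[i]] <- diagnosis_item(cand_surfaces[i], accuracy,
                                     plausibility, specificity)
  }

  omission <- draw_likert(5 * q, sd, 0, 5)
  uncertainty <- if (omission < 5) draw_likert(5 * q, sd, 0, 5) else NA_real_

  n_sent <- resample(cfg$sentences_min:cfg$sentences_max, 1)
  sentences <- vector("list", n_sent)
  templates <- c("the note documents %s with supporting findings",
                 "findings are consistent with %s on review",
                 "%s is suggested by the subjective section",
                 "assessment favors %s given the course")
  for (j in seq_len(max(n_sent, 0))) {
    topic <- cand_surfaces[((j - 1) %% n_cand) + 1]
    txt <- sprintf(resample(templates, 1), topic)
    sentences[[j]] <- reasoning_sentence_item(
      txt,
      comprehension = draw_likert(3 - 2 * q, sd, 1, 5),
      rationale = draw_likert(3 - 2 * q, sd, 1, 5),
      recall = draw_likert(3 - 2 * q, sd, 1, 5)
    )
  }
  reasoning_omission <- rbinom(1, 1, clamp(0.26 * (1 - q), 0, 1))

  reasoning_text <- paste(vapply(sentences, function(s) s$sentence_text,
                                 character(1)), collapse = ". ")
  raw <- paste0(paste(cand_surfaces, collapse = " # "),
                " <Reasoning> ", reasoning_text)
  list(
    generation = list(
      record_id = record_id,
      candidate_diagnoses = unname(cand_surfaces),
      reference_diagnoses = unname(ref_surfaces),
      reasoning_text = reasoning_text,
      raw = raw
    ),
    annotation = record_annotation(
      record_id = record_id, diagnoses = diagnoses,
      omission = omission, uncertainty = uncertainty,
      reasoning_sentences = sentences,
      reasoning_omission = reasoning_omission
    ),
    overlap_realized = n_shared / n_cand
  )
}

#' Generate a full synthetic cohort
#'
#' Draws latent qualities `q_i ~ Beta(a, b)`, mixes them with independent
#' uniforms at rate `|rho_star|` to produce each record's concept-overlap
#' target (sign of `rho_star` flips the direction), and emits aligned
#' annotation records, generation texts and a ground-truth table.
#'
#' @param cfg A [generator_config()].
#' @return A `synthetic_cohort` list: `cfg`, `lexicon`, `records` (list of
#'   [record_annotation()]s), `generations` (tibble: `record_id`,
#'   `candidate`, `reference`, `raw`), `truth` (tibble: `record_id`, `q`,
#'   `overlap_target`, `overlap_realized`, `rho_star`).
#' @examples
#' cohort <- generate_cohort(generator_config(seed = 7, n_records = 20))
#' nrow(cohort$truth)
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    lexicon <- generate_lexicon(cfg$lexicon_size)
    n <- cfg$n_records
    q <- rbeta(n, cfg$beta_a, cfg$beta_b)
    u <- runif(n)
    w <- abs(cfg$rho_star)
    base <- if (cfg$rho_star >= 0) q else 1 - q
    overlap <- clamp(w * base + (1 - w) * u, 0, 1)
    records <- vector("list", n)
    gen_rows <- vector("list", n)
    truth_rows <- vector("list", n)
    for (i in seq_len(n)) {
      id <- sprintf("R%04d", i)
      out <- generate_record(cfg, lexicon, q[i], overlap[i], id)
      records[[i]] <- out$annotation
      gen_rows[[i]] <- tibble::tibble(
        record_id = id,
        candidate = paste(out$generation$candidate_diagnoses, collapse = " # "),
        reference = paste(out$generation$reference_diagnoses, collapse = " # "),
        raw = out$generation$raw
      )
      truth_rows[[i]] <- tibble::tibble(
        record_id = id, q = q[i], overlap_target = overlap[i],
        overlap_realized = out$overlap_realized, rho_star = cfg$rho_star
      )
    }
    structure(
      list(cfg = cfg, lexicon = lexicon, records = records,
           generations = do.call(rbind, gen_rows),
           truth = do.call(rbind, truth_rows)),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", length(x$records), "records, rho* =",
      x$cfg$rho_star, ", seed =", x$cfg$seed, "\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the exact formats the rest of the pipeline consumes:
#' `annotations.csv` (long annotation format), `generations.tsv` and
#' `references.tsv` (`record_id<TAB>text` lines), `truth.csv` and
#' `lexicon.csv`.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    annotations = file.path(dir, "annotations.csv"),
    generations = file.path(dir, "generations.tsv"),
    references = file.path(dir, "references.tsv"),
    truth = file.path(dir, "truth.csv"),
    lexicon = file.path(dir, "lexicon.csv")
  )
  write_annotations(cohort$records, paths["annotations"])
  writeLines(paste(cohort$generations$record_id, cohort$generations$raw,
                   sep = "\t"), paths["generations"])
  writeLines(paste(cohort$generations$record_id, cohort$generations$reference,
                   sep = "\t"), paths["references"])
  utils::write.csv(as.data.frame(cohort$truth), paths["truth"],
                   row.names = FALSE)
  utils::write.csv(as.data.frame(cohort$lexicon), paths["lexicon"],
                   row.names = FALSE)
  invisible(paths)
}
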