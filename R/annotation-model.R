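#' A single annotated diagnosis
#'
#' One candidate diagnosis with its branched Likert judgments.  Plausibility
#' is only scored when the diagnosis passed the accuracy gate, and
#' Specificity only when it passed the plausibility gate; gated-out values
#' are `NA` in the raw export and later imputed to 0 by
#' [impute_branching()].
#'
#' @param diagnosis_text Free text of the diagnosis.
#' @param accuracy Likert rating 1--5.
#' @param plausibility Likert rating 1--5, or `NA` when gated out.
#' @param specificity Likert rating 0--5, or `NA` when gated out.
#' @return A `dx_diagnosis` list.
#' @export
diagnosis_item <- function(diagnosis_text, accuracy,
                           plausibility = NA_real_, specificity = NA_real_) {
  structure(
    list(
      diagnosis_text = as.character(diagnosis_text),
      accuracy = as.numeric(accuracy),
      plausibility = as.numeric(plausibility),
      specificity = as.numeric(specificity)
    ),
    class = "dx_diagnosis"
  )
}

#' A single annotated reasoning sentence
#'
#' Raw Comprehension, Rationale and Recall ratings use an inverse scale:
#' 1 means *no evidence* of incorrect comprehension / reasoning / recall
#' (best), 5 means strong evidence (worst).  [invert_reasoning()] maps them
#' to `6 - x` so that higher is better before averaging.
#'
#' @param sentence_text Free text of the sentence.
#' @param comprehension,rationale,recall Raw Likert ratings 1--5.
#' @return A `dx_sentence` list.
#' @export
reasoning_sentence_item <- function(sentence_text, comprehension, rationale, recall) {
  structure(
    list(
      sentence_text = as.character(sentence_text),
      comprehension = as.numeric(comprehension),
      rationale = as.numeric(rationale),
      recall = as.numeric(recall)
    ),
    class = "dx_sentence"
  )
}

#' All human judgments for one generated output
#'
#' Bundles the per-diagnosis items, the output-level Omission/Uncertainty
#' pair (Uncertainty is conditional on an omission having occurred), the
#' per-sentence reasoning items and the binary output-level reasoning
#' Omission for a single progress-note record.
#'
#' @param record_id Record identifier.
#' @param diagnoses List of [diagnosis_item()]s (may be empty only when
#'   `empty_output = TRUE`).
#' @param omission Likert rating 0--5; the scale maximum means no diagnosis
#'   was omitted.
#' @param uncertainty Likert rating 0--5, or `NA` when no omission occurred.
#' @param reasoning_sentences List of [reasoning_sentence_item()]s.
#' @param reasoning_omission Binary 0/1: the output lacked an explanation
#'   for its diagnoses.
#' @param empty_output Flag marking a generation that produced no diagnoses
#'   at all (scored with zero plausibility/specificity means).
#' @return A `record_annotation` list.
#' @export
record_annotation <- function(record_id, diagnoses, omission,
                              uncertainty = NA_real_,
                              reasoning_sentences = list(),
                              reasoning_omission = 0,
                              empty_output = FALSE) {
  stopifnot(length(record_id) == 1L)
  if (!is.list(diagnoses)) stop("diagnoses must be a list of diagnosis_item()s")
  structure(
    list(
      record_id = as.character(record_id),
      diagnoses = diagnoses,
      omission = as.numeric(omission),
      uncertainty = as.numeric(uncertainty),
      reasoning_sentences = reasoning_sentences,
      reasoning_omission = as.numeric(reasoning_omission),
      empty_output = isTRUE(empty_output)
    ),
    class = "record_annotation"
  )
}

#' @export
print.record_annotation <- function(x, ...) {
  cat("<record_annotation>", x$record_id, "\n")
  cat("  diagnoses:", length(x$diagnoses),
      "| reasoning sentences:", length(x$reasoning_sentences), "\n")
  cat("  omission:", x$omission, "| uncertainty:", x$uncertainty,
      "| reasoning omission:", x$reasoning_omission, "\n")
  invisible(x)
}

violation_row <- function(record_id, unit_type, unit_index, component, rule) {
  tibble::tibble(
    record_id = record_id, unit_type = unit_type,
    unit_index = as.integer(unit_index), component = component, rule = rule
  )
}

#' Validate a record against the instrument's range and branching rules
#'
#' Checks every present value against its scale and enforces the branching
#' logic: Plausibility present iff the diagnosis passed the accuracy gate,
#' Specificity present iff it passed the plausibility gate, Uncertainty
#' present iff an omission occurred (Omission below the scale maximum).
#' Violations are returned, never raised.
#'
#' @param rec A [record_annotation()].
#' @param cfg A [framework_config()].
#' @return A tibble with columns `record_id`, `unit_type`, `unit_index`,
#'   `component`, `rule`; zero rows iff the record is fully compliant.
#' @export
validate_record <- function(rec, cfg = framework_config()) {
  stopifnot(inherits(rec, "record_annotation"))
  out <- list()
  add <- function(v) out[[length(out) + 1L]] <<- v
  id <- rec$record_id

  if (length(rec$diagnoses) == 0 && !rec$empty_output) {
    add(violation_row(id, "output", NA, "diagnoses",
                      "no diagnoses and empty_output flag not set"))
  }

  for (i in seq_along(rec$diagnoses)) {
    d <- rec$diagnoses[[i]]
    if (is_absent(d$accuracy)) {
      add(violation_row(id, "diagnosis", i, "accuracy", "accuracy missing"))
      next
    }
    if (!in_scale(cfg, "accuracy", d$accuracy)) {
      add(violation_row(id, "diagnosis", i, "accuracy", "value out of scale"))
    }
    accurate <- !is_absent(d$accuracy) && d$accuracy >= cfg$accuracy_gate
    if (accurate && is_absent(d$plausibility)) {
      add(violation_row(id, "diagnosis", i, "plausibility",
                        "missing despite passing accuracy gate"))
    }
    if (!accurate && !is_absent(d$plausibility)) {
      add(violation_row(id, "diagnosis", i, "plausibility",
                        "present although accuracy gate failed"))
    }
    if (!is_absent(d$plausibility) && !in_scale(cfg, "plausibility", d$plausibility)) {
      add(violation_row(id, "diagnosis", i, "plausibility", "value out of scale"))
    }
    plausible <- !is_absent(d$plausibility) &&
      d$plausibility >= cfg$plausibility_gate
    if (plausible && is_absent(d$specificity)) {
      add(violation_row(id, "diagnosis", i, "specificity",
                        "missing despite passing plausibility gate"))
    }
    if (!plausible && !is_absent(d$specificity)) {
      add(violation_row(id, "diagnosis", i, "specificity",
                        "present although plausibility gate failed"))
    }
    if (!is_absent(d$specificity) && !in_scale(cfg, "specificity", d$specificity)) {
      add(violation_row(id, "diagnosis", i, "specificity", "value out of scale"))
    }
  }

  if (is_absent(rec$omission)) {
    add(violation_row(id, "output", NA, "omission", "omission missing"))
  } else {
    if (!in_scale(cfg, "omission", rec$omission)) {
      add(violation_row(id, "output", NA, "omission", "value out of scale"))
    }
    omitted <- rec$omission < cfg$no_omission_level
    if (omitted && is_absent(rec$uncertainty)) {
      add(violation_row(id, "output", NA, "uncertainty",
                        "missing although an omission occurred"))
    }
    if (!omitted && !is_absent(rec$uncertainty)) {
      add(violation_row(id, "output", NA, "uncertainty",
                        "present although no omission occurred"))
    }
    if (!is_absent(rec$uncertainty) && !in_scale(cfg, "uncertainty", rec$uncertainty)) {
      add(violation_row(id, "output", NA, "uncertainty", "value out of scale"))
    }
  }

  for (j in seq_along(rec$reasoning_sentences)) {
    s <- rec$reasoning_sentences[[j]]
    for (comp in c("comprehension", "rationale", "recall")) {
      v <- s[[comp]]
      if (is_absent(v) || !in_scale(cfg, comp, v)) {
        add(violation_row(id, "sentence", j, comp, "value missing or out of scale"))
      }
    }
  }

  if (is_absent(rec$reasoning_omission) ||
      !in_scale(cfg, "reasoning_omission", rec$reasoning_omission)) {
    add(violation_row(id, "output", NA, "reasoning_omission",
                      "value missing or out of scale"))
  }

  if (length(out) == 0) {
    violation_row(character(), character(), integer(), character(), character())
  } else {
    do.call(rbind, out)
  }
}

#' Impute branched-out values to zero
#'
#' Replaces every `NA` that is explained by the instrument's branching
#' logic with 0: Plausibility and Specificity of diagnoses that failed a
#' gate, and Uncertainty when no omission occurred.  Present values are
#' never touched.  An `NA` that branching cannot explain indicates a
#' corrupt export and raises an error.
#'
#' @inheritParams validate_record
#' @return The record with no absent values; idempotent.
#' @export
impute_branching <- function(rec, cfg = framework_config()) {
  stopifnot(inherits(rec, "record_annotation"))
  for (i in seq_along(rec$diagnoses)) {
    d <- rec$diagnoses[[i]]
    if (is_absent(d$accuracy)) {
      stop("record ", rec$record_id, ", diagnosis ", i,
           ": accuracy missing (not a branched item)")
    }
    accurate <- d$accuracy >= cfg$accuracy_gate
    if (is_absent(d$plausibility)) {
      if (accurate) {
        stop("record ", rec$record_id, ", diagnosis ", i,
             ": plausibility absent but accuracy gate passed")
      }
      d$plausibility <- 0
      if (!is_absent(d$specificity)) {
        stop("record ", rec$record_id, ", diagnosis ", i,
             ": specificity present under failed accuracy gate")
      }
      d$specificity <- 0
    }
    if (is_absent(d$specificity)) {
      if (d$plausibility >= cfg$plausibility_gate) {
        stop("record ", rec$record_id, ", diagnosis ", i,
             ": specificity absent but plausibility gate passed")
      }
      d$specificity <- 0
    }
    rec$diagnoses[[i]] <- d
  }
  if (is_absent(rec$omission)) {
    stop("record ", rec$record_id, ": omission missing (not a branched item)")
  }
  if (is_absent(rec$uncertainty)) {
    if (rec$omission < cfg$no_omission_level) {
      stop("record ", rec$record_id,
           ": uncertainty absent although an omission occurred")
    }
    rec$uncertainty <- 0
  }
  rec
}

#' Invert the reasoning components
#'
#' The raw reasoning ratings measure *evidence of a problem* (1 = none,
#' best), so they are transformed to `6 - x` before averaging, making
#' higher uniformly better.  The transform is an involution: applying it
#' twice restores the input.
#'
#' @param rec A [record_annotation()].
#' @return The record with comprehension, rationale and recall replaced by
#'   `6 - x`; all other fields untouched.
#' @export
invert_reasoning <- function(rec) {
  stopifnot(inherits(rec, "record_annotation"))
  for (j in seq_along(rec$reasoning_sentences)) {
    s <- rec$reasoning_sentences[[j]]
    for (comp in c("comprehension", "rationale", "recall")) {
      v <- s[[comp]]
      if (is_absent(v) || v < 1 || v > 5) {
        stop("record ", rec$record_id, ", sentence ", j, ": ", comp,
             " must be in 1..5 to invert")
      }
      s[[comp]] <- 6 - v
    }
    rec$reasoning_sentences[[j]] <- s
  }
  rec
}

#' Score one record: Diagnostic Accuracy and Diagnostic Reasoning
#'
#' Applies the full scoring pipeline — validate, impute branched `NA`s to
#' zero, invert the reasoning components — then averages:
#' \deqn{D_i = (\bar p_i + \bar s_i + \bar o_i) / 15, \qquad
#'       R_i = (\bar c_i + \bar e_i + \bar a_i) / 15}
#' where \eqn{\bar p_i, \bar s_i} are the mean plausibility and specificity
#' over *all* diagnoses (imputed zeros included), \eqn{\bar o_i} the mean
#' of the omission and (imputed) uncertainty ratings, and
#' \eqn{\bar c_i, \bar e_i, \bar a_i} the post-inversion means of
#' comprehension, recall and rationale.  Both composites lie in `[0, 1]`.
#'
#' Records with zero reasoning sentences receive `R = NA`; records flagged
#' `empty_output` score zero plausibility and specificity means.
#'
#' @inheritParams validate_record
#' @param validate If `TRUE` (default), error on any instrument violation;
#'   set `FALSE` to score a value-complete record mechanically (used for
#'   perturbation analyses).
#' @return One-row tibble: `record_id`, `n_diagnoses`, `n_sentences`,
#'   `p_bar`, `s_bar`, `o_bar`, `c_bar`, `e_bar`, `a_bar`, `D`, `R`.
#' @examples
#' rec <- record_annotation(
#'   "R001",
#'   diagnoses = list(
#'     diagnosis_item("sepsis", accuracy = 5, plausibility = 5, specificity = 4),
#'     diagnosis_item("fatigue", accuracy = 2)
#'   ),
#'   omission = 3, uncertainty = 4,
#'   reasoning_sentences = list(
#'     reasoning_sentence_item("...", comprehension = 1, rationale = 2, recall = 1)
#'   )
#' )
#' score_record(rec)
#' @export
score_record <- function(rec, cfg = framework_config(), validate = TRUE) {
  stopifnot(inherits(rec, "record_annotation"))
  if (validate) {
    v <- validate_record(rec, cfg)
    if (nrow(v) > 0) {
      stop("record ", rec$record_id, " has ", nrow(v),
           " instrument violation(s); first: ", v$component[1], " - ", v$rule[1])
    }
  }
  if (length(rec$diagnoses) == 0 && !rec$empty_output) {
    stop("record ", rec$record_id, ": no diagnoses and empty_output flag not set")
  }
  rec <- impute_branching(rec, cfg)
  rec <- invert_reasoning(rec)

  if (length(rec$diagnoses) > 0) {
    p_bar <- mean(vapply(rec$diagnoses, function(d) d$plausibility, numeric(1)))
    s_bar <- mean(vapply(rec$diagnoses, function(d) d$specificity, numeric(1)))
  } else {
    p_bar <- 0
    s_bar <- 0
  }
  o_bar <- mean(c(rec$omission, rec$uncertainty))

  n_sent <- length(rec$reasoning_sentences)
  if (n_sent > 0) {
    c_bar <- mean(vapply(rec$reasoning_sentences, function(s) s$comprehension, numeric(1)))
    e_bar <- mean(vapply(rec$reasoning_sentences, function(s) s$recall, numeric(1)))
    a_bar <- mean(vapply(rec$reasoning_sentences, function(s) s$rationale, numeric(1)))
    R <- (c_bar + e_bar + a_bar) / cfg$denominator
  } else {
    c_bar <- NA_real_
    e_bar <- NA_real_
    a_bar <- NA_real_
    R <- NA_real_
  }

  tibble::tibble(
    record_id = rec$record_id,
    n_diagnoses = length(rec$diagnoses),
    n_sentences = n_sent,
    p_bar = p_bar, s_bar = s_bar, o_bar = o_bar,
    c_bar = c_bar, e_bar = e_bar, a_bar = a_bar,
    D = (p_bar + s_bar + o_bar) / cfg$denominator,
    R = R
  )
}

component_frequencies <- function(records, cfg) {
  acc <- plaus <- spec <- numeric(0)
  om <- unc_epistemic <- reason_om <- logical(0)
  comp_raw <- rat_raw <- rec_raw <- numeric(0)
  for (rec in records) {
    for (d in rec$diagnoses) {
      acc <- c(acc, d$accuracy)
      plaus <- c(plaus, ifelse(is_absent(d$plausibility), 0, d$plausibility))
      spec <- c(spec, ifelse(is_absent(d$specificity), 0, d$specificity))
    }
    om <- c(om, rec$omission >= cfg$no_omission_level)
    unc_epistemic <- c(unc_epistemic,
                       !is_absent(rec$uncertainty) && rec$uncertainty <= 2)
    reason_om <- c(reason_om, isTRUE(rec$reasoning_omission >= 1))
    for (s in rec$reasoning_sentences) {
      comp_raw <- c(comp_raw, s$comprehension)
      rat_raw <- c(rat_raw, s$rationale)
      rec_raw <- c(rec_raw, s$recall)
    }
  }
  freq <- function(component, unit, flag) {
    tibble::tibble(component = component, unit = unit,
                   count = sum(flag), total = length(flag),
                   fraction = if (length(flag) > 0) mean(flag) else NA_real_)
  }
  spec_hi <- scale_max(cfg, "specificity") - 1
  rbind(
    freq("accurate", "diagnosis", acc >= cfg$accuracy_gate),
    freq("plausible", "diagnosis", plaus >= cfg$plausibility_gate),
    freq("specific", "diagnosis", spec >= spec_hi),
    freq("no_omission", "record", om),
    freq("epistemic_uncertainty", "record", unc_epistemic),
    freq("comprehension_clean", "sentence", comp_raw <= 2),
    freq("rationale_clean", "sentence", rat_raw <= 2),
    freq("recall_clean", "sentence", rec_raw <= 2),
    freq("reasoning_omitted", "record", reason_om)
  )
}

#' Score a cohort of annotated records
#'
#' Scores every record with [score_record()] and summarises the cohort:
#' median and interquartile range of the Diagnostic Accuracy and Diagnostic
#' Reasoning scores, plus per-component frequencies (fraction of diagnoses
#' accurate / plausible / specific, records without omission, records with
#' low-uncertainty "epistemic" omissions, sentences with little or no
#' evidence of incorrect comprehension / rationale / recall, records whose
#' reasoning lacked an explanation).  Records with zero reasoning sentences
#' are excluded from the R summary.
#'
#' @param records List of [record_annotation()]s.
#' @param cfg A [framework_config()].
#' @return A `cohort_scores` list: `scores` (tibble, one row per record),
#'   `summary` (tibble with median / IQR of D and R) and `components`
#'   (frequency tibble).
#' @export
score_cohort <- function(records, cfg = framework_config()) {
  if (length(records) == 0) stop("at least one record required")
  rows <- vector("list", length(records))
  for (i in seq_along(records)) {
    rows[[i]] <- tryCatch(
      score_record(records[[i]], cfg),
      error = function(e) {
        stop("scoring failed for record ", records[[i]]$record_id, ": ",
             conditionMessage(e), call. = FALSE)
      }
    )
  }
  scores <- do.call(rbind, rows)
  summarise_score <- function(x, label) {
    x <- x[!is.na(x)]
    tibble::tibble(
      score = label, n = length(x),
      median = stats::median(x),
      q25 = unname(stats::quantile(x, 0.25)),
      q75 = unname(stats::quantile(x, 0.75))
    )
  }
  n_no_reason <- sum(scores$n_sentences == 0)
  if (n_no_reason > 0) {
    message(n_no_reason,
            " record(s) have no reasoning sentences; excluded from the R summary")
  }
  structure(
    list(
      scores = scores,
      summary = rbind(
        summarise_score(scores$D, "diagnostic_accuracy"),
        summarise_score(scores$R, "diagnostic_reasoning")
      ),
      components = component_frequencies(records, cfg)
    ),
    class = "cohort_scores"
  )
}

#' @export
print.cohort_scores <- function(x, ...) {
  cat("<cohort_scores>", nrow(x$scores), "records\n")
  print(x$summary)
  invisible(x)
}
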