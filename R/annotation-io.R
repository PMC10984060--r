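# Readers and writers for annotation exports and scored tables.
#
# The long CSV format has one row per scored unit and component:
#   record_id, unit_type in {diagnosis, sentence, output}, unit_index,
#   component, value.
# Free text travels as component == "text" rows; branched-out values are
# written as empty cells and read back as NA ("NA" is also accepted).

annotation_rows <- function(rec) {
  rows <- list()
  add <- function(unit_type, unit_index, component, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      record_id = rec$record_id, unit_type = unit_type,
      unit_index = as.integer(unit_index), component = component,
      value = value, stringsAsFactors = FALSE
    )
  }
  fmt <- function(v) if (is_absent(v)) "" else format(v, scientific = FALSE)
  for (i in seq_along(rec$diagnoses)) {
    d <- rec$diagnoses[[i]]
    add("diagnosis", i, "text", d$diagnosis_text)
    add("diagnosis", i, "accuracy", fmt(d$accuracy))
    add("diagnosis", i, "plausibility", fmt(d$plausibility))
    add("diagnosis", i, "specificity", fmt(d$specificity))
  }
  for (j in seq_along(rec$reasoning_sentences)) {
    s <- rec$reasoning_sentences[[j]]
    add("sentence", j, "text", s$sentence_text)
    add("sentence", j, "comprehension", fmt(s$comprehension))
    add("sentence", j, "rationale", fmt(s$rationale))
    add("sentence", j, "recall", fmt(s$recall))
  }
  add("output", NA, "omission", fmt(rec$omission))
  add("output", NA, "uncertainty", fmt(rec$uncertainty))
  add("output", NA, "reasoning_omission", fmt(rec$reasoning_omission))
  if (rec$empty_output) add("output", NA, "empty_output", "1")
  do.call(rbind, rows)
}

#' Write annotation records to a long-format CSV
#'
#' @param records List of [record_annotation()]s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @seealso [read_annotations()] for the inverse; the round trip is
#'   lossless.
#' @export
write_annotations <- function(records, path) {
  tbl <- do.call(rbind, lapply(records, annotation_rows))
  utils::write.csv(tbl, path, row.names = FALSE, na = "")
  invisible(path)
}

parse_value <- function(x) {
  if (is.na(x) || x == "" || x == "NA") NA_real_ else as.numeric(x)
}

record_from_rows <- function(tbl) {
  id <- tbl$record_id[1]
  pick <- function(unit, idx, comp) {
    sel <- tbl$unit_type == unit & tbl$component == comp &
      (if (is.na(idx)) TRUE else !is.na(tbl$unit_index) & tbl$unit_index == idx)
    v <- tbl$value[sel]
    if (length(v) == 0) NA_character_ else v[1]
  }
  diag_idx <- sort(unique(tbl$unit_index[tbl$unit_type == "diagnosis"]))
  diagnoses <- lapply(diag_idx, function(i) {
    diagnosis_item(
      diagnosis_text = pick("diagnosis", i, "text"),
      accuracy = parse_value(pick("diagnosis", i, "accuracy")),
      plausibility = parse_value(pick("diagnosis", i, "plausibility")),
      specificity = parse_value(pick("diagnosis", i, "specificity"))
    )
  })
  sent_idx <- sort(unique(tbl$unit_index[tbl$unit_type == "sentence"]))
  sentences <- lapply(sent_idx, function(j) {
    reasoning_sentence_item(
      sentence_text = pick("sentence", j, "text"),
      comprehension = parse_value(pick("sentence", j, "comprehension")),
      rationale = parse_value(pick("sentence", j, "rationale")),
      recall = parse_value(pick("sentence", j, "recall"))
    )
  })
  empty_flag <- pick("output", NA, "empty_output")
  record_annotation(
    record_id = id,
    diagnoses = diagnoses,
    omission = parse_value(pick("output", NA, "omission")),
    uncertainty = parse_value(pick("output", NA, "uncertainty")),
    reasoning_sentences = sentences,
    reasoning_omission = parse_value(pick("output", NA, "reasoning_omission")),
    empty_output = !is.na(empty_flag) && empty_flag == "1"
  )
}

#' Read annotation records from a long-format CSV
#'
#' @param path CSV path written by [write_annotations()] (or an equivalent
#'   survey export).
#' @return List of [record_annotation()]s in file order.
#' @export
read_annotations <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(value = "character"))
  needed <- c("record_id", "unit_type", "unit_index", "component", "value")
  if (!all(needed %in% names(tbl))) {
    stop("annotation CSV must have columns: ", paste(needed, collapse = ", "))
  }
  ids <- unique(tbl$record_id)
  lapply(ids, function(id) record_from_rows(tbl[tbl$record_id == id, , drop = FALSE]))
}

record_to_list <- function(rec) {
  list(
    record_id = rec$record_id,
    diagnoses = lapply(rec$diagnoses, function(d) {
      list(diagnosis_text = d$diagnosis_text, accuracy = d$accuracy,
           plausibility = d$plausibility, specificity = d$specificity)
    }),
    omission = rec$omission,
    uncertainty = rec$uncertainty,
    reasoning_sentences = lapply(rec$reasoning_sentences, function(s) {
      list(sentence_text = s$sentence_text, comprehension = s$comprehension,
           rationale = s$rationale, recall = s$recall)
    }),
    reasoning_omission = rec$reasoning_omission,
    empty_output = rec$empty_output
  )
}

#' Write annotation records to nested JSON
#'
#' @inheritParams write_annotations
#' @return `path`, invisibly.
#' @export
write_annotations_json <- function(records, path) {
  jsonlite::write_json(lapply(records, record_to_list), path,
                       auto_unbox = TRUE, digits = NA, na = "null", null = "null")
  invisible(path)
}

#' Read annotation records from nested JSON
#'
#' @param path JSON path written by [write_annotations_json()].
#' @return List of [record_annotation()]s.
#' @export
read_annotations_json <- function(path) {
  raw <- jsonlite::read_json(path)
  num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  lapply(raw, function(r) {
    record_annotation(
      record_id = r$record_id,
      diagnoses = lapply(r$diagnoses, function(d) {
        diagnosis_item(d$diagnosis_text, num(d$accuracy),
                       num(d$plausibility), num(d$specificity))
      }),
      omission = num(r$omission),
      uncertainty = num(r$uncertainty),
      reasoning_sentences = lapply(r$reasoning_sentences, function(s) {
        reasoning_sentence_item(s$sentence_text, num(s$comprehension),
                                num(s$rationale), num(s$recall))
      }),
      reasoning_omission = num(r$reasoning_omission),
      empty_output = isTRUE(r$empty_output)
    )
  })
}

#' Write scored records to CSV
#'
#' @param scores Scores tibble from [score_cohort()] (the `$scores`
#'   element) or [score_record()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scored <- function(scores, path) {
  cols <- c("record_id", "p_bar", "s_bar", "o_bar",
            "c_bar", "e_bar", "a_bar", "D", "R")
  utils::write.csv(as.data.frame(scores)[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}
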