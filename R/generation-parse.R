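# Parser for the LLM output dialect: diagnoses separated by `#`, followed
# by a reasoning section introduced by the first `<Reasoning>` marker.

#' Parse a raw generation string
#'
#' Text before the first `<Reasoning>` marker is split on `#`, trimmed,
#' and empty segments dropped; the remainder (marker stripped) is the
#' reasoning text.  Later `<Reasoning>` occurrences belong to the
#' reasoning text.  A missing marker parses the whole string as diagnoses
#' with empty reasoning and a warning.
#'
#' @param raw Character scalar, the model's raw output.
#' @return List with `diagnoses` (character vector) and `reasoning`
#'   (character scalar).
#' @examples
#' parse_generation("sepsis # pneumonia # AKI <Reasoning> because ...")
#' @export
parse_generation <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (is.na(raw) || !nzchar(trimws(raw))) {
    stop("empty generation: nothing to parse")
  }
  marker <- regexpr("<Reasoning>", raw, fixed = TRUE)
  if (marker == -1L) {
    warning("no <Reasoning> marker found; whole text parsed as diagnoses")
    head_txt <- raw
    reasoning <- ""
  } else {
    head_txt <- substr(raw, 1L, marker - 1L)
    reasoning <- trimws(substr(raw, marker + attr(marker, "match.length"),
                               nchar(raw)))
  }
  segs <- trimws(strsplit(head_txt, "#", fixed = TRUE)[[1]])
  list(diagnoses = segs[nzchar(segs)], reasoning = reasoning)
}

read_tsv_lines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  tab <- regexpr("\t", lines, fixed = TRUE)
  if (any(tab == -1L)) stop("malformed line (no tab) in ", path)
  tibble::tibble(
    record_id = substr(lines, 1L, tab - 1L),
    text = substring(lines, tab + 1L)
  )
}

#' Read generation texts from a tab-separated file
#'
#' One record per line: `record_id<TAB>raw generation`.  Each generation
#' is parsed with [parse_generation()].
#'
#' @param path Input path.
#' @return Tibble: `record_id`, `candidate` (diagnoses re-joined with
#'   `" # "`), `n_diagnoses`, `reasoning`, `raw`.
#' @export
read_generations <- function(path) {
  tbl <- read_tsv_lines(path)
  parsed <- lapply(tbl$text, parse_generation)
  tibble::tibble(
    record_id = tbl$record_id,
    candidate = vapply(parsed, function(p) paste(p$diagnoses, collapse = " # "),
                       character(1)),
    n_diagnoses = vapply(parsed, function(p) length(p$diagnoses), integer(1)),
    reasoning = vapply(parsed, function(p) p$reasoning, character(1)),
    raw = tbl$text
  )
}

#' Read reference diagnosis lists
#'
#' Same line format as [read_generations()]; the text is a `#`-separated
#' diagnosis list without a reasoning section.
#'
#' @param path Input path.
#' @return Tibble: `record_id`, `reference`.
#' @export
read_references <- function(path) {
  tbl <- read_tsv_lines(path)
  refs <- vapply(tbl$text, function(t) {
    segs <- trimws(strsplit(t, "#", fixed = TRUE)[[1]])
    paste(segs[nzchar(segs)], collapse = " # ")
  }, character(1))
  tibble::tibble(record_id = tbl$record_id, reference = unname(refs))
}

#' Build candidate/reference pairs for the metric suite
#'
#' Joins parsed generations with references on `record_id`; the diagnosis
#' lists are scored at the output level, joined into one text per record.
#'
#' @param generations Tibble from [read_generations()] (or the
#'   `generations` element of a synthetic cohort).
#' @param references Tibble from [read_references()]; may be `NULL` when
#'   `generations` already carries a `reference` column.
#' @param sep Separator used to join multi-diagnosis lists into one text.
#' @return Tibble: `pair_id`, `candidate`, `reference`.
#' @export
generation_pairs <- function(generations, references = NULL, sep = " ; ") {
  if (is.null(references)) {
    stopifnot("reference" %in% names(generations))
    merged <- generations
  } else {
    merged <- merge(as.data.frame(generations), as.data.frame(references),
                    by = "record_id")
  }
  join <- function(txt) {
    segs <- trimws(strsplit(txt, "#", fixed = TRUE)[[1]])
    paste(segs[nzchar(segs)], collapse = sep)
  }
  tibble::tibble(
    pair_id = merged$record_id,
    candidate = vapply(merged$candidate, join, character(1), USE.NAMES = FALSE),
    reference = vapply(merged$reference, join, character(1), USE.NAMES = FALSE)
  )
}
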