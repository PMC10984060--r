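#' Default Likert scale definitions for the annotation instrument
#'
#' Accuracy, Plausibility and the three reasoning components use the common
#' 1--5 agreement scale; Specificity, Omission and Uncertainty start at 0
#' (the zero is also the value branched-out items are imputed to); the
#' output-level reasoning Omission is a binary decision.
#'
#' @return Named list of `c(min, max)` integer vectors, one per component.
#' @export
default_scales <- function() {
  list(
    accuracy           = c(min = 1, max = 5),
    plausibility       = c(min = 1, max = 5),
    specificity        = c(min = 0, max = 5),
    omission           = c(min = 0, max = 5),
    uncertainty        = c(min = 0, max = 5),
    comprehension      = c(min = 1, max = 5),
    rationale          = c(min = 1, max = 5),
    recall             = c(min = 1, max = 5),
    reasoning_omission = c(min = 0, max = 1)
  )
}

#' Configuration of the human evaluation framework
#'
#' Collects the scale definitions, branching gates and inversion set that
#' define how raw annotation exports are validated, imputed and combined
#' into the composite Diagnostic Accuracy (D) and Diagnostic Reasoning (R)
#' scores.
#'
#' The branching instrument scores Plausibility only for diagnoses judged
#' accurate and Specificity only for plausible ones; Uncertainty is scored
#' only when an omission occurred.  A diagnosis "classified as accurate" is
#' taken to mean an Accuracy rating at or above `accuracy_gate` (the
#' agreement region of the Likert scale), and likewise for
#' `plausibility_gate`.  "No omission occurred" corresponds to the maximum
#' of the Omission scale.
#'
#' @param accuracy_gate Minimum Accuracy rating for a diagnosis to count as
#'   accurate (default 4, i.e. Agree / Strongly Agree).
#' @param plausibility_gate Minimum Plausibility rating for a diagnosis to
#'   count as plausible (default 4).
#' @param inverted Character vector of components whose raw ratings mean
#'   the opposite of quality (1 = no evidence of a problem) and are
#'   therefore transformed to `6 - x` before averaging.
#' @param scales Named list of `c(min, max)` vectors, one per component;
#'   see [default_scales()].
#' @param denominator Normalising constant of the composite scores;
#'   15 = three component means, each at most 5.
#' @return An object of class `framework_config`.
#' @examples
#' cfg <- framework_config()
#' cfg$accuracy_gate
#' @export
framework_config <- function(accuracy_gate = 4,
                             plausibility_gate = 4,
                             inverted = c("comprehension", "rationale", "recall"),
                             scales = default_scales(),
                             denominator = 15) {
  stopifnot(is_scalar_number(accuracy_gate), is_scalar_number(plausibility_gate),
            is_scalar_number(denominator), denominator > 0)
  required <- names(default_scales())
  missing <- setdiff(required, names(scales))
  if (length(missing) > 0) {
    stop("scales must define every instrument component; missing: ",
         paste(missing, collapse = ", "))
  }
  for (nm in names(scales)) {
    sc <- scales[[nm]]
    if (length(sc) != 2 || any(is.na(sc)) || sc[["min"]] >= sc[["max"]]) {
      stop("invalid scale for component '", nm, "'")
    }
  }
  if (!all(inverted %in% names(scales))) {
    stop("inverted components must have scale definitions")
  }
  structure(
    list(
      accuracy_gate = accuracy_gate,
      plausibility_gate = plausibility_gate,
      inverted = inverted,
      scales = scales,
      denominator = denominator,
      no_omission_level = unname(scales$omission[["max"]])
    ),
    class = "framework_config"
  )
}

#' @export
print.framework_config <- function(x, ...) {
  cat("<framework_config>\n")
  cat("  accuracy gate >=", x$accuracy_gate,
      "| plausibility gate >=", x$plausibility_gate, "\n")
  cat("  inverted components:", paste(x$inverted, collapse = ", "), "\n")
  cat("  no-omission level:", x$no_omission_level,
      "| denominator:", x$denominator, "\n")
  invisible(x)
}

scale_min <- function(cfg, component) unname(cfg$scales[[component]][["min"]])
scale_max <- function(cfg, component) unname(cfg$scales[[component]][["max"]])

in_scale <- function(cfg, component, value) {
  !is.na(value) && value >= scale_min(cfg, component) &&
    value <= scale_max(cfg, component)
}
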