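#' Default tokenizer for text-overlap metrics
#'
#' Lowercases, replaces punctuation by spaces and splits on whitespace.
#' Backends may supply their own tokenizer; this one is deliberately
#' simple since the texts being compared are short diagnosis strings.
#'
#' @param text Character scalar.
#' @param lowercase Fold case before splitting.
#' @param strip_punct Replace punctuation with spaces before splitting.
#' @return Character vector of tokens (length 0 for empty input).
#' @examples
#' tokenize("Sepsis, from influenza-pneumonia")
#' @export
tokenize <- function(text, lowercase = TRUE, strip_punct = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text)) return(character(0))
  if (lowercase) text <- tolower(text)
  if (strip_punct) text <- gsub("[[:punct:]]", " ", text)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}
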