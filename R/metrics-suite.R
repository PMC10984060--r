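# Metric registry and suite runner: one row per (pair, metric), with
# missing backends skipped loudly rather than silently zeroed.

registry_entry <- function(fn, backend_id, available = TRUE, note = NULL) {
  list(fn = fn, backend_id = backend_id, available = available, note = note)
}

#' External-adapter metric
#'
#' Wraps a user-supplied function `(candidate, reference) -> numeric` as a
#' registry entry.  This is the integration point for learned-regression
#' metrics (COMET- or BLEURT-style models) which are never reimplemented
#' here: the adapter calls out to whatever produces the float.
#'
#' @param name Metric name used in result rows.
#' @param fn Function of `(candidate, reference)` returning a numeric
#'   scalar, or `NULL` to register the metric as unavailable.
#' @param backend_id Identifier recorded in result rows.
#' @return A registry entry for [run_metric_suite()].
#' @export
adapter_metric <- function(name, fn = NULL, backend_id = "external-adapter") {
  if (is.null(fn)) {
    return(registry_entry(NULL, backend_id, available = FALSE,
                          note = paste0("adapter '", name, "' has no bound function")))
  }
  stopifnot(is.function(fn))
  registry_entry(
    function(candidate, reference, pair_id) {
      metric_score(pair_id, name, as.numeric(fn(candidate, reference)),
                   backend_id = backend_id)
    },
    backend_id
  )
}

#' Default metric registry
#'
#' Builds the bundled metric set: `rouge_l` always; `embed_greedy` over a
#' hashed-projection embedding provider; `logprob` over the bigram scorer;
#' and, when a lexicon is supplied, `concept_f` (dictionary extraction)
#' and `graph_embed_f` (hashed concept embeddings).  Additional entries
#' (e.g. [adapter_metric()]s or providers wrapping real clinical encoders)
#' can be appended by name.
#'
#' @param lexicon Optional lexicon data frame (`surface`, `cui`) enabling
#'   the concept metrics.
#' @param embedding_dim Dimension of the toy embedding backends.
#' @param seed Seed for the hashed embedding backends.
#' @param extra Named list of additional registry entries.
#' @return Named list of registry entries.
#' @export
metric_registry <- function(lexicon = NULL, embedding_dim = 32, seed = 0,
                            extra = list()) {
  reg <- list(
    rouge_l = registry_entry(
      function(candidate, reference, pair_id) {
        rouge_l(candidate, reference, pair_id)
      }, "lcs"),
    embed_greedy = local({
      prov <- hash_embedding_provider(embedding_dim, seed)
      registry_entry(
        function(candidate, reference, pair_id) {
          greedy_match_fscore(candidate, reference, prov, pair_id)
        }, prov$id)
    }),
    logprob = local({
      sc <- bigram_scorer()
      registry_entry(
        function(candidate, reference, pair_id) {
          logprob_score(candidate, reference, sc, pair_id)
        }, sc$id)
    })
  )
  if (!is.null(lexicon)) {
    ex <- dictionary_extractor(lexicon)
    ce <- hash_concept_embedder(embedding_dim, seed + 1)
    reg$concept_f <- registry_entry(
      function(candidate, reference, pair_id) {
        concept_fscore(candidate, reference, ex, pair_id)
      }, ex$id)
    reg$graph_embed_f <- registry_entry(
      function(candidate, reference, pair_id) {
        graph_embedding_fscore(candidate, reference, ex, ce, pair_id)
      }, paste0(ex$id, "+graph"))
  }
  for (nm in names(extra)) reg[[nm]] <- extra[[nm]]
  reg
}

#' Load a metric registry from a YAML or JSON config
#'
#' The config maps metric names to a backend `type` plus parameters.
#' Supported types: `rouge_l`; `embedding` (`dim`, `seed`);
#' `onehot_embedding` (`vocab`); `concept` and `graph_embedding`
#' (`lexicon`: path to a CSV with `surface`, `cui`; graph additionally
#' `dim`, `seed`); `logprob_bigram`; `logprob_uniform` (`vocab_size`);
#' `adapter` (registered unavailable until a function is bound in code).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` registry config.
#' @return Named list of registry entries for [run_metric_suite()].
#' @export
read_metric_registry <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  load_lexicon <- function(spec) {
    utils::read.csv(spec$lexicon, stringsAsFactors = FALSE)
  }
  reg <- list()
  for (nm in names(cfg)) {
    spec <- cfg[[nm]]
    type <- spec$type %||% stop("metric '", nm, "' has no type")
    reg[[nm]] <- switch(
      type,
      rouge_l = registry_entry(
        function(candidate, reference, pair_id) rouge_l(candidate, reference, pair_id),
        "lcs"),
      embedding = local({
        prov <- hash_embedding_provider(spec$dim %||% 32, spec$seed %||% 0)
        registry_entry(function(candidate, reference, pair_id) {
          greedy_match_fscore(candidate, reference, prov, pair_id)
        }, prov$id)
      }),
      onehot_embedding = local({
        prov <- onehot_provider(unlist(spec$vocab))
        registry_entry(function(candidate, reference, pair_id) {
          greedy_match_fscore(candidate, reference, prov, pair_id)
        }, prov$id)
      }),
      concept = local({
        ex <- dictionary_extractor(load_lexicon(spec))
        registry_entry(function(candidate, reference, pair_id) {
          concept_fscore(candidate, reference, ex, pair_id)
        }, ex$id)
      }),
      graph_embedding = local({
        ex <- dictionary_extractor(load_lexicon(spec))
        ce <- hash_concept_embedder(spec$dim %||% 32, spec$seed %||% 1)
        registry_entry(function(candidate, reference, pair_id) {
          graph_embedding_fscore(candidate, reference, ex, ce, pair_id)
        }, paste0(ex$id, "+graph"))
      }),
      logprob_bigram = local({
        sc <- bigram_scorer()
        registry_entry(function(candidate, reference, pair_id) {
          logprob_score(candidate, reference, sc, pair_id)
        }, sc$id)
      }),
      logprob_uniform = local({
        sc <- uniform_scorer(spec$vocab_size %||% 100)
        registry_entry(function(candidate, reference, pair_id) {
          logprob_score(candidate, reference, sc, pair_id)
        }, sc$id)
      }),
      adapter = adapter_metric(nm, fn = NULL,
                               backend_id = spec$backend_id %||% "external-adapter"),
      stop("unknown backend type '", type, "' for metric '", nm, "'")
    )
  }
  reg
}

#' Run a suite of metrics over candidate/reference pairs
#'
#' @param pairs Data frame with columns `pair_id`, `candidate`,
#'   `reference`.
#' @param registry Named list of registry entries, e.g. from
#'   [metric_registry()] or [read_metric_registry()].
#' @param metrics Optional character vector restricting the suite; unknown
#'   names raise an error listing the available metrics.
#' @return Tibble with one row per (pair, metric): `pair_id`,
#'   `metric_name`, `precision`, `recall`, `value`, `backend_id`.
#'   Unavailable backends are skipped with a warning, never silently
#'   zeroed.
#' @export
run_metric_suite <- function(pairs, registry = metric_registry(),
                             metrics = NULL) {
  stopifnot(all(c("pair_id", "candidate", "reference") %in% names(pairs)))
  if (!is.null(metrics)) {
    unknown <- setdiff(metrics, names(registry))
    if (length(unknown) > 0) {
      stop("unknown metric(s): ", paste(unknown, collapse = ", "),
           "; available: ", paste(names(registry), collapse = ", "))
    }
    registry <- registry[metrics]
  }
  rows <- list()
  for (nm in names(registry)) {
    entry <- registry[[nm]]
    if (!isTRUE(entry$available)) {
      warning("metric '", nm, "' skipped: ",
              entry$note %||% "backend unavailable")
      next
    }
    for (k in seq_len(nrow(pairs))) {
      rows[[length(rows) + 1L]] <- entry$fn(pairs$candidate[k],
                                            pairs$reference[k],
                                            pairs$pair_id[k])
    }
  }
  if (length(rows) == 0) {
    return(metric_score(character(0), character(0), numeric(0))[0, ])
  }
  do.call(rbind, rows)
}

#' Write a metric table to CSV
#'
#' @param metric_table Tibble from [run_metric_suite()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(metric_table, path) {
  utils::write.csv(as.data.frame(metric_table), path, row.names = FALSE, na = "")
  invisible(path)
}
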