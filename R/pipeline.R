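#' @keywords internal
"_PACKAGE"

# model name -> expansion configuration; the hroc1/2/3 variants differ only
# by normalization, the hroc_ap1/2/3 variants use norm1 with an adaptive
# window
.expansion_models <- c("rocchio", "hroc1", "hroc2", "hroc3",
                       "hroc_ap1", "hroc_ap2", "hroc_ap3")

.config_for_model <- function(model, config) {
  switch(model,
    hroc1 = { config$norm_method <- "norm1"; config },
    hroc2 = { config$norm_method <- "norm2"; config },
    hroc3 = { config$norm_method <- "norm3"; config },
    hroc_ap1 = { config$norm_method <- "norm1"
                 config$window <- window_spec("adaptive", variant = "f1"); config },
    hroc_ap2 = { config$norm_method <- "norm1"
                 config$window <- window_spec("adaptive", variant = "f2"); config },
    hroc_ap3 = { config$norm_method <- "norm1"
                 config$window <- window_spec("adaptive", variant = "f3"); config },
    config)
}

#' Full pseudo-relevance-feedback search for one query
#'
#' First-pass retrieval, feedback-set selection (top `n_feedback_docs`
#' documents), query expansion with the chosen model, and a BM25 second pass
#' with the expanded weights as fractional query term frequencies.
#'
#' @param index a `corpus_index`.
#' @param query the original [weighted_query()].
#' @param model one of `"rocchio"`, `"hroc1"`, `"hroc2"`, `"hroc3"`,
#'   `"hroc_ap1"`, `"hroc_ap2"`, `"hroc_ap3"`.
#' @param config an [hroc_config()]; for the norm/window-specific models the
#'   relevant fields are overridden accordingly.
#' @param first_model first-pass model, `"bm25"` (default) or `"dirichlet"`.
#' @param first_params parameters for the first pass (`NULL`: `config$bm25`
#'   for BM25, defaults for Dirichlet).
#' @param rocchio_alpha,rocchio_beta Rocchio mixing weights (defaults 1 and
#'   `config$beta`); only used when `model = "rocchio"`.
#' @param cutoff rank cutoff of the final ranking (default 1000).
#' @return list with `run` (the final run data frame), `expanded` (the
#'   expanded [weighted_query()]), `first_pass` (the first-pass run) and
#'   `feedback_docs`.
#' @export
expand_search <- function(index, query, model = "hroc1",
                          config = hroc_config(), first_model = "bm25",
                          first_params = NULL, rocchio_alpha = 1,
                          rocchio_beta = NULL, cutoff = 1000) {
  model <- match.arg(model, .expansion_models)
  config <- .config_for_model(model, config)
  if (is.null(first_params) && first_model == "bm25") {
    first_params <- config$bm25
  }
  first <- retrieve(index, query, model = first_model, params = first_params,
                    cutoff = cutoff)
  feedback <- utils::head(first$doc_id, config$n_feedback_docs)
  if (!length(feedback)) {
    return(list(run = first, expanded = query, first_pass = first,
                feedback_docs = character()))
  }
  expanded <- if (model == "rocchio") {
    if (is.null(rocchio_beta)) rocchio_beta <- config$beta
    rocchio_expand(index, query, feedback, alpha = rocchio_alpha,
                   beta = rocchio_beta, n_terms = config$n_expansion_terms,
                   params = config$bm25, idf_scheme = config$idf_scheme)
  } else {
    hroc_expand(index, query, feedback, config)
  }
  run <- second_pass(index, expanded, params = config$bm25, cutoff = cutoff)
  list(run = run, expanded = expanded, first_pass = first,
       feedback_docs = feedback)
}

#' Run a set of topics through a retrieval model
#'
#' Applies first-pass retrieval (`model` in `"bm25"`, `"dirichlet"`) or a
#' full PRF pipeline (expansion models, see [expand_search()]) to every
#' topic and row-binds the per-topic rankings into one run.
#'
#' @param index a `corpus_index`.
#' @param topics list of topics as from [read_topics()], or a list of
#'   [weighted_query()] objects.
#' @param model retrieval or expansion model name.
#' @param config an [hroc_config()].
#' @param field topic field used to seed the query (see [query_from_topic()]).
#' @param analyzer a [text_analyzer()].
#' @param cutoff rank cutoff per topic.
#' @param ... passed on to [expand_search()] for expansion models.
#' @return a run data frame covering all topics.
#' @export
run_topics <- function(index, topics, model = "bm25",
                       config = hroc_config(), field = NULL,
                       analyzer = text_analyzer(), cutoff = 1000, ...) {
  queries <- lapply(topics, function(tp) {
    if (inherits(tp, "weighted_query")) tp
    else query_from_topic(tp, field = field, analyzer = analyzer)
  })
  runs <- lapply(queries, function(q) {
    if (model %in% c("bm25", "dirichlet")) {
      params <- if (model == "bm25") config$bm25 else dirichlet_params()
      retrieve(index, q, model = model, params = params, cutoff = cutoff)
    } else {
      expand_search(index, q, model = model, config = config,
                    cutoff = cutoff, ...)$run
    }
  })
  do.call(rbind, runs)
}

#' Index a corpus from disk and persist it
#'
#' Reads a corpus (directory of `*.txt` or JSON-lines), analyzes it and
#' writes the index next to a small JSON manifest capturing the inputs and
#' configuration, so every produced artifact can be traced to its run.
#'
#' @param corpus_path corpus location (see [read_corpus()]).
#' @param index_path output index file.
#' @param analyzer a [text_analyzer()].
#' @return the `corpus_index`, invisibly.
#' @export
cmd_index <- function(corpus_path, index_path, analyzer = text_analyzer()) {
  texts <- read_corpus(corpus_path)
  index <- index_corpus(texts, analyzer)
  save_index(index, index_path)
  .write_manifest(paste0(index_path, ".manifest.json"),
                  list(command = "index", corpus = corpus_path,
                       n_docs = index$n_docs, stopwords = analyzer$stopwords,
                       stem = analyzer$stem))
  invisible(index)
}

#' First-pass search to a TREC run file
#'
#' @param index_path path of a saved index.
#' @param topics_path topics file.
#' @param run_path output run file.
#' @param model `"bm25"` or `"dirichlet"`.
#' @param config an [hroc_config()].
#' @param field,tag,cutoff see [run_topics()] and [write_run()].
#' @return the run data frame, invisibly.
#' @export
cmd_search <- function(index_path, topics_path, run_path, model = "bm25",
                       config = hroc_config(), field = NULL, tag = model,
                       cutoff = 1000) {
  index <- load_index(index_path)
  topics <- read_topics(topics_path)
  run <- run_topics(index, topics, model = model, config = config,
                    field = field, cutoff = cutoff)
  write_run(run, run_path, tag = tag)
  .write_manifest(paste0(run_path, ".manifest.json"),
                  list(command = "search", index = index_path,
                       topics = topics_path, model = model, cutoff = cutoff))
  invisible(run)
}

#' Full PRF pipeline to a TREC run file
#'
#' @inheritParams cmd_search
#' @param model an expansion model (see [expand_search()]).
#' @param explain_path optional TSV path; when given, the per-topic
#'   [feedback_term_table()] is appended there (column `topic_id` first).
#' @return the run data frame, invisibly.
#' @export
cmd_expand_search <- function(index_path, topics_path, run_path,
                              model = "hroc1", config = hroc_config(),
                              field = NULL, tag = model, cutoff = 1000,
                              explain_path = NULL) {
  model <- match.arg(model, .expansion_models)
  index <- load_index(index_path)
  topics <- read_topics(topics_path)
  cfg <- .config_for_model(model, config)
  runs <- list(); tables <- list()
  for (tp in topics) {
    q <- query_from_topic(tp, field = field)
    res <- expand_search(index, q, model = model, config = config,
                         cutoff = cutoff)
    runs[[tp$topic_id]] <- res$run
    if (!is.null(explain_path) && length(res$feedback_docs)) {
      tab <- feedback_term_table(index, q, res$feedback_docs, cfg)
      tables[[tp$topic_id]] <- cbind(topic_id = tp$topic_id, tab)
    }
  }
  run <- do.call(rbind, runs)
  write_run(run, run_path, tag = tag)
  if (!is.null(explain_path) && length(tables)) {
    utils::write.table(do.call(rbind, tables), explain_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  .write_manifest(paste0(run_path, ".manifest.json"),
                  list(command = "expand-search", index = index_path,
                       topics = topics_path, model = model,
                       alpha = config$alpha, beta = config$beta,
                       n_feedback_docs = config$n_feedback_docs,
                       n_expansion_terms = config$n_expansion_terms,
                       window_mode = cfg$window$mode, D = cfg$window$D,
                       window_variant = cfg$window$variant,
                       norm_method = cfg$norm_method, cutoff = cutoff))
  invisible(run)
}

#' Evaluate a run file against a qrels file
#'
#' Writes per-topic metrics as TSV and the means as JSON; topics present in
#' the run but unjudged are dropped with a warning listing them.
#'
#' @param run_path TREC run file.
#' @param qrels_path TREC qrels file.
#' @param out_prefix output prefix; writes `<prefix>.per_topic.tsv` and
#'   `<prefix>.means.json`.
#' @param cutoff,ks see [evaluate_run()].
#' @return the `metric_report`, invisibly.
#' @export
cmd_eval <- function(run_path, qrels_path, out_prefix, cutoff = 1000,
                     ks = c(5, 10, 20)) {
  run <- read_run(run_path)
  qr <- read_qrels(qrels_path)
  dropped <- setdiff(unique(run$topic_id),
                     unique(qr$topic_id[qr$grade > 0]))
  if (length(dropped)) {
    warning("topics without judgments removed: ",
            paste(dropped, collapse = ", "))
  }
  report <- suppressWarnings(evaluate_run(run, qr, cutoff = cutoff, ks = ks))
  utils::write.table(report$per_topic, paste0(out_prefix, ".per_topic.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(as.list(round(report$means, 6)),
                       paste0(out_prefix, ".means.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(report)
}

.write_manifest <- function(path, fields) {
  fields$package_version <- as.character(utils::packageVersion("hroc"))
  fields$timestamp <- format(Sys.time(), tz = "UTC", usetz = TRUE)
  jsonlite::write_json(fields, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}
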