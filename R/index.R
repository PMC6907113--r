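#' Build a positional inverted index
#'
#' Constructs the corpus statistics every scoring formula needs: postings
#' with within-document term frequencies and 0-based token positions, the
#' number of indexed documents N, document frequencies df, the average
#' document length avdl, and collection term frequencies (for the Dirichlet
#' collection model). The analyzed token streams themselves are retained so
#' that sliding-window proximity weights can be computed over feedback
#' documents without re-reading the corpus.
#'
#' @param docs named list; each element is the character vector of analyzed
#'   tokens of one document, named by its document id. An empty token vector
#'   is a valid (empty) document.
#' @return an object of class `corpus_index` with elements `postings`
#'   (term -> list of `doc_id`, `tf`, `positions`), `docs`, `dl`, `n_docs`,
#'   `df`, `avg_dl`, `cf` (collection term frequency) and `total_tokens`.
#' @export
#' @examples
#' idx <- build_index(list(d1 = c("a", "b", "a"), d2 = c("b", "c")))
#' idx$df[["a"]]
#' idx$avg_dl
build_index <- function(docs) {
  stopifnot(is.list(docs))
  ids <- names(docs)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every document must be named by a non-empty doc_id")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate doc_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  postings <- new.env(parent = emptyenv())
  dl <- integer(length(docs))
  names(dl) <- ids
  for (id in ids) {
    toks <- docs[[id]]
    stopifnot(is.character(toks))
    dl[[id]] <- length(toks)
    if (!length(toks)) next
    pos_by_term <- split(seq_along(toks) - 1L, toks)
    for (term in names(pos_by_term)) {
      p <- postings[[term]]
      if (is.null(p)) p <- list(doc_id = character(), tf = integer(), positions = list())
      pos <- pos_by_term[[term]]
      p$doc_id <- c(p$doc_id, id)
      p$tf <- c(p$tf, length(pos))
      p$positions <- c(p$positions, list(pos))
      postings[[term]] <- p
    }
  }
  postings <- as.list(postings)
  df <- vapply(postings, function(p) length(p$doc_id), integer(1))
  cf <- vapply(postings, function(p) sum(p$tf), numeric(1))
  structure(list(
    postings = postings,
    docs = docs,
    dl = dl,
    n_docs = length(docs),
    df = df,
    avg_dl = if (length(docs)) mean(dl) else 0,
    cf = cf,
    total_tokens = sum(dl)
  ), class = "corpus_index")
}

#' Index a raw-text corpus
#'
#' Convenience wrapper: tokenizes each text with the given analyzer and
#' builds the index.
#'
#' @param texts named character vector or named list of character scalars
#'   (names are document ids).
#' @param analyzer a [text_analyzer()].
#' @return a `corpus_index`.
#' @export
index_corpus <- function(texts, analyzer = text_analyzer()) {
  texts <- as.list(texts)
  build_index(lapply(texts, tokenize, analyzer = analyzer))
}

#' @export
print.corpus_index <- function(x, ...) {
  cat(sprintf("<corpus_index> %d docs, %d terms, avg dl %.2f\n",
              x$n_docs, length(x$postings), x$avg_dl))
  invisible(x)
}

#' Inverse document frequency
#'
#' The BM25-consistent form `log((N - df + 0.5) / (df + 0.5))`, floored at
#' zero so that terms occurring in more than half the collection contribute
#' nothing rather than a negative weight; or the plain `log(N / df)` form.
#' Terms absent from the collection get 0 under the default `unseen = "zero"`
#' policy, or the maximal value (df treated as 0 / as 1 for plain) under
#' `unseen = "max"`.
#'
#' @param index a `corpus_index`.
#' @param terms character vector of analyzed terms.
#' @param scheme `"bm25"` (default) or `"plain"`.
#' @param unseen policy for df = 0 terms: `"zero"` (default) or `"max"`.
#' @return numeric vector of non-negative idf values, named by term.
#' @export
idf <- function(index, terms, scheme = c("bm25", "plain"),
                unseen = c("zero", "max")) {
  scheme <- match.arg(scheme)
  unseen <- match.arg(unseen)
  stopifnot(inherits(index, "corpus_index"))
  df <- index$df[terms]
  df[is.na(df)] <- 0L
  N <- index$n_docs
  if (any(df > N)) stop("inconsistent statistics: df > N")
  out <- if (scheme == "bm25") {
    pmax(0, log((N - df + 0.5) / (df + 0.5)))
  } else {
    ifelse(df > 0, log(N / pmax(df, 1)), 0)
  }
  if (unseen == "max") {
    mx <- if (scheme == "bm25") log((N + 0.5) / 0.5) else log(N)
    out[df == 0] <- mx
  } else {
    out[df == 0] <- 0
  }
  names(out) <- terms
  out
}

#' Term frequency and positions of a term in one document
#'
#' @param index a `corpus_index`.
#' @param term analyzed term.
#' @param doc_id document id.
#' @return list with `tf` (integer) and `positions` (0-based integer vector);
#'   `tf = 0` and empty positions when the term does not occur.
#' @export
term_stats <- function(index, term, doc_id) {
  p <- index$postings[[term]]
  if (!is.null(p)) {
    i <- match(doc_id, p$doc_id)
    if (!is.na(i)) return(list(tf = p$tf[[i]], positions = p$positions[[i]]))
  }
  list(tf = 0L, positions = integer())
}

# current on-disk index layout version
.index_format_version <- 1L

#' Persist / load an index
#'
#' The index is written as a versioned RDS file; [load_index()] refuses
#' files written by a different layout version.
#'
#' @param index a `corpus_index`.
#' @param path file path.
#' @return `save_index`: the path, invisibly. `load_index`: a `corpus_index`.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "corpus_index"))
  saveRDS(list(format = "hroc_index", version = .index_format_version,
               index = index), path)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  if (!file.exists(path)) stop("no such index file: ", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "hroc_index")) {
    stop("not an index file: ", path)
  }
  if (!identical(obj$version, .index_format_version)) {
    stop("index format version ", obj$version, " unsupported")
  }
  obj$index
}
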