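#' Okapi BM25 parameters
#'
#' `k1` controls within-document term-frequency saturation, `b` the degree of
#' document-length normalization, and `k3` the within-query term-frequency
#' saturation. Defaults follow common practice for this family of models:
#' `k1 = 1.2`, `k3 = 8`, `b = 0.5`.
#'
#' The standard Okapi query-side factor is `(k3 + 1) * qtf / (k3 + qtf)`.
#' Some presentations misprint the denominator as `k3 * qtf`, which makes the
#' factor constant in `qtf`; setting `as_printed = TRUE` reproduces that
#' literal variant for auditability. The default is the standard form.
#'
#' @param k1 positive real, term-frequency saturation (default 1.2).
#' @param b length-normalization slope in `[0, 1]` (default 0.5).
#' @param k3 positive real, query-side saturation (default 8).
#' @param as_printed logical; use the degenerate `k3 * qtf` denominator.
#' @return an object of class `bm25_params`.
#' @export
bm25_params <- function(k1 = 1.2, b = 0.5, k3 = 8, as_printed = FALSE) {
  stopifnot(k1 > 0, k3 > 0, b >= 0, b <= 1)
  structure(list(k1 = k1, b = b, k3 = k3, as_printed = isTRUE(as_printed)),
            class = "bm25_params")
}

#' Dirichlet-smoothing parameters
#'
#' The language-model document score smooths the document's maximum-
#' likelihood term distribution with the collection model using a Dirichlet
#' prior of mass `mu`. The default `mu = 2000` is a common optimum for
#' verbose biomedical queries.
#'
#' @param mu non-negative real prior mass.
#' @return an object of class `dirichlet_params`.
#' @export
dirichlet_params <- function(mu = 2000) {
  stopifnot(is.numeric(mu), length(mu) == 1L, mu >= 0)
  structure(list(mu = mu), class = "dirichlet_params")
}

#' Sparse weighted query
#'
#' Both the original query and every expanded query are a sparse
#' term -> weight map. Zero-weight entries are dropped; terms must already be
#' analyzer-normalized.
#'
#' @param topic_id topic identifier (coerced to character).
#' @param weights named numeric vector of term weights.
#' @return an object of class `weighted_query`.
#' @export
#' @examples
#' weighted_query("1", c(heart = 1, diseas = 1))
weighted_query <- function(topic_id, weights) {
  stopifnot(is.numeric(weights))
  if (length(weights) && (is.null(names(weights)) || any(!nzchar(names(weights))))) {
    stop("weights must be named by term")
  }
  weights <- weights[weights != 0]
  if (anyDuplicated(names(weights))) {
    weights <- tapply(weights, names(weights), sum)
    weights <- stats::setNames(as.numeric(weights), names(weights))
    weights <- weights[weights != 0]
  }
  structure(list(topic_id = as.character(topic_id), weights = weights),
            class = "weighted_query")
}

#' Build a unit-weight query from raw text
#'
#' Tokenizes the text and assigns each distinct term its within-query term
#' frequency as weight.
#'
#' @param topic_id topic identifier.
#' @param text raw query text.
#' @param analyzer a [text_analyzer()].
#' @return a [weighted_query()].
#' @export
query_from_text <- function(topic_id, text, analyzer = text_analyzer()) {
  toks <- tokenize(text, analyzer)
  if (!length(toks)) return(weighted_query(topic_id, stats::setNames(numeric(), character())))
  tab <- table(toks)
  weighted_query(topic_id, stats::setNames(as.numeric(tab), names(tab)))
}

#' @export
print.weighted_query <- function(x, ...) {
  cat(sprintf("<weighted_query> topic %s, %d terms\n",
              x$topic_id, length(x$weights)))
  if (length(x$weights)) {
    w <- sort(x$weights, decreasing = TRUE)
    print(utils::head(round(w, 4), 10))
  }
  invisible(x)
}

# query-side saturation factor
.bm25_qfactor <- function(qtf, params) {
  if (params$as_printed) {
    ifelse(qtf > 0, (params$k3 + 1) * qtf / (params$k3 * qtf), 0)
  } else {
    (params$k3 + 1) * qtf / (params$k3 + qtf)
  }
}

#' BM25 weight of one query term in one document
#'
#' `((k1+1) tf / (K + tf)) * ((k3+1) qtf / (k3 + qtf)) * log((N - df + 0.5)
#' / (df + 0.5))` with `K = k1 ((1 - b) + b dl / avdl)`. The idf factor is
#' floored at zero. Vectorized over `tf` and `dl`.
#'
#' @param tf within-document term frequency (>= 0).
#' @param qtf within-query term weight (>= 0, may be fractional for
#'   expansion terms).
#' @param dl document length in tokens.
#' @param df document frequency of the term.
#' @param N number of indexed documents.
#' @param avdl average document length.
#' @param params a [bm25_params()].
#' @return numeric score contribution(s).
#' @export
bm25_term_weight <- function(tf, qtf, dl, df, N, avdl, params = bm25_params()) {
  stopifnot(all(tf >= 0), all(qtf >= 0))
  if (df > N) stop("inconsistent statistics: df > N")
  K <- params$k1 * ((1 - params$b) + params$b * dl / avdl)
  idf_t <- max(0, log((N - df + 0.5) / (df + 0.5)))
  doc_side <- ifelse(tf > 0, (params$k1 + 1) * tf / (K + tf), 0)
  doc_side * .bm25_qfactor(qtf, params) * idf_t
}

#' BM25 score of a query against one document
#'
#' Sum of [bm25_term_weight()] over the query terms present in the document.
#'
#' @param index a `corpus_index`.
#' @param query a [weighted_query()].
#' @param doc_id document id.
#' @param params a [bm25_params()].
#' @return numeric score (0 when no query term occurs in the document).
#' @export
score_bm25 <- function(index, query, doc_id, params = bm25_params()) {
  stopifnot(inherits(query, "weighted_query"))
  if (!length(query$weights)) stop("empty query")
  dl <- index$dl[[doc_id]]
  if (is.null(dl)) stop("unknown doc_id: ", doc_id)
  s <- 0
  for (term in names(query$weights)) {
    qtf <- query$weights[[term]]
    if (qtf <= 0) next
    ts <- term_stats(index, term, doc_id)
    if (ts$tf == 0L) next
    df_t <- index$df[[term]]
    s <- s + bm25_term_weight(ts$tf, qtf, dl, df_t, index$n_docs,
                              index$avg_dl, params)
  }
  s
}

#' Dirichlet query-likelihood score of a query against one document
#'
#' `sum_w qtf(w) * log p(w | D)` with
#' `p(w | D) = (c(w, D) + mu p(w | C)) / (|D| + mu)`.
#' Query terms absent from the entire collection are skipped (contribute 0)
#' rather than sending the score to minus infinity; when `mu = 0` a term not
#' present in the document is likewise skipped.
#'
#' @inheritParams score_bm25
#' @param params a [dirichlet_params()].
#' @return numeric log-likelihood score (<= 0 for unit query weights).
#' @export
score_dirichlet <- function(index, query, doc_id, params = dirichlet_params()) {
  stopifnot(inherits(query, "weighted_query"))
  if (!length(query$weights)) stop("empty query")
  dl <- index$dl[[doc_id]]
  if (is.null(dl)) stop("unknown doc_id: ", doc_id)
  mu <- params$mu
  s <- 0
  for (term in names(query$weights)) {
    qtf <- query$weights[[term]]
    if (qtf <= 0) next
    cf_t <- index$cf[term]
    if (is.na(cf_t) || cf_t == 0) next       # unseen in collection: skip
    p_c <- cf_t / index$total_tokens
    c_td <- term_stats(index, term, doc_id)$tf
    p_d <- (c_td + mu * p_c) / (dl + mu)
    if (p_d <= 0) next                       # mu = 0 and term absent
    s <- s + qtf * log(p_d)
  }
  unname(s)
}

# score every document containing at least one query term; returns a named
# numeric vector (may be empty)
.score_all_docs <- function(index, query, model, params) {
  terms <- names(query$weights)[query$weights > 0]
  terms <- terms[terms %in% names(index$postings)]
  if (!length(terms)) return(stats::setNames(numeric(), character()))
  cand <- unique(unlist(lapply(terms, function(t) index$postings[[t]]$doc_id)))
  if (model == "bm25") {
    acc <- stats::setNames(numeric(length(cand)), cand)
    for (term in terms) {
      p <- index$postings[[term]]
      qtf <- query$weights[[term]]
      w <- bm25_term_weight(p$tf, qtf, index$dl[p$doc_id], index$df[[term]],
                            index$n_docs, index$avg_dl, params)
      acc[p$doc_id] <- acc[p$doc_id] + w
    }
    acc
  } else {
    mu <- params$mu
    dl <- index$dl[cand]
    acc <- stats::setNames(numeric(length(cand)), cand)
    for (term in terms) {
      cf_t <- index$cf[term]
      if (is.na(cf_t) || cf_t == 0) next
      qtf <- query$weights[[term]]
      p_c <- cf_t / index$total_tokens
      p <- index$postings[[term]]
      c_td <- stats::setNames(numeric(length(cand)), cand)
      c_td[p$doc_id[p$doc_id %in% cand]] <- p$tf[p$doc_id %in% cand]
      p_d <- (c_td + mu * p_c) / (dl + mu)
      ok <- p_d > 0
      acc[ok] <- acc[ok] + qtf * log(p_d[ok])
    }
    acc
  }
}

#' First-pass retrieval
#'
#' Scores every document containing at least one query term with BM25 or the
#' Dirichlet-smoothed language model, and returns the top `cutoff` documents.
#' Ties are broken lexicographically by document id (byte order), so repeated
#' runs are byte-identical.
#'
#' @param index a `corpus_index`.
#' @param query a [weighted_query()].
#' @param model `"bm25"` or `"dirichlet"`.
#' @param params a [bm25_params()] or [dirichlet_params()] matching `model`;
#'   `NULL` uses the model's defaults.
#' @param cutoff maximum number of documents returned (default 1000).
#' @return a run data frame with columns `topic_id`, `doc_id`, `rank`,
#'   `score`, scores non-increasing.
#' @export
retrieve <- function(index, query, model = c("bm25", "dirichlet"),
                     params = NULL, cutoff = 1000) {
  model <- match.arg(model)
  stopifnot(inherits(index, "corpus_index"), inherits(query, "weighted_query"))
  if (index$n_docs == 0L) stop("empty index")
  if (!length(query$weights)) stop("empty query")
  if (is.null(params)) {
    params <- if (model == "bm25") bm25_params() else dirichlet_params()
  }
  scores <- .score_all_docs(index, query, model, params)
  if (model == "bm25") scores <- scores[scores > 0]
  ranking_from_scores(query$topic_id, scores, cutoff)
}

#' Assemble a ranking from raw scores
#'
#' Sorts by descending score with deterministic lexicographic doc-id
#' tie-breaking and truncates to `cutoff`.
#'
#' @param topic_id topic identifier.
#' @param scores named numeric vector (names are doc ids).
#' @param cutoff rank cutoff.
#' @return a run data frame (`topic_id`, `doc_id`, `rank`, `score`).
#' @export
ranking_from_scores <- function(topic_id, scores, cutoff = 1000) {
  if (!length(scores)) {
    return(data.frame(topic_id = character(), doc_id = character(),
                      rank = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  ord <- order(-scores, names(scores), method = "radix")
  ord <- ord[seq_len(min(length(ord), cutoff))]
  data.frame(topic_id = as.character(topic_id),
             doc_id = names(scores)[ord],
             rank = seq_along(ord),
             score = unname(scores[ord]),
             stringsAsFactors = FALSE)
}
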