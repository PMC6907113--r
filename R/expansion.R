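#' BM25 feedback weight of a term in one document
#'
#' The document-side BM25 weight used to score candidate expansion terms in a
#' feedback document: `((k1 + 1) tf / (K + tf)) * idf(term)` with
#' `K = k1 ((1 - b) + b dl / avdl)`. No query-side factor is applied — a
#' candidate term has no within-query frequency.
#'
#' @param index a `corpus_index`.
#' @param term analyzed term.
#' @param doc_id document id.
#' @param params a [bm25_params()].
#' @param idf_scheme idf scheme passed to [idf()].
#' @return non-negative numeric weight (0 when the term does not occur).
#' @export
bm25_feedback_weight <- function(index, term, doc_id, params = bm25_params(),
                                 idf_scheme = "bm25") {
  ts <- term_stats(index, term, doc_id)
  if (ts$tf == 0L) return(0)
  dl <- index$dl[[doc_id]]
  K <- params$k1 * ((1 - params$b) + params$b * dl / index$avg_dl)
  unname((params$k1 + 1) * ts$tf / (K + ts$tf) * idf(index, term, idf_scheme))
}

# BM25 feedback weights of every distinct term of one document, vectorized
.feedback_vector <- function(index, doc_id, params, idf_scheme = "bm25") {
  tokens <- index$docs[[doc_id]]
  if (is.null(tokens)) stop("unknown doc_id: ", doc_id)
  if (!length(tokens)) return(stats::setNames(numeric(), character()))
  tab <- table(tokens)
  terms <- names(tab)
  tf <- as.numeric(tab)
  dl <- index$dl[[doc_id]]
  K <- params$k1 * ((1 - params$b) + params$b * dl / index$avg_dl)
  stats::setNames((params$k1 + 1) * tf / (K + tf) *
                    idf(index, terms, idf_scheme), terms)
}

# mean over feedback documents of per-document term vectors; union of terms,
# absent terms contribute 0
.mean_vector <- function(vectors) {
  terms <- sort(unique(unlist(lapply(vectors, names))))
  if (!length(terms)) return(stats::setNames(numeric(), character()))
  acc <- stats::setNames(numeric(length(terms)), terms)
  for (v in vectors) acc[names(v)] <- acc[names(v)] + v
  acc / length(vectors)
}

#' Score normalization
#'
#' Three normalizations used to make the frequency-based and the
#' proximity-based feedback components commensurable before mixing:
#' \describe{
#'   \item{norm1}{min-max: `(t - min) / (max - min)`; degenerate input
#'     (all values equal) maps to all zeros with a warning.}
#'   \item{norm2}{L2: `t / sqrt(sum(t^2))`; all-zero input stays zero.}
#'   \item{norm3}{max: `t / max(t)`; all-zero input stays zero.}
#' }
#'
#' @param scores named numeric vector.
#' @param method `"norm1"`, `"norm2"` or `"norm3"`.
#' @return named numeric vector over the same terms.
#' @export
#' @examples
#' normalize_scores(c(a = 1, b = 2, c = 3), "norm1")  # 0, 0.5, 1
#' normalize_scores(c(a = 3, b = 4), "norm2")         # 0.6, 0.8
normalize_scores <- function(scores, method = c("norm1", "norm2", "norm3")) {
  method <- match.arg(method)
  stopifnot(is.numeric(scores), length(scores) >= 1L)
  switch(method,
    norm1 = {
      rng <- range(scores)
      if (rng[1] == rng[2]) {
        warning("degenerate input to norm1 (all values equal); returning zeros")
        scores * 0
      } else {
        (scores - rng[1]) / (rng[2] - rng[1])
      }
    },
    norm2 = {
      nrm <- sqrt(sum(scores^2))
      if (nrm == 0) scores else scores / nrm
    },
    norm3 = {
      mx <- max(scores)
      if (mx == 0) scores else scores / mx
    })
}

#' Classic Rocchio query expansion
#'
#' `Q1 = alpha * Q0 + beta * centroid(R)` where the centroid is the per-term
#' arithmetic mean of the feedback documents' BM25 term-weight vectors.
#' Candidate terms (centroid terms that are not original query terms) are
#' truncated to the `n_terms` heaviest before merging; the centroid's mass on
#' the original query terms is always kept. In this parameterization `alpha`
#' is conventionally fixed at 1 and only `beta` tuned.
#'
#' @param index a `corpus_index`.
#' @param query the original [weighted_query()].
#' @param feedback_docs character vector of feedback document ids (top of the
#'   first-pass ranking).
#' @param alpha original-query weight (default 1).
#' @param beta feedback weight in `[0, 1]` (default 0.5).
#' @param n_terms number of expansion terms kept (default 10).
#' @param params a [bm25_params()].
#' @param idf_scheme idf scheme for the feedback weights.
#' @return the expanded [weighted_query()].
#' @export
rocchio_expand <- function(index, query, feedback_docs, alpha = 1, beta = 0.5,
                           n_terms = 10, params = bm25_params(),
                           idf_scheme = "bm25") {
  stopifnot(inherits(query, "weighted_query"))
  if (!length(feedback_docs)) stop("empty feedback set")
  centroid <- .mean_vector(lapply(feedback_docs, .feedback_vector,
                                  index = index, params = params,
                                  idf_scheme = idf_scheme))
  qterms <- names(query$weights)
  cand <- centroid[setdiff(names(centroid), qterms)]
  if (length(cand)) {
    keep <- names(cand)[order(-cand, names(cand), method = "radix")]
    keep <- utils::head(keep, n_terms)
    cand <- cand[keep]
  }
  kept <- c(centroid[intersect(names(centroid), qterms)], cand)
  new_w <- alpha * query$weights
  add <- beta * kept
  all_terms <- union(names(new_w), names(add))
  out <- stats::setNames(numeric(length(all_terms)), all_terms)
  out[names(new_w)] <- new_w
  out[names(add)] <- out[names(add)] + add
  weighted_query(query$topic_id, out)
}

#' HRoc configuration
#'
#' Hyper-parameters of the proximity-weighted expansion model:
#' `alpha` mixes the original query with the feedback information
#' (`alpha = 0` keeps the original query untouched), `beta` mixes the
#' frequency-based component against the proximity-based component,
#' `n_feedback_docs` is the feedback-set size |R|, `n_expansion_terms` the
#' number of expansion terms kept, `window` the sliding-window specification,
#' and `norm_method` selects the normalization (norm1/2/3 give the HRoc1,
#' HRoc2 and HRoc3 variants).
#'
#' @param alpha real in `[0, 1]` (default 0.5).
#' @param beta real in `[0, 1]` (default 0.5).
#' @param n_feedback_docs positive integer |R| (default 10).
#' @param n_expansion_terms positive integer (default 10).
#' @param window a [window_spec()] (default fixed, D = 5).
#' @param norm_method `"norm1"`, `"norm2"` or `"norm3"`.
#' @param bm25 a [bm25_params()] used for feedback term weights and the
#'   second pass.
#' @param idf_scheme idf scheme used throughout.
#' @return an object of class `hroc_config`.
#' @export
hroc_config <- function(alpha = 0.5, beta = 0.5, n_feedback_docs = 10,
                        n_expansion_terms = 10,
                        window = window_spec("fixed", D = 5),
                        norm_method = c("norm1", "norm2", "norm3"),
                        bm25 = bm25_params(), idf_scheme = "bm25") {
  norm_method <- match.arg(norm_method)
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, beta <= 1,
            n_feedback_docs >= 1, n_expansion_terms >= 1,
            inherits(window, "window_spec"), inherits(bm25, "bm25_params"))
  structure(list(alpha = alpha, beta = beta,
                 n_feedback_docs = as.integer(n_feedback_docs),
                 n_expansion_terms = as.integer(n_expansion_terms),
                 window = window, norm_method = norm_method, bm25 = bm25,
                 idf_scheme = idf_scheme),
            class = "hroc_config")
}

#' Per-candidate feedback term table
#'
#' The two feedback components of the proximity-weighted expansion — the mean
#' BM25 term weight and the mean IDF-weighted HAL proximity weight over the
#' feedback set — for every candidate term, before and after normalization,
#' plus their `beta`-combination. Useful for `--explain`-style dumps and is
#' the internal substrate of [hroc_expand()].
#'
#' @inheritParams hroc_expand
#' @return data frame with columns `term`, `bm25_raw`, `hal_raw`,
#'   `bm25_norm`, `hal_norm`, `combined`, sorted by decreasing `combined`
#'   (ties by term).
#' @export
feedback_term_table <- function(index, query, feedback_docs, config) {
  stopifnot(inherits(config, "hroc_config"), inherits(query, "weighted_query"))
  if (!length(feedback_docs)) stop("empty feedback set")
  r_vecs <- lapply(feedback_docs, .feedback_vector, index = index,
                   params = config$bm25, idf_scheme = config$idf_scheme)
  hal_vecs <- lapply(feedback_docs, function(id) {
    D <- .window_for_doc(config$window, index$dl[[id]], index$avg_dl)
    w_hal(index, id, query, D, idf_scheme = config$idf_scheme)
  })
  mean_r <- .mean_vector(r_vecs)
  mean_hal <- .mean_vector(hal_vecs)
  cand <- setdiff(sort(unique(c(names(mean_r), names(mean_hal)))),
                  names(query$weights))
  if (!length(cand)) {
    return(data.frame(term = character(), bm25_raw = numeric(),
                      hal_raw = numeric(), bm25_norm = numeric(),
                      hal_norm = numeric(), combined = numeric(),
                      stringsAsFactors = FALSE))
  }
  bm25_raw <- ifelse(cand %in% names(mean_r), mean_r[cand], 0)
  hal_raw <- ifelse(cand %in% names(mean_hal), mean_hal[cand], 0)
  names(bm25_raw) <- names(hal_raw) <- cand
  bm25_norm <- suppressWarnings(normalize_scores(bm25_raw, config$norm_method))
  if (all(hal_raw == 0)) {
    warning("all proximity components are zero; ",
            "falling back to the frequency-only branch")
    combined <- suppressWarnings(normalize_scores(bm25_raw, config$norm_method))
    hal_norm <- hal_raw
  } else {
    hal_norm <- normalize_scores(hal_raw, config$norm_method)
    combined <- (1 - config$beta) * bm25_norm + config$beta * hal_norm
  }
  out <- data.frame(term = cand, bm25_raw = unname(bm25_raw),
                    hal_raw = unname(hal_raw), bm25_norm = unname(bm25_norm),
                    hal_norm = unname(hal_norm), combined = unname(combined),
                    stringsAsFactors = FALSE)
  out[order(-out$combined, out$term, method = "radix"), , drop = FALSE]
}

#' Proximity-weighted Rocchio expansion (HRoc)
#'
#' `Q' = (1 - alpha) * Q0 + alpha * ((1 - beta) * Norm(mean_R r) +
#' beta * Norm(mean_R W_HAL))`, where `r` is a feedback document's BM25 term
#' vector and `W_HAL` its IDF-weighted HAL proximity vector computed with
#' that document's window size (fixed `D` or adaptive). Candidate terms (all
#' feedback-document terms minus the original query terms) are ranked by the
#' bracketed combined score, truncated to `n_expansion_terms` (ties broken
#' lexicographically), then merged with the rescaled original query.
#' `alpha = 0` returns `Q0` unchanged; `beta = 0` reduces to a normalized
#' Rocchio expansion.
#'
#' @param index a `corpus_index`.
#' @param query the original [weighted_query()].
#' @param feedback_docs character vector of feedback document ids.
#' @param config an [hroc_config()].
#' @return the expanded [weighted_query()].
#' @export
hroc_expand <- function(index, query, feedback_docs, config = hroc_config()) {
  stopifnot(inherits(config, "hroc_config"), inherits(query, "weighted_query"))
  if (!length(feedback_docs)) stop("empty feedback set")
  if (config$alpha == 0) return(query)
  tab <- feedback_term_table(index, query, feedback_docs, config)
  keep <- utils::head(tab, config$n_expansion_terms)
  new_w <- (1 - config$alpha) * query$weights
  add <- stats::setNames(config$alpha * keep$combined, keep$term)
  all_terms <- union(names(new_w), names(add))
  out <- stats::setNames(numeric(length(all_terms)), all_terms)
  out[names(new_w)] <- new_w
  out[names(add)] <- out[names(add)] + add
  weighted_query(query$topic_id, out)
}

#' Second-pass retrieval with an expanded query
#'
#' BM25 retrieval with the expansion-term weights used as fractional
#' within-query term frequencies; deterministic tie-breaking as in
#' [retrieve()].
#'
#' @param index a `corpus_index`.
#' @param query an expanded [weighted_query()].
#' @param params a [bm25_params()].
#' @param cutoff rank cutoff (default 1000).
#' @return a run data frame.
#' @export
second_pass <- function(index, query, params = bm25_params(), cutoff = 1000) {
  retrieve(index, query, model = "bm25", params = params, cutoff = cutoff)
}
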