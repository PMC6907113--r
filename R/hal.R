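#' HAL distance-decay strength
#'
#' In a Hyperspace-Analogue-to-Language (HAL) sliding window of size `D`,
#' a co-occurrence at token distance `l` receives strength `D - l + 1`:
#' adjacent terms (distance 1) get the full strength `D`, and the strength
#' decays linearly to 1 at the window boundary (distance `D`).
#'
#' @param l token distance, `1 <= l <= D`. Vectorized.
#' @param D window size (positive integer).
#' @return integer strength(s) `D - l + 1`.
#' @export
#' @examples
#' hal_strength(1, 5)  # adjacent: 5
#' hal_strength(5, 5)  # window boundary: 1
hal_strength <- function(l, D) {
  stopifnot(length(D) == 1L, D >= 1)
  if (any(l < 1) || any(l > D)) stop("distance l must satisfy 1 <= l <= D")
  as.integer(D - l + 1)
}

#' Window size specification
#'
#' Either a fixed window size `D`, or an adaptive size recomputed per
#' document from its length via [adaptive_window()].
#'
#' @param mode `"fixed"` or `"adaptive"`.
#' @param D fixed window size (used when `mode = "fixed"`; default 5).
#' @param variant adaptive function, one of `"f1"`, `"f2"`, `"f3"`
#'   (used when `mode = "adaptive"`).
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(mode = c("fixed", "adaptive"), D = 5,
                        variant = c("f1", "f2", "f3")) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  if (mode == "fixed") stopifnot(length(D) == 1L, D >= 1)
  structure(list(mode = mode, D = as.integer(D), variant = variant),
            class = "window_spec")
}

# resolve the window size for one document
.window_for_doc <- function(window, dl, avg_dl) {
  if (window$mode == "fixed") window$D
  else adaptive_window(dl, avg_dl, window$variant)
}

#' Adaptive sliding-window size
#'
#' Replaces the fixed HAL window size with a per-document function of the
#' document length `dl` and the collection average length `avg_dl`:
#' \describe{
#'   \item{f1}{`dl` — the document's own length.}
#'   \item{f2}{`dl * (1 + dl / avg_dl)`.}
#'   \item{f3}{`(dl + avg_dl) / (1 + log2(dl / avg_dl))`.}
#' }
#' Results are rounded to the nearest integer and floored at 1. The printed
#' form of f3 is ambiguous about precedence; the default reading groups both
#' the numerator and denominator, and `literal = TRUE` gives the literal
#' left-to-right reading `dl + avg_dl / 1 + log2(dl / avg_dl)`. If the f3
#' denominator is non-positive (documents shorter than half the average
#' length), the function falls back to f1 with a warning.
#'
#' @param dl document length (tokens, >= 1). Vectorized.
#' @param avg_dl average document length (> 0).
#' @param variant `"f1"`, `"f2"` or `"f3"`.
#' @param literal logical; literal precedence reading of f3.
#' @return positive integer window size(s).
#' @export
#' @examples
#' adaptive_window(300, 816.3, "f1")   # 300
#' adaptive_window(100, 100, "f2")     # 200
adaptive_window <- function(dl, avg_dl, variant = c("f1", "f2", "f3"),
                            literal = FALSE) {
  variant <- match.arg(variant)
  stopifnot(all(dl >= 1), avg_dl > 0)
  D <- switch(variant,
    f1 = dl,
    f2 = dl * (1 + dl / avg_dl),
    f3 = {
      if (literal) {
        dl + avg_dl / 1 + log2(dl / avg_dl)
      } else {
        den <- 1 + log2(dl / avg_dl)
        out <- (dl + avg_dl) / den
        bad <- den <= 0 | !is.finite(out) | out < 1
        if (any(bad)) {
          warning("f3 window undefined for ", sum(bad),
                  " document(s); falling back to f1")
          out[bad] <- dl[bad]
        }
        out
      }
    })
  pmax(1L, as.integer(round(D)))
}

#' Distance histogram of a (candidate, query term) pair in a document
#'
#' For every occurrence position `i` of `query_term` and every occurrence
#' position `j` of `candidate` with `1 <= |i - j| <= D`, the count at
#' distance `|i - j|` is incremented. The window is symmetric: occurrences
#' before and after the query term both count. All occurrence pairs within
#' the window are counted, not only nearest neighbours. A term paired with
#' itself counts distinct occurrence pairs (distance 0 never arises).
#'
#' @param tokens character vector, the analyzed token stream of one document.
#' @param candidate candidate term.
#' @param query_term query term.
#' @param D window size.
#' @return an object of class `distance_histogram`: list with `candidate`,
#'   `query_term`, `D` and `counts`, an integer vector indexed by distance
#'   `1..D`.
#' @export
distance_histogram <- function(tokens, candidate, query_term, D) {
  stopifnot(D >= 1)
  D <- as.integer(D)
  counts <- integer(D)
  qi <- which(tokens == query_term) - 1L
  tj <- which(tokens == candidate) - 1L
  if (length(qi) && length(tj)) {
    d <- abs(outer(qi, tj, "-"))
    d <- d[d >= 1L & d <= D]
    if (length(d)) {
      tab <- tabulate(d, nbins = D)
      counts <- counts + tab
    }
  }
  structure(list(candidate = candidate, query_term = query_term, D = D,
                 counts = counts), class = "distance_histogram")
}

#' HAL proximity score of a candidate term with respect to a query term
#'
#' `sum over l = 1..D of w(l) * p(t, l, q)` where `p(t, l, q)` is the number
#' of co-occurrences of candidate `t` and query term `q` at distance `l`
#' within the document and `w(l) = D - l + 1` is the linear decay strength.
#'
#' @inheritParams distance_histogram
#' @return non-negative numeric score.
#' @export
#' @examples
#' hal_score(c("q", "t"), "t", "q", 5)  # one adjacent pair: 5
hal_score <- function(tokens, candidate, query_term, D) {
  h <- distance_histogram(tokens, candidate, query_term, D)
  sum(hal_strength(seq_len(h$D), h$D) * h$counts)
}

#' HAL scores of every document term against one query term
#'
#' Single-pass computation of `hal_score(tokens, t, query_term, D)` for all
#' distinct terms `t` in the document: for each occurrence of the query term
#' the surrounding window positions are visited once and their strengths
#' accumulated per token. Equivalent to calling [hal_score()] per term, but
#' linear in `occurrences x D` instead of quadratic in term occurrences.
#'
#' @inheritParams distance_histogram
#' @param query_term query term.
#' @return named numeric vector over the document's distinct terms (terms
#'   with zero score included as 0); empty document gives an empty vector.
#' @export
hal_profile <- function(tokens, query_term, D) {
  stopifnot(D >= 1)
  D <- as.integer(D)
  vocab <- unique(tokens)
  out <- stats::setNames(numeric(length(vocab)), vocab)
  qpos <- which(tokens == query_term)
  if (!length(qpos)) return(out)
  n <- length(tokens)
  offs <- c(-(D:1), 1:D)
  strengths <- D - abs(offs) + 1L
  for (p in qpos) {
    at <- p + offs
    ok <- at >= 1L & at <= n
    if (!any(ok)) next
    contrib <- tapply(strengths[ok], tokens[at[ok]], sum)
    out[names(contrib)] <- out[names(contrib)] + contrib
  }
  out
}

#' IDF-weighted proximity weight of candidate terms
#'
#' The proximity feedback weight of a candidate term `t` in one document is
#' the sum over the original query terms `q_i` of
#' `HAL(t, q_i) * IDF(q_i)` — each query term's HAL profile scaled by how
#' discriminative that query term is in the collection.
#'
#' @param index a `corpus_index` (supplies the idf of the query terms).
#' @param doc_id id of the (feedback) document, which must be indexed.
#' @param query the original [weighted_query()].
#' @param D window size for this document.
#' @param candidates optional character vector restricting the result;
#'   default: every distinct term of the document.
#' @param idf_scheme idf scheme passed to [idf()].
#' @return named numeric vector of `W_HAL` values (>= 0) over the candidates.
#' @export
w_hal <- function(index, doc_id, query, D, candidates = NULL,
                  idf_scheme = "bm25") {
  stopifnot(inherits(index, "corpus_index"), inherits(query, "weighted_query"))
  if (!length(query$weights)) stop("empty query")
  tokens <- index$docs[[doc_id]]
  if (is.null(tokens)) stop("unknown doc_id: ", doc_id)
  vocab <- unique(tokens)
  out <- stats::setNames(numeric(length(vocab)), vocab)
  qterms <- names(query$weights)
  idfs <- idf(index, qterms, scheme = idf_scheme)
  for (q in qterms) {
    if (idfs[[q]] == 0) next
    prof <- hal_profile(tokens, q, D)
    out[names(prof)] <- out[names(prof)] + prof * idfs[[q]]
  }
  if (!is.null(candidates)) {
    out <- stats::setNames(ifelse(candidates %in% names(out),
                                  out[candidates], 0), candidates)
  }
  out
}

#' Directional HAL co-occurrence matrix of one document
#'
#' The classic HAL construction: entry (a, b) is the distance-decayed count
#' of occurrences of term `b` appearing within `D` tokens *before* term `a`
#' (row term = focus, column term = preceding context), accumulated over the
#' document. With `directional = FALSE` the symmetric matrix
#' `M + t(M)` is returned, whose entries match [hal_score()]. Intended for
#' inspection and teaching; the retrieval model itself only ever uses
#' per-document, per-query-term vectors.
#'
#' @param tokens analyzed token stream.
#' @param D window size.
#' @param directional logical (default `TRUE`).
#' @return square numeric matrix with dimnames = document vocabulary.
#' @export
hal_matrix <- function(tokens, D = 5, directional = TRUE) {
  stopifnot(D >= 1)
  D <- as.integer(D)
  vocab <- unique(tokens)
  M <- matrix(0, length(vocab), length(vocab), dimnames = list(vocab, vocab))
  n <- length(tokens)
  for (i in seq_len(n)) {
    lo <- max(1L, i - D)
    js <- seq_len(i - 1L)
    js <- js[js >= lo]
    for (j in js) {
      M[tokens[i], tokens[j]] <- M[tokens[i], tokens[j]] + (D - (i - j) + 1L)
    }
  }
  if (!directional) M <- M + t(M)
  M
}

#' Write a HAL matrix as CSV
#'
#' @param M matrix from [hal_matrix()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_hal_matrix <- function(M, path) {
  utils::write.csv(M, path, row.names = TRUE)
  invisible(path)
}
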