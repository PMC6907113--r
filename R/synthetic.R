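#' Synthetic collection specification
#'
#' Describes a deterministic toy collection with controlled topical and
#' proximity structure, so the whole PRF pipeline can be exercised without
#' external data. Each topic owns a disjoint set of query terms, designated
#' expansion terms and decoy terms; a shared filler vocabulary provides
#' background text. Per topic the collection contains five document kinds:
#' \describe{
#'   \item{seed relevant}{every query term and every expansion term planted
#'     twice, query-to-expansion distance exactly `relevant_gap`; these are
#'     the documents the first pass finds and feedback mines.}
#'   \item{hidden relevant}{one planted query/expansion block plus extra
#'     expansion-term occurrences; weaker query-term evidence, so they sit
#'     low in the first pass and surface only through good expansion terms.}
#'   \item{distractor (non-relevant)}{the same query and expansion terms,
#'     but every query-to-expansion distance at least `nonrelevant_gap`,
#'     plus a high-frequency decoy-term block far from the query terms —
#'     frequent but positionally unrelated terms that frequency-based
#'     feedback mistakes for good expansion terms.}
#'   \item{decoy-only (non-relevant)}{the decoy block without query terms;
#'     these documents are pulled up exactly when decoys enter the query.}
#'   \item{filler}{background documents from the filler vocabulary only.}
#' }
#'
#' @param seed integer seed; all randomness flows through one generator.
#' @param n_topics number of topics (default 20).
#' @param n_rel_seed,n_rel_hidden,n_distractor,n_decoy_only,n_filler_docs
#'   per-topic document counts (defaults 2, 3, 5, 8, 7 — 25 docs per topic,
#'   relevant fraction 0.2).
#' @param n_query_terms,n_expansion_terms,n_decoy_terms per-topic term counts
#'   (defaults 2, 2, 2).
#' @param doc_length length-2 integer vector `c(min, max)` of document
#'   lengths in tokens (default `c(60, 100)`).
#' @param relevant_gap query-to-expansion token distance planted in relevant
#'   documents (default 2; must be small relative to the window size).
#' @param nonrelevant_gap minimal query-to-expansion distance in distractor
#'   documents (default 12; must exceed the window size, conventionally at
#'   least twice it).
#' @param decoy_tf occurrences of each decoy term in decoy-bearing documents
#'   (default 8).
#' @param filler_vocab size of the shared filler vocabulary (default 300).
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1, n_topics = 20, n_rel_seed = 2,
                       n_rel_hidden = 3, n_distractor = 5, n_decoy_only = 8,
                       n_filler_docs = 7, n_query_terms = 2,
                       n_expansion_terms = 2, n_decoy_terms = 2,
                       doc_length = c(60, 100), relevant_gap = 2,
                       nonrelevant_gap = 12, decoy_tf = 8,
                       filler_vocab = 300) {
  stopifnot(length(doc_length) == 2L, doc_length[1] >= 1,
            doc_length[2] >= doc_length[1], n_topics >= 1,
            relevant_gap >= 1, nonrelevant_gap >= 1,
            n_query_terms >= 1, n_expansion_terms >= 1, n_decoy_terms >= 1,
            decoy_tf >= 1, filler_vocab >= 1)
  if (relevant_gap >= nonrelevant_gap) {
    stop("relevant_gap must be smaller than nonrelevant_gap")
  }
  min_len <- doc_length[1]
  block_span <- (n_query_terms + n_expansion_terms) * relevant_gap + 1L
  distractor_span <- 2L * nonrelevant_gap + n_query_terms +
    n_expansion_terms + n_decoy_terms * decoy_tf + 2L
  if (block_span >= min_len || nonrelevant_gap >= min_len) {
    stop("proximity gap does not fit in the minimum document length")
  }
  if (distractor_span >= min_len) {
    stop("distractor layout (nonrelevant_gap = ", nonrelevant_gap,
         ", decoy block = ", n_decoy_terms * decoy_tf,
         ") does not fit in the minimum document length")
  }
  structure(list(seed = as.integer(seed), n_topics = n_topics,
                 n_rel_seed = n_rel_seed, n_rel_hidden = n_rel_hidden,
                 n_distractor = n_distractor, n_decoy_only = n_decoy_only,
                 n_filler_docs = n_filler_docs,
                 n_query_terms = n_query_terms,
                 n_expansion_terms = n_expansion_terms,
                 n_decoy_terms = n_decoy_terms,
                 doc_length = as.integer(doc_length),
                 relevant_gap = as.integer(relevant_gap),
                 nonrelevant_gap = as.integer(nonrelevant_gap),
                 decoy_tf = as.integer(decoy_tf),
                 filler_vocab = as.integer(filler_vocab)),
            class = "synth_spec")
}

# topic-local term names; pure alphanumerics that the analyzer maps to
# themselves (no stemmable suffix), keeping planted distances exact
.synth_terms <- function(prefix, topic, n) {
  sprintf("%s%02d%s", prefix, topic, letters[seq_len(n)])
}

# interleave query and expansion terms with `gap` spacing and write the
# block into tokens starting at `at` (1-based); returns modified tokens
.plant_block <- function(tokens, at, qterms, eterms, gap) {
  seq_terms <- character(0)
  m <- max(length(qterms), length(eterms))
  for (i in seq_len(m)) {
    if (i <= length(qterms)) seq_terms <- c(seq_terms, qterms[i])
    if (i <= length(eterms)) seq_terms <- c(seq_terms, eterms[i])
  }
  pos <- at + (seq_along(seq_terms) - 1L) * gap
  stopifnot(max(pos) <= length(tokens))
  tokens[pos] <- seq_terms
  tokens
}

#' Generate a synthetic collection
#'
#' Deterministic for a fixed spec (including its seed): produces the token
#' streams, raw texts, topics and qrels of the collection described by
#' [synth_spec()], optionally writing them in the formats the TREC readers
#' consume (`corpus.jsonl`, `topics.xml`, `qrels.txt`).
#'
#' @param spec a [synth_spec()].
#' @param out_dir optional directory; created if missing.
#' @return list with `tokens` (named list of token vectors), `texts` (named
#'   character vector), `topics` (as [read_topics()] returns), `qrels`
#'   ([qrels()] data frame), `spec`, and — when `out_dir` is given — `paths`.
#' @export
generate_collection <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  filler <- sprintf("f%03dz", seq_len(spec$filler_vocab))
  tokens <- list()
  topics <- list()
  qr_topic <- character(0); qr_doc <- character(0)

  new_doc <- function() {
    len <- sample(spec$doc_length[1]:spec$doc_length[2], 1L)
    sample(filler, len, replace = TRUE)
  }

  for (t in seq_len(spec$n_topics)) {
    q <- .synth_terms("q", t, spec$n_query_terms)
    e <- .synth_terms("e", t, spec$n_expansion_terms)
    d <- .synth_terms("d", t, spec$n_decoy_terms)
    g1 <- spec$relevant_gap
    g2 <- spec$nonrelevant_gap
    block_span <- (length(q) + length(e) - 1L) * g1 + 1L

    for (i in seq_len(spec$n_rel_seed)) {
      toks <- new_doc()
      len <- length(toks)
      a1 <- max(1L, round(0.15 * len))
      a2 <- min(len - block_span, round(0.60 * len))
      toks <- .plant_block(toks, a1, q, e, g1)
      toks <- .plant_block(toks, a2, q, e, g1)
      tokens[[sprintf("t%02d-rel%02d", t, i)]] <- toks
      qr_topic <- c(qr_topic, as.character(t))
      qr_doc <- c(qr_doc, sprintf("t%02d-rel%02d", t, i))
    }

    for (i in seq_len(spec$n_rel_hidden)) {
      toks <- new_doc()
      len <- length(toks)
      a1 <- max(1L, round(0.25 * len))
      toks <- .plant_block(toks, a1, q, e, g1)
      a2 <- min(len - length(e), round(0.85 * len))
      toks[a2 + seq_along(e) - 1L] <- e
      tokens[[sprintf("t%02d-hid%02d", t, i)]] <- toks
      qr_topic <- c(qr_topic, as.character(t))
      qr_doc <- c(qr_doc, sprintf("t%02d-hid%02d", t, i))
    }

    for (i in seq_len(spec$n_distractor)) {
      toks <- new_doc()
      # query cluster at the front, expansion cluster one nonrelevant_gap
      # away, decoy block another gap beyond that
      toks[seq_along(q)] <- q
      e_at <- length(q) + g2
      toks[e_at + seq_along(e) - 1L] <- e
      d_at <- e_at + length(e) - 1L + g2
      toks[d_at + seq_len(length(d) * spec$decoy_tf) - 1L] <-
        rep(d, spec$decoy_tf)
      tokens[[sprintf("t%02d-dis%02d", t, i)]] <- toks
    }

    for (i in seq_len(spec$n_decoy_only)) {
      toks <- new_doc()
      a1 <- max(1L, round(0.40 * length(toks)) -
                  (length(d) * spec$decoy_tf) %/% 2L)
      toks[a1 + seq_len(length(d) * spec$decoy_tf) - 1L] <-
        rep(d, spec$decoy_tf)
      tokens[[sprintf("t%02d-dec%02d", t, i)]] <- toks
    }

    for (i in seq_len(spec$n_filler_docs)) {
      tokens[[sprintf("t%02d-fil%02d", t, i)]] <- new_doc()
    }

    qtext <- paste(q, collapse = " ")
    topics[[t]] <- list(
      topic_id = as.character(t),
      fields = list(title = qtext,
                    description = paste("patient case about", qtext),
                    note = qtext))
  }

  qr <- qrels(qr_topic, qr_doc, rep(1L, length(qr_doc)))
  texts <- vapply(tokens, paste, character(1), collapse = " ")
  out <- list(tokens = tokens, texts = texts, topics = topics, qrels = qr,
              spec = spec)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- list(corpus = file.path(out_dir, "corpus.jsonl"),
                  topics = file.path(out_dir, "topics.xml"),
                  qrels = file.path(out_dir, "qrels.txt"))
    write_corpus_jsonl(texts, paths$corpus)
    write_topics(topics, paths$topics)
    write_qrels(qr, paths$qrels)
    out$paths <- paths
  }
  out
}
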