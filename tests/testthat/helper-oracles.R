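# Independent oracles, deliberately naive and sharing no code with the
# package internals.

# HAL score by brute-force enumeration of all occurrence pairs
oracle_hal_score <- function(tokens, candidate, query_term, D) {
  total <- 0
  for (i in seq_along(tokens)) {
    if (tokens[i] != query_term) next
    for (j in seq_along(tokens)) {
      if (tokens[j] != candidate) next
      l <- abs(i - j)
      if (l >= 1 && l <= D) total <- total + (D - l + 1)
    }
  }
  total
}

# trec-eval-style average precision, straight from the definition
oracle_average_precision <- function(doc_ids, relevant, n_relevant,
                                     cutoff = 1000) {
  doc_ids <- head(doc_ids, cutoff)
  hits <- 0
  s <- 0
  for (r in seq_along(doc_ids)) {
    if (doc_ids[r] %in% relevant) {
      hits <- hits + 1
      s <- s + hits / r
    }
  }
  s / n_relevant
}

oracle_precision_at_k <- function(doc_ids, relevant, k) {
  sum(head(doc_ids, k) %in% relevant) / k
}

# random judged run/qrels pair over a shared topic
random_run_and_qrels <- function(topic, n_docs = 40, n_ranked = 25) {
  docs <- sprintf("doc%03d", seq_len(n_docs))
  ranked <- sample(docs, n_ranked)
  rel <- sample(docs, sample(2:10, 1))
  run <- data.frame(topic_id = topic, doc_id = ranked,
                    rank = seq_len(n_ranked),
                    score = sort(runif(n_ranked), decreasing = TRUE),
                    stringsAsFactors = FALSE)
  qr <- hroc::qrels(rep(topic, length(docs)), docs,
                    as.integer(docs %in% rel))
  list(run = run, qrels = qr, relevant = rel)
}

# small fixed corpus used across module tests
toy_corpus <- function() {
  list(
    d1 = c("heart", "diseas", "china", "treatment", "heart"),
    d2 = c("heart", "failur", "drug", "therapi"),
    d3 = c("china", "travel", "report"),
    d4 = c("diseas", "outbreak", "china", "heart", "diseas"),
    d5 = c("cooking", "recip", "tomato")
  )
}

random_tokens <- function(n, vocab) sample(vocab, n, replace = TRUE)
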