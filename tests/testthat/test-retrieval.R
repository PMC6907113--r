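test_that("bm25 term weight matches a direct formula evaluation", {
  # tf=2, qtf=1, dl=avdl, b=0.5, k1=1.2, k3=8, N=10, df=2, evaluated
  # independently: K = 1.2, doc side 2.2*2/3.2, query side 9*1/9,
  # idf log(8.5/2.5)
  p <- bm25_params(k1 = 1.2, b = 0.5, k3 = 8)
  got <- bm25_term_weight(tf = 2, qtf = 1, dl = 100, df = 2, N = 10,
                          avdl = 100, params = p)
  expect_equal(got, (2.2 * 2 / 3.2) * 1 * log(8.5 / 2.5))

  expect_equal(bm25_term_weight(0, 3, 50, 2, 10, 80), 0)
  expect_error(bm25_term_weight(1, 1, 50, 11, 10, 80), "df > N")
})

test_that("bm25 query factor is monotone and bounded; as_printed is constant", {
  p <- bm25_params()
  qtfs <- c(0.1, 0.5, 1, 2, 5, 20, 100)
  w <- vapply(qtfs, function(q) bm25_term_weight(1, q, 10, 1, 10, 10, p),
              numeric(1))
  expect_true(all(diff(w) > 0))
  cap <- bm25_term_weight(1, 1e9, 10, 1, 10, 10, p)
  expect_true(all(w < cap + 1e-9))
  lit <- bm25_params(as_printed = TRUE)
  w_lit <- vapply(qtfs, function(q) bm25_term_weight(1, q, 10, 1, 10, 10, lit),
                  numeric(1))
  expect_true(all(abs(w_lit - w_lit[1]) < 1e-12))
})

test_that("bm25 single-term score is increasing in tf, non-increasing in dl", {
  p <- bm25_params(b = 0.75)
  w_tf <- vapply(1:10, function(tf) bm25_term_weight(tf, 1, 50, 1, 10, 50, p),
                 numeric(1))
  expect_true(all(diff(w_tf) > 0))
  w_dl <- vapply(c(10, 30, 50, 100, 500),
                 function(dl) bm25_term_weight(2, 1, dl, 1, 10, 50, p),
                 numeric(1))
  expect_true(all(diff(w_dl) < 0))
})

test_that("document score is the sum of per-term weights", {
  idx <- build_index(toy_corpus())
  q <- weighted_query("1", c(heart = 1, diseas = 1, china = 1))
  expect_equal(score_bm25(idx, weighted_query("1", c(absentterm = 1)), "d1"), 0)
  q1 <- weighted_query("1", c(heart = 1))
  expect_equal(score_bm25(idx, q1, "d1"),
               bm25_term_weight(2, 1, 5, 3, 5, idx$avg_dl))
  for (d in names(toy_corpus())) {
    manual <- sum(vapply(names(q$weights), function(term) {
      ts <- term_stats(idx, term, d)
      if (ts$tf == 0) return(0)
      bm25_term_weight(ts$tf, q$weights[[term]], idx$dl[[d]],
                       idx$df[[term]], idx$n_docs, idx$avg_dl)
    }, numeric(1)))
    expect_equal(score_bm25(idx, q, d), manual)
  }
})

test_that("dirichlet smoothing follows the formula", {
  idx <- build_index(list(d1 = c("w", "x", "y", "z"), d2 = c("w", "w", "v")))
  q <- weighted_query("1", c(w = 1))
  expect_equal(score_dirichlet(idx, q, "d1", dirichlet_params(mu = 0)),
               log(1 / 4))
  mu <- 100
  p_c <- 3 / 7
  expect_equal(score_dirichlet(idx, weighted_query("1", c(v = 1)), "d1",
                               dirichlet_params(mu)),
               log((0 + mu * (1 / 7)) / (4 + mu)))
  # unseen-in-collection terms are skipped, never -Inf
  expect_equal(score_dirichlet(idx, weighted_query("1", c(qq = 1)), "d1",
                               dirichlet_params(mu)), 0)
})

test_that("dirichlet ranking equals brute force on a toy collection", {
  idx <- build_index(toy_corpus())
  q <- weighted_query("1", c(heart = 1, china = 2))
  run <- retrieve(idx, q, model = "dirichlet", params = dirichlet_params(100))
  mu <- 100
  brute <- vapply(names(toy_corpus()), function(d) {
    toks <- toy_corpus()[[d]]
    s <- 0
    for (term in c("heart", "china")) {
      qtf <- q$weights[[term]]
      cf <- sum(unlist(toy_corpus()) == term)
      pd <- (sum(toks == term) + mu * cf / idx$total_tokens) /
        (length(toks) + mu)
      s <- s + qtf * log(pd)
    }
    s
  }, numeric(1))
  # candidate docs: those containing at least one query term
  cand <- names(brute)[vapply(toy_corpus(), function(t) {
    any(c("heart", "china") %in% t)
  }, logical(1))]
  brute <- sort(brute[cand], decreasing = TRUE)
  expect_equal(run$doc_id, names(brute))
  expect_equal(run$score, unname(brute))
})

test_that("dirichlet ranking is invariant to scaling query weights", {
  idx <- build_index(toy_corpus())
  q1 <- weighted_query("1", c(heart = 1, china = 1))
  q2 <- weighted_query("1", c(heart = 7, china = 7))
  r1 <- retrieve(idx, q1, model = "dirichlet")
  r2 <- retrieve(idx, q2, model = "dirichlet")
  expect_equal(r1$doc_id, r2$doc_id)
  expect_equal(r2$score, 7 * r1$score)
})

test_that("retrieve ranks, truncates and tie-breaks deterministically", {
  # single matching doc among non-matching ones ranks first
  idx1 <- build_index(list(only = c("t", "u"), z1 = c("v"), z2 = c("w")))
  run <- retrieve(idx1, weighted_query("1", c(t = 1)))
  expect_equal(run$doc_id, "only")
  expect_equal(run$rank, 1L)

  # identical duplicate documents: adjacent, id-ordered
  idx2 <- build_index(list(b = c("t", "x"), a = c("t", "x"),
                           c1 = "y", c2 = "y", c3 = "y"))
  run2 <- retrieve(idx2, weighted_query("1", c(t = 1)))
  expect_equal(run2$doc_id, c("a", "b"))

  idx <- build_index(toy_corpus())
  q <- weighted_query("7", c(heart = 1, diseas = 1))
  run3 <- retrieve(idx, q, cutoff = 3)
  all_scores <- vapply(names(toy_corpus()), function(d) {
    score_bm25(idx, q, d)
  }, numeric(1))
  all_scores <- all_scores[all_scores > 0]
  ord <- order(-all_scores, names(all_scores), method = "radix")
  expect_equal(run3$doc_id, utils::head(names(all_scores)[ord], 3))
  expect_true(all(diff(run3$score) <= 0))
  expect_lte(nrow(run3), 3L)

  expect_error(retrieve(idx, weighted_query("1", numeric())), "empty query")
})

test_that("repeated retrieval produces byte-identical run files", {
  idx <- build_index(toy_corpus())
  q <- weighted_query("1", c(heart = 1, china = 1))
  f1 <- tempfile(); f2 <- tempfile()
  write_run(retrieve(idx, q), f1)
  write_run(retrieve(idx, q), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
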