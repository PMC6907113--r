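test_that("normalizations hit their forced values", {
  expect_equal(unname(normalize_scores(c(a = 1, b = 2, c = 3), "norm1")),
               c(0, 0.5, 1))
  expect_equal(unname(normalize_scores(c(a = 3, b = 4), "norm2")),
               c(0.6, 0.8))
  expect_equal(unname(normalize_scores(c(a = 2, b = 4), "norm3")),
               c(0.5, 1))
  expect_warning(z <- normalize_scores(c(a = 2, b = 2), "norm1"), "degenerate")
  expect_equal(unname(z), c(0, 0))
  expect_equal(unname(normalize_scores(c(a = 0, b = 0), "norm2")), c(0, 0))
  expect_equal(unname(normalize_scores(c(a = 0, b = 0), "norm3")), c(0, 0))
})

test_that("normalization contracts hold on random vectors", {
  set.seed(301)
  for (rep in 1:200) {
    n <- sample(2:20, 1)
    x <- stats::setNames(stats::runif(n, 0, 100), paste0("t", seq_len(n)))
    if (max(x) == min(x)) next
    n1 <- normalize_scores(x, "norm1")
    expect_true(all(n1 >= 0 & n1 <= 1))
    expect_equal(min(n1), 0)
    expect_equal(max(n1), 1)
    n2 <- normalize_scores(x, "norm2")
    expect_equal(sqrt(sum(n2^2)), 1)
    n3 <- normalize_scores(x, "norm3")
    expect_equal(max(n3), 1)
    expect_identical(names(n1), names(x))
  }
})

test_that("bm25 feedback weight saturates and matches direct evaluation", {
  idx <- build_index(toy_corpus())
  expect_equal(bm25_feedback_weight(idx, "cooking", "d1"), 0)
  p <- bm25_params()
  # direct evaluation: diseas tf=2 in d4, dl=5, df=2, N=5
  K <- p$k1 * ((1 - p$b) + p$b * 5 / idx$avg_dl)
  expect_equal(bm25_feedback_weight(idx, "diseas", "d4", p),
               (p$k1 + 1) * 2 / (K + 2) * log((5 - 2 + 0.5) / 2.5))
  # bounded saturation in tf
  idx_big <- build_index(list(d = rep(c("t", "x"), c(50, 5)),
                              e1 = "y", e2 = "y", e3 = "y"))
  w <- bm25_feedback_weight(idx_big, "t", "d")
  cap <- (p$k1 + 1) * unname(idf(idx_big, "t"))
  expect_lt(w, cap)
  expect_gt(w, 0.9 * cap)
})

test_that("rocchio expansion reduces and averages correctly", {
  idx <- build_index(toy_corpus())
  q0 <- weighted_query("1", c(heart = 1, china = 1))

  # beta = 0: pure rescaling of the original query
  q_b0 <- rocchio_expand(idx, q0, c("d1", "d2"), alpha = 0.7, beta = 0)
  expect_equal(q_b0$weights[names(q0$weights)], 0.7 * q0$weights)
  expect_setequal(names(q_b0$weights), names(q0$weights))

  # alpha = 1, beta = 1, one feedback doc: Q0 + r
  r <- vapply(unique(toy_corpus()$d2), function(t) {
    bm25_feedback_weight(idx, t, "d2")
  }, numeric(1))
  q_sum <- rocchio_expand(idx, q0, "d2", alpha = 1, beta = 1, n_terms = 50)
  manual <- q0$weights
  for (t in names(r)) {
    manual[t] <- if (t %in% names(manual)) manual[[t]] + r[[t]] else r[[t]]
  }
  manual <- manual[manual != 0]
  expect_equal(q_sum$weights[sort(names(q_sum$weights))],
               manual[sort(names(manual))])

  # two feedback docs: centroid is the per-term arithmetic mean
  q_c <- rocchio_expand(idx, q0, c("d1", "d4"), alpha = 1, beta = 1,
                        n_terms = 50)
  terms <- setdiff(unique(c(toy_corpus()$d1, toy_corpus()$d4)),
                   names(q0$weights))
  for (t in terms) {
    mean_w <- (bm25_feedback_weight(idx, t, "d1") +
                 bm25_feedback_weight(idx, t, "d4")) / 2
    expect_equal(unname(q_c$weights[[t]]), mean_w)
  }
  expect_error(rocchio_expand(idx, q0, character()), "empty feedback")
})

test_that("hroc_expand with alpha = 0 is the identity on Q0", {
  idx <- build_index(toy_corpus())
  q0 <- weighted_query("1", c(heart = 1, china = 2))
  cfg <- hroc_config(alpha = 0, beta = 0.5)
  out <- hroc_expand(idx, q0, c("d1", "d2"), cfg)
  expect_identical(out$weights, q0$weights)
  expect_identical(out$topic_id, q0$topic_id)
})

test_that("hroc_expand with beta = 0 equals a normalized Rocchio", {
  set.seed(302)
  vocab <- c("q1", "q2", letters[1:10])
  docs <- lapply(1:8, function(i) random_tokens(sample(15:30, 1), vocab))
  names(docs) <- paste0("d", 1:8)
  idx <- build_index(docs)
  q0 <- weighted_query("1", c(q1 = 1, q2 = 1))
  fb <- c("d1", "d2", "d3")
  for (norm in c("norm1", "norm2", "norm3")) {
    cfg <- hroc_config(alpha = 0.6, beta = 0, n_expansion_terms = 5,
                       norm_method = norm)
    got <- suppressWarnings(hroc_expand(idx, q0, fb, cfg))
    # independent reconstruction: normalized mean BM25 vector, top-5,
    # alpha-mixed
    vecs <- lapply(fb, function(d) {
      terms <- unique(docs[[d]])
      stats::setNames(vapply(terms, function(t) {
        bm25_feedback_weight(idx, t, d)
      }, numeric(1)), terms)
    })
    all_terms <- sort(unique(unlist(lapply(vecs, names))))
    mean_r <- vapply(all_terms, function(t) {
      mean(vapply(vecs, function(v) if (t %in% names(v)) v[[t]] else 0,
                  numeric(1)))
    }, numeric(1))
    cand <- mean_r[setdiff(names(mean_r), c("q1", "q2"))]
    n_cand <- suppressWarnings(normalize_scores(cand, norm))
    keep <- names(sort(n_cand, decreasing = TRUE))
    keep <- keep[order(-n_cand[keep], keep)][1:5]
    want <- c(0.4 * q0$weights, 0.6 * n_cand[keep])
    want <- want[want != 0]
    expect_equal(got$weights[sort(names(got$weights))],
                 want[sort(names(want))])
  }
})

test_that("hroc expansion keeps original query terms when alpha < 1", {
  idx <- build_index(toy_corpus())
  q0 <- weighted_query("1", c(heart = 1, china = 1))
  for (alpha in c(0.1, 0.5, 0.9)) {
    cfg <- hroc_config(alpha = alpha, beta = 0.5, n_expansion_terms = 3)
    out <- suppressWarnings(hroc_expand(idx, q0, c("d1", "d4"), cfg))
    expect_true(all(names(q0$weights) %in% names(out$weights)))
  }
})

test_that("all-zero proximity components fall back with a warning", {
  # query terms occur but no candidate within the window
  idx <- build_index(list(
    d1 = c("q1", "x", "x", "x", "x", "x", "x", "t"),
    d2 = c("u", "v")
  ))
  q0 <- weighted_query("1", c(q1 = 1))
  cfg <- hroc_config(alpha = 0.5, beta = 0.5,
                     window = window_spec("fixed", D = 1),
                     n_expansion_terms = 3)
  # d1: only "x" is adjacent to q1 -> not all-zero; use d2 (no query term)
  expect_warning(hroc_expand(idx, q0, "d2", cfg), "falling back")
  expect_error(hroc_expand(idx, q0, character(), cfg), "empty feedback")
})

test_that("full expansion vector matches an end-to-end hand computation", {
  # 5 tiny documents, 2-term query, D = 3, norm1 — scripted independently
  docs <- list(
    f1 = c("q1", "t", "q2", "u", "x"),
    f2 = c("t", "q1", "y", "u", "q2", "t"),
    d3 = c("x", "y", "z"),
    d4 = c("q1", "z", "z", "x"),
    d5 = c("u", "u", "y")
  )
  idx <- build_index(docs)
  q0 <- weighted_query("9", c(q1 = 1, q2 = 1))
  fb <- c("f1", "f2")
  cfg <- hroc_config(alpha = 0.5, beta = 0.5, n_expansion_terms = 2,
                     window = window_spec("fixed", D = 3),
                     norm_method = "norm1")
  got <- hroc_expand(idx, q0, fb, cfg)

  # oracle: brute-force every quantity from definitions
  p <- bm25_params()
  r_vec <- function(d) {
    terms <- unique(docs[[d]])
    K <- p$k1 * ((1 - p$b) + p$b * length(docs[[d]]) / idx$avg_dl)
    stats::setNames(vapply(terms, function(t) {
      tf <- sum(docs[[d]] == t)
      idf_t <- max(0, log((5 - unname(idx$df[[t]]) + 0.5) /
                            (unname(idx$df[[t]]) + 0.5)))
      (p$k1 + 1) * tf / (K + tf) * idf_t
    }, numeric(1)), terms)
  }
  hal_vec <- function(d) {
    terms <- unique(docs[[d]])
    stats::setNames(vapply(terms, function(t) {
      sum(vapply(c("q1", "q2"), function(qt) {
        oracle_hal_score(docs[[d]], t, qt, 3) *
          max(0, log((5 - unname(idx$df[[qt]]) + 0.5) /
                       (unname(idx$df[[qt]]) + 0.5)))
      }, numeric(1)))
    }, numeric(1)), terms)
  }
  mean_of <- function(vecs) {
    terms <- sort(unique(unlist(lapply(vecs, names))))
    vapply(terms, function(t) {
      mean(vapply(vecs, function(v) if (t %in% names(v)) v[[t]] else 0,
                  numeric(1)))
    }, numeric(1))
  }
  mr <- mean_of(lapply(fb, r_vec))
  mh <- mean_of(lapply(fb, hal_vec))
  cand <- sort(setdiff(unique(c(names(mr), names(mh))), c("q1", "q2")))
  mr <- vapply(cand, function(t) if (t %in% names(mr)) mr[[t]] else 0,
               numeric(1))
  mh <- vapply(cand, function(t) if (t %in% names(mh)) mh[[t]] else 0,
               numeric(1))
  nr <- (mr - min(mr)) / (max(mr) - min(mr))
  nh <- (mh - min(mh)) / (max(mh) - min(mh))
  comb <- 0.5 * nr + 0.5 * nh
  top2 <- names(sort(comb, decreasing = TRUE))
  top2 <- top2[order(-comb[top2], top2)][1:2]
  want <- c(0.5 * q0$weights, 0.5 * comb[top2])
  want <- want[want != 0]
  expect_equal(got$weights[sort(names(got$weights))],
               want[sort(names(want))])
})

test_that("second pass with the unexpanded query equals the first pass", {
  idx <- build_index(toy_corpus())
  q0 <- weighted_query("1", c(heart = 1, china = 1))
  first <- retrieve(idx, q0, model = "bm25")
  second <- second_pass(idx, q0)
  expect_identical(first, second)
})
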