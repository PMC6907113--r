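test_that("average precision follows from the definition", {
  qr <- qrels(c("1", "1"), c("r1", "r2"), c(1L, 0L))
  run1 <- data.frame(topic_id = "1", doc_id = c("r1", "x"), rank = 1:2,
                     score = c(2, 1), stringsAsFactors = FALSE)
  expect_equal(average_precision(run1, qr), 1.0)

  run2 <- data.frame(topic_id = "1", doc_id = c("x", "r1"), rank = 1:2,
                     score = c(2, 1), stringsAsFactors = FALSE)
  expect_equal(average_precision(run2, qr), 0.5)

  # topic without relevant judgments is removed with a warning
  qr0 <- qrels("2", "y", 1L)
  expect_warning(ap <- average_precision(run1, qr0, topic = "1"), "removed")
  expect_true(is.na(ap))
})

test_that("precision at k pads short rankings as non-relevant", {
  qr <- qrels(rep("1", 5), paste0("r", 1:5), rep(1L, 5))
  run <- data.frame(topic_id = "1", doc_id = paste0("r", 1:5), rank = 1:5,
                    score = 5:1, stringsAsFactors = FALSE)
  expect_equal(precision_at_k(run, qr, 5), 1.0)
  run2 <- data.frame(topic_id = "1", doc_id = c("r1", "x", "r2", "y", "z"),
                     rank = 1:5, score = 5:1, stringsAsFactors = FALSE)
  expect_equal(precision_at_k(run2, qr, 5), 0.4)
  short <- run[1:2, ]
  expect_equal(precision_at_k(short, qr, 10), 0.2)
})

test_that("f1 is the harmonic mean with a zero guard", {
  expect_equal(f1_score(0.5, 0.5), 0.5)
  expect_equal(f1_score(1, 0), 0)
  expect_equal(f1_score(0, 0), 0)
  expect_equal(f1_score(0.25, 0.75), 0.375)
})

test_that("MAP and P@k equal the reference evaluator on random runs", {
  set.seed(401)
  for (rep in 1:50) {
    rq <- random_run_and_qrels(as.character(rep))
    ap <- average_precision(rq$run, rq$qrels)
    n_rel <- sum(rq$qrels$grade > 0)
    expect_equal(ap, oracle_average_precision(rq$run$doc_id, rq$relevant,
                                              n_rel))
    for (k in c(5, 10, 20)) {
      expect_equal(precision_at_k(rq$run, rq$qrels, k),
                   oracle_precision_at_k(rq$run$doc_id, rq$relevant, k))
    }
    rep_all <- evaluate_run(rq$run, rq$qrels)
    expect_equal(rep_all$means[["map"]], ap)
    expect_equal(rep_all$means[["p_at_10"]],
                 oracle_precision_at_k(rq$run$doc_id, rq$relevant, 10))
  }
})

test_that("evaluate_run averages per-topic values and bounds hold", {
  set.seed(402)
  runs <- list(); qrs <- list()
  for (tp in 1:6) {
    rq <- random_run_and_qrels(as.character(tp))
    runs[[tp]] <- rq$run
    qrs[[tp]] <- rq$qrels
  }
  run <- do.call(rbind, runs)
  qr <- do.call(rbind, qrs)
  class(qr) <- c("qrels", "data.frame")
  rep_all <- evaluate_run(run, qr)
  expect_equal(nrow(rep_all$per_topic), 6L)
  expect_true(all(as.matrix(rep_all$per_topic[, -1]) >= 0))
  expect_true(all(as.matrix(rep_all$per_topic[, -1]) <= 1))
  expect_equal(unname(rep_all$means["map"]), mean(rep_all$per_topic$ap))
  expect_equal(unname(rep_all$means["f1"]), mean(rep_all$per_topic$f1))
  # judged topic missing from the run scores zero
  qr_extra <- qrels("99", "zz", 1L)
  qr2 <- rbind(qr, qr_extra)
  class(qr2) <- c("qrels", "data.frame")
  rep2 <- evaluate_run(run, qr2)
  expect_equal(rep2$per_topic$ap[rep2$per_topic$topic_id == "99"], 0)
})

test_that("P@k is non-increasing in k for perfect-prefix rankings", {
  qr <- qrels(rep("1", 3), paste0("r", 1:3), rep(1L, 3))
  run <- data.frame(topic_id = "1",
                    doc_id = c(paste0("r", 1:3), paste0("n", 1:17)),
                    rank = 1:20, score = 20:1, stringsAsFactors = FALSE)
  pk <- vapply(c(1, 3, 5, 10, 20), function(k) precision_at_k(run, qr, k),
               numeric(1))
  expect_true(all(diff(pk) <= 0))
})

test_that("parity split partitions topics by number", {
  sp <- parity_split(c("1", "2", "3", "4"))
  expect_setequal(sp$odd, c("1", "3"))
  expect_setequal(sp$even, c("2", "4"))
  sp1 <- parity_split("7")
  expect_identical(sp1$odd, "7")
  expect_length(sp1$even, 0L)
  ids <- as.character(sample(1:1000, 30))
  sp30 <- parity_split(ids)
  expect_setequal(c(sp30$odd, sp30$even), ids)
  expect_length(intersect(sp30$odd, sp30$even), 0L)
  expect_error(parity_split(c("1", "abc")), "abc")
})

test_that("grid sweep is exhaustive with first-in-grid tie-breaking", {
  g1 <- data.frame(b = 0.4)
  sw1 <- grid_sweep(g1, function(row) row$b)
  expect_equal(sw1$best$b, 0.4)

  g2 <- data.frame(b = c(0.1, 0.2, 0.3))
  sw2 <- grid_sweep(g2, function(row) 7)  # constant objective
  expect_equal(sw2$best$b, 0.1)

  grid <- expand.grid(alpha = c(0.2, 0.8), beta = c(0.1, 0.9))
  fn <- function(row) -(row$alpha - 0.75)^2 - (row$beta - 0.2)^2
  sw <- grid_sweep(grid, fn)
  brute <- grid[which.max(apply(grid, 1, function(r) {
    -(r[["alpha"]] - 0.75)^2 - (r[["beta"]] - 0.2)^2
  })), ]
  expect_equal(sw$best$alpha, brute$alpha)
  expect_equal(sw$best$beta, brute$beta)
  expect_equal(nrow(sw$results), 4L)
  expect_error(grid_sweep(grid[0, , drop = FALSE], fn), "empty grid")
})

test_that("cross-validated sweep selects on the training fold only", {
  topics <- as.character(1:10)
  grid <- data.frame(x = c(1, 2, 3))
  # objective: config x = 2 is best on odd topics, x = 3 on even topics
  eval_fn <- function(row, fold_topics) {
    odd <- all(as.integer(fold_topics) %% 2 == 1)
    if (odd) c(1, 5, 2)[row$x] else c(1, 2, 5)[row$x]
  }
  cv <- cv_sweep(topics, grid, eval_fn)
  train_odd <- cv$folds[[1]]
  expect_equal(train_odd$train_best$x, 2)          # chosen on odd fold
  expect_equal(train_odd$test_objective, 2)        # applied to even fold
  train_even <- cv$folds[[2]]
  expect_equal(train_even$train_best$x, 3)
  expect_equal(train_even$test_objective, 2)
  expect_equal(cv$mean_test_objective, 2)
})

test_that("paired significance reports both tests", {
  set.seed(403)
  x <- runif(20); y <- x + runif(20, 0, 0.3)
  p <- paired_significance(x, y)
  expect_named(p, c("t_p_value", "wilcoxon_p_value"))
  expect_true(all(p > 0 & p <= 1))
  expect_lt(p[["wilcoxon_p_value"]], 0.05)
})
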