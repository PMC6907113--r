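#' Relevance judgments (qrels)
#'
#' Constructor/validator for a qrels data frame: one row per judged
#' (topic, document) pair with an integer relevance grade; grades above zero
#' count as relevant (graded judgments are binarized downstream).
#'
#' @param topic_id character or coercible vector.
#' @param doc_id character vector.
#' @param grade integer vector (>= 0).
#' @return data frame of class `qrels` with columns `topic_id`, `doc_id`,
#'   `grade`.
#' @export
qrels <- function(topic_id, doc_id, grade) {
  topic_id <- as.character(topic_id)
  doc_id <- as.character(doc_id)
  grade <- as.integer(grade)
  stopifnot(length(topic_id) == length(doc_id),
            length(doc_id) == length(grade), all(grade >= 0))
  key <- paste(topic_id, doc_id)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (topic, doc) judgment(s): ", paste(dup, collapse = ", "))
  }
  structure(data.frame(topic_id = topic_id, doc_id = doc_id, grade = grade,
                       stringsAsFactors = FALSE),
            class = c("qrels", "data.frame"))
}

# relevant doc ids for one topic
.relevant_docs <- function(qr, topic) {
  qr$doc_id[qr$topic_id == topic & qr$grade > 0]
}

# top-`cutoff` doc ids of one topic from a run data frame, in rank order
.topic_docs <- function(run, topic, cutoff) {
  r <- run[run$topic_id == topic, , drop = FALSE]
  r <- r[order(r$rank), , drop = FALSE]
  utils::head(r$doc_id, cutoff)
}

#' Average precision of one topic
#'
#' Mean over the relevant retrieved ranks `r` (within the cutoff) of
#' precision at `r`, divided by the total number of relevant documents for
#' the topic. Unjudged documents count as non-relevant.
#'
#' @param run a run data frame (`topic_id`, `doc_id`, `rank`, `score`)
#'   containing the topic.
#' @param qr a [qrels()] data frame.
#' @param topic topic id (defaults to the single topic in `run`).
#' @param cutoff rank cutoff (default 1000).
#' @return average precision in `[0, 1]`; `NA` with a warning when the topic
#'   has no relevant document in the qrels (such topics are removed from
#'   averages).
#' @export
average_precision <- function(run, qr, topic = NULL, cutoff = 1000) {
  if (is.null(topic)) topic <- unique(run$topic_id)
  stopifnot(length(topic) == 1L)
  rel <- .relevant_docs(qr, topic)
  if (!length(rel)) {
    warning("topic ", topic, " has no relevant document in the qrels; removed")
    return(NA_real_)
  }
  docs <- .topic_docs(run, topic, cutoff)
  if (!length(docs)) return(0)
  hits <- docs %in% rel
  if (!any(hits)) return(0)
  prec_at_hit <- cumsum(hits)[hits] / which(hits)
  sum(prec_at_hit) / length(rel)
}

#' Precision at rank k of one topic
#'
#' Fraction of the top `k` retrieved documents that are relevant; rankings
#' shorter than `k` are padded as non-relevant.
#'
#' @inheritParams average_precision
#' @param k rank depth.
#' @return precision in `[0, 1]`.
#' @export
precision_at_k <- function(run, qr, k, topic = NULL) {
  if (is.null(topic)) topic <- unique(run$topic_id)
  stopifnot(length(topic) == 1L, k >= 1)
  rel <- .relevant_docs(qr, topic)
  docs <- .topic_docs(run, topic, k)
  sum(docs %in% rel) / k
}

#' Recall at a rank cutoff of one topic
#'
#' @inheritParams average_precision
#' @return recall in `[0, 1]`; `NA` when the topic has no relevant document.
#' @export
recall_at_cutoff <- function(run, qr, topic = NULL, cutoff = 1000) {
  if (is.null(topic)) topic <- unique(run$topic_id)
  stopifnot(length(topic) == 1L)
  rel <- .relevant_docs(qr, topic)
  if (!length(rel)) return(NA_real_)
  docs <- .topic_docs(run, topic, cutoff)
  sum(docs %in% rel) / length(rel)
}

#' F1 score
#'
#' Harmonic mean of precision and recall, `2PR / (P + R)`; 0 when both are 0.
#'
#' @param precision,recall values in `[0, 1]`. Vectorized.
#' @return F1 in `[0, 1]`.
#' @export
#' @examples
#' f1_score(0.25, 0.75)  # 0.375
f1_score <- function(precision, recall) {
  stopifnot(all(precision >= 0 & precision <= 1, na.rm = TRUE),
            all(recall >= 0 & recall <= 1, na.rm = TRUE))
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Evaluate a run against qrels
#'
#' Per-topic and mean MAP, P@k for `k` in `ks`, recall at the cutoff, and F1.
#' Precision for F1 is computed at the same cutoff as recall, so both refer
#' to the same retrieved set. Topics present in the run but without relevant
#' documents in the qrels are removed (with a warning from
#' [average_precision()]); topics judged in the qrels but missing from the
#' run score zero.
#'
#' @param run a run data frame (possibly many topics).
#' @param qr a [qrels()] data frame.
#' @param cutoff rank cutoff for MAP/recall/precision (default 1000).
#' @param ks depths for P@k (default `c(5, 10, 20)`).
#' @return list of class `metric_report` with `per_topic` (data frame) and
#'   `means` (named numeric: `map`, `p_at_k...`, `recall`, `f1`).
#' @export
evaluate_run <- function(run, qr, cutoff = 1000, ks = c(5, 10, 20)) {
  topics <- sort(unique(c(run$topic_id, qr$topic_id[qr$grade > 0])))
  rows <- lapply(topics, function(tp) {
    rel <- .relevant_docs(qr, tp)
    if (!length(rel)) return(NULL)
    docs <- .topic_docs(run, tp, cutoff)
    ap <- if (length(docs)) average_precision(run, qr, tp, cutoff) else 0
    pk <- vapply(ks, function(k) {
      if (length(docs)) precision_at_k(run, qr, k, tp) else 0
    }, numeric(1))
    rc <- sum(docs %in% rel) / length(rel)
    pr <- if (length(docs)) sum(docs %in% rel) / length(docs) else 0
    c(ap = ap, stats::setNames(pk, paste0("p_at_", ks)), recall = rc,
      precision = pr, f1 = f1_score(pr, rc))
  })
  keep <- !vapply(rows, is.null, logical(1))
  per_topic <- do.call(rbind, rows[keep])
  per_topic <- data.frame(topic_id = topics[keep], per_topic,
                          stringsAsFactors = FALSE, row.names = NULL)
  means <- colMeans(per_topic[, -1, drop = FALSE])
  names(means)[names(means) == "ap"] <- "map"
  structure(list(per_topic = per_topic, means = means),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>", nrow(x$per_topic), "topics\n")
  print(round(x$means, 4))
  invisible(x)
}

#' Split topics by the parity of their numbers
#'
#' Deterministic two-fold partition used for cross-validation: topics with
#' odd numeric ids in one fold, even in the other.
#'
#' @param topic_ids vector of topic ids carrying an integer component.
#' @return list with elements `odd` and `even` (character vectors; union =
#'   input, intersection empty).
#' @export
#' @examples
#' parity_split(c("1", "2", "3", "4"))
parity_split <- function(topic_ids) {
  topic_ids <- as.character(topic_ids)
  nums <- suppressWarnings(as.integer(gsub("[^0-9]", "", topic_ids)))
  if (anyNA(nums)) {
    stop("non-numeric topic id(s): ",
         paste(topic_ids[is.na(nums)], collapse = ", "))
  }
  list(odd = topic_ids[nums %% 2L == 1L],
       even = topic_ids[nums %% 2L == 0L])
}

#' Exhaustive grid sweep
#'
#' Evaluates an objective (mean MAP by default, but any scalar) at every row
#' of a configuration grid and returns the best row, ties broken by
#' first-in-grid order.
#'
#' @param grid data frame; one row per configuration.
#' @param eval_fn function taking one grid row (as a one-row data frame) and
#'   returning a scalar objective to maximize.
#' @return list with `best` (the winning row), `best_objective`, and
#'   `results` (the grid with an `objective` column appended).
#' @export
grid_sweep <- function(grid, eval_fn) {
  stopifnot(is.data.frame(grid))
  if (!nrow(grid)) stop("empty grid")
  obj <- vapply(seq_len(nrow(grid)), function(i) {
    as.numeric(eval_fn(grid[i, , drop = FALSE]))
  }, numeric(1))
  best_i <- which.max(obj)  # first maximum wins ties
  results <- cbind(grid, objective = obj)
  list(best = grid[best_i, , drop = FALSE],
       best_objective = obj[best_i],
       results = results)
}

#' Two-fold cross-validated sweep over parity folds
#'
#' Selects the best configuration on each training fold with [grid_sweep()]
#' and applies it once to the held-out fold; no test-fold information is used
#' during selection.
#'
#' @param topic_ids all topic ids.
#' @param grid configuration grid (data frame).
#' @param eval_fn function(config_row, topic_ids) -> scalar objective on
#'   those topics.
#' @return list with per-fold elements `train_best` and `test_objective`,
#'   plus `mean_test_objective`.
#' @export
cv_sweep <- function(topic_ids, grid, eval_fn) {
  folds <- parity_split(topic_ids)
  out <- lapply(list(c(train = "odd", test = "even"),
                     c(train = "even", test = "odd")), function(fd) {
    sw <- grid_sweep(grid, function(row) eval_fn(row, folds[[fd[["train"]]]]))
    list(train_fold = fd[["train"]],
         train_best = sw$best,
         test_objective = eval_fn(sw$best, folds[[fd[["test"]]]]))
  })
  list(folds = out,
       mean_test_objective = mean(vapply(out, `[[`, numeric(1),
                                         "test_objective")))
}

#' Paired significance tests between two runs
#'
#' Two-sided paired t-test and Wilcoxon signed-rank test over per-topic
#' metric values of two systems on the same topics; both p-values are
#' reported side by side. Delegates to [stats::t.test()] and
#' [stats::wilcox.test()].
#'
#' @param x,y numeric vectors of per-topic metric values, aligned by topic.
#' @return named numeric vector with `t_p_value` and `wilcoxon_p_value`.
#' @export
paired_significance <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  t_p <- tryCatch(stats::t.test(x, y, paired = TRUE)$p.value,
                  error = function(e) NA_real_)
  w_p <- tryCatch(suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE)$p.value),
    error = function(e) NA_real_)
  c(t_p_value = t_p, wilcoxon_p_value = w_p)
}
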