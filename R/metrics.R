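# Classification, ranking and representation-quality metrics.

#' Area under the ROC curve
#'
#' Rank formula: the probability that a uniformly random positive outranks a
#' uniformly random negative, with ties counting one half (midrank
#' convention).
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1), both classes present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUROC requires both classes", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise (average precision) interpolation: walking down the ranking,
#' each increment in recall contributes the precision at that point. Tied
#' scores are processed as one group.
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1), at least one positive.
#' @return AUPR in \[0, 1\].
#' @export
aupr <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  if (n1 == 0L) stop("AUPR requires at least one positive", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # group boundaries: last index of each tied-score block
  ends <- which(c(s[-1L] != s[-length(s)], TRUE))
  tp <- cumsum(y)[ends]
  npred <- ends
  prec <- tp / npred
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' F1 score and accuracy at a threshold
#'
#' F1 is defined as 0 when precision + recall is 0.
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @param theta threshold (calls positive at `score >= theta`).
#' @return list with `f1` and `accuracy`.
#' @export
f1_accuracy <- function(scores, labels, theta) {
  labels <- as.integer(labels)
  pred <- binarize(scores, theta)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(f1 = f1, accuracy = mean(pred == labels))
}

#' Threshold-based and threshold-free classification metrics
#'
#' @param scores numeric scores.
#' @param labels binary labels (both classes present).
#' @param theta threshold for F1/accuracy.
#' @return list with `auroc`, `aupr`, `f1`, `accuracy`.
#' @export
classification_metrics <- function(scores, labels, theta) {
  fa <- f1_accuracy(scores, labels, theta)
  list(auroc = auroc(scores, labels), aupr = aupr(scores, labels),
       f1 = fa$f1, accuracy = fa$accuracy)
}

#' Top-K ranking metrics over per-query candidate tables
#'
#' For each query the candidates are sorted by decreasing score (stable in
#' input order for ties). Reports Precision@K and Recall@K for each K,
#' reciprocal rank of the first relevant candidate, and NDCG@10 with binary
#' gains, `1/log2(rank + 1)` discounts and ideal normalization; all
#' macro-averaged over queries. Queries without any relevant candidate are
#' excluded with a warning.
#'
#' @param table data.frame with columns `query`, `candidate`, `score`,
#'   `relevant` (0/1).
#' @param K integer vector of cutoffs (default `c(1, 3)`).
#' @param ndcg_k NDCG cutoff (default 10).
#' @return list with `p_at`, `r_at` (named by K), `mrr`, `ndcg`, `n_queries`.
#' @export
ranking_metrics <- function(table, K = c(1L, 3L), ndcg_k = 10L) {
  stopifnot(all(c("query", "candidate", "score", "relevant") %in% names(table)))
  queries <- split(table, table$query)
  has_rel <- vapply(queries, function(q) any(q$relevant == 1), logical(1))
  if (any(!has_rel)) {
    warning(sprintf("%d quer%s without relevant candidates excluded",
                    sum(!has_rel), if (sum(!has_rel) == 1) "y" else "ies"))
    queries <- queries[has_rel]
  }
  if (length(queries) == 0L) stop("no query has a relevant candidate", call. = FALSE)
  p_at <- matrix(0, length(queries), length(K))
  r_at <- matrix(0, length(queries), length(K))
  rr <- numeric(length(queries))
  ndcg <- numeric(length(queries))
  for (qi in seq_along(queries)) {
    q <- queries[[qi]]
    ord <- order(-q$score)
    rel <- q$relevant[ord]
    n_rel <- sum(rel)
    for (ki in seq_along(K)) {
      k <- min(K[ki], length(rel))
      hits <- sum(rel[seq_len(k)])
      p_at[qi, ki] <- hits / K[ki]
      r_at[qi, ki] <- hits / n_rel
    }
    rr[qi] <- 1 / which(rel == 1)[1L]
    k <- min(ndcg_k, length(rel))
    dcg <- sum(rel[seq_len(k)] / log2(seq_len(k) + 1))
    ideal <- sum(1 / log2(seq_len(min(n_rel, k)) + 1))
    ndcg[qi] <- dcg / ideal
  }
  list(p_at = stats::setNames(colMeans(p_at), paste0("P@", K)),
       r_at = stats::setNames(colMeans(r_at), paste0("R@", K)),
       mrr = mean(rr), ndcg = mean(ndcg), n_queries = length(queries))
}

#' Cohen's d with pooled standard deviation
#'
#' @param x,y numeric samples.
#' @return standardized mean difference `(mean(x) - mean(y)) / s_pooled`.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- if (nx + ny > 2) {
    sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2))
  } else {
    0
  }
  if (!is.finite(sp) || sp == 0) {
    return(if (mean(x) == mean(y)) 0 else Inf * sign(mean(x) - mean(y)))
  }
  (mean(x) - mean(y)) / sp
}

#' Normalized mutual information between two labelings
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return NMI in \[0, 1\].
#' @export
nmi <- function(a, b) {
  a <- as.integer(factor(a))
  b <- as.integer(factor(b))
  igraph::compare(a, b, method = "nmi")
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b label vectors of equal length.
#' @return ARI (1 = identical partitions, ~0 under independence).
#' @export
ari <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}
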