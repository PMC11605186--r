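#' ROC curve with tie grouping
#'
#' Sweeps thresholds over the unique scores (descending), grouping tied
#' scores into a single step, and returns true- and false-positive rates
#' (`TPR = TP/(TP+FN)`, `FPR = FP/(FP+TN)`). Curves start at (0,0) and end
#' at (1,1); the area is computed by the trapezoidal rule.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary labels.
#' @return A `roc_result`: list(thresholds, tpr, fpr, auroc).
#' @export
roc_curve <- function(scores, labels) {
  if (length(unique(labels)) < 2L)
    ecn_stop("both classes must be present", "evaluation_error")
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # collapse tied scores into single steps
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- which(!duplicated(grp, fromLast = TRUE))
  n1 <- sum(y); n0 <- length(y) - n1
  tpr <- c(0, tp[last] / n1)
  fpr <- c(0, fp[last] / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(thresholds = c(Inf, s[last]), tpr = tpr, fpr = fpr,
                 auroc = auc),
            class = "roc_result")
}

#' Area under the ROC curve
#'
#' Computed in the Mann-Whitney form: the fraction of positive-negative
#' pairs in which the positive outscores the negative, with tied pairs
#' credited one half. Equals the trapezoidal area under [roc_curve()].
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @return AUROC in \[0,1\].
#' @export
auroc <- function(scores, labels) {
  if (length(unique(labels)) < 2L)
    ecn_stop("both classes must be present", "evaluation_error")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-condition transfer-testing matrix
#'
#' Evaluates each condition-pair model on the held-out test split of every
#' condition pair: `M[i, j]` is the AUROC of the model trained on pair i
#' applied to the test split of pair j, so the diagonal holds self-test
#' AUROCs. Feature-schema hashes are checked before any evaluation.
#'
#' @param models named list of `trained_model`s (one per condition pair).
#' @param datasets named list of `encoded_dataset`s, same names/order.
#' @param split evaluation split of the target dataset (default "test").
#' @return A `cross_test_matrix`: list(conditions, matrix).
#' @export
cross_test <- function(models, datasets, split = "test") {
  stopifnot(length(models) == length(datasets))
  k <- length(models)
  ids <- names(models) %||% as.character(seq_len(k))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    hi <- models[[i]]$schema_hash
    hj <- if (!is.null(datasets[[j]]$schema))
      schema_hash(datasets[[j]]$schema) else NA_character_
    if (!is.na(hi) && !is.na(hj) && hi != hj)
      ecn_stop(sprintf("schema hash mismatch: model %s vs dataset %s",
                       ids[i], ids[j]), "compatibility_error")
  }
  M <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    pr <- predict_split(models[[i]], datasets[[j]], split = split)
    M[i, j] <- auroc(pr$scores, pr$labels)
  }
  structure(list(conditions = ids, matrix = M), class = "cross_test_matrix")
}

#' Cluster conditions from a cross-test matrix
#'
#' Transforms transfer AUROCs into a distance
#' `d(i,j) = 1 - (M[i,j] + M[j,i]) / 2` (clipped to \[0,1\], zero
#' diagonal) and applies average-linkage hierarchical clustering; flat
#' clusters are cut at `k`.
#'
#' @param xt a `cross_test_matrix` (or plain K x K matrix).
#' @param k number of flat clusters (default 2).
#' @return list(distance, linkage = hclust object, clusters = named
#'   integer vector).
#' @export
cluster_conditions <- function(xt, k = 2L) {
  M <- if (inherits(xt, "cross_test_matrix")) xt$matrix else xt
  if (nrow(M) < 2L) ecn_stop("need at least 2 conditions", "evaluation_error")
  D <- 1 - (M + t(M)) / 2
  D <- pmin(pmax(D, 0), 1)
  diag(D) <- 0
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  list(distance = D, linkage = hc,
       clusters = stats::cutree(hc, k = min(k, nrow(M))))
}
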