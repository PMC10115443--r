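#' Area under the ROC curve (rank estimator)
#'
#' Computes AUROC as the Mann-Whitney probability that a randomly chosen
#' positive sample outranks a randomly chosen negative one; tied scores
#' contribute 1/2. Equivalent to exhaustive pair counting.
#'
#' @param scores numeric vector of predicted scores (higher = more positive).
#' @param labels binary vector (0/1 or logical) of true classes.
#' @return AUROC in \[0, 1\].
#' @examples
#' compute_auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
#' @export
compute_auroc <- function(scores, labels) {
  labels <- check_binary_labels(labels, length(scores))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Precision-recall AUC by average precision
#'
#' Step-wise average precision: samples are swept in decreasing score order,
#' tied scores are processed as one block (every member of a tie block
#' receives the precision at the end of the block), and precision is averaged
#' over the positions of the true positives. The expected value for an
#' uninformative scorer equals the positive-class prevalence.
#'
#' @inheritParams compute_auroc
#' @return PR-AUC in \[0, 1\].
#' @export
compute_pr_auc <- function(scores, labels) {
  labels <- check_binary_labels(labels, length(scores))
  n_pos <- sum(labels == 1)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  blocks <- cumsum(!duplicated(s))
  tp_block <- tapply(y, blocks, sum)
  n_block <- tabulate(blocks)
  cum_tp <- cumsum(tp_block)
  cum_n <- cumsum(n_block)
  sum((cum_tp / cum_n) * tp_block) / n_pos
}

#' PR-AUC enrichment over prevalence
#'
#' Returns the full evaluation of a score vector: AUROC, PR-AUC, prevalence
#' pi = k/n, and the enrichment PR-AUC-E = PR-AUC - pi. PR-AUC-E is zero in
#' expectation for an unskilled model regardless of class balance, which makes
#' it comparable across models with different numbers of deficient samples.
#'
#' @inheritParams compute_auroc
#' @return A list of class `ddr_eval` with elements `auroc`, `pr_auc`,
#'   `prevalence`, `pr_auc_e`.
#' @examples
#' ev <- compute_pr_auc_e(c(0.9, 0.8, 0.7), c(1, 0, 1))
#' ev$pr_auc_e
#' @export
compute_pr_auc_e <- function(scores, labels) {
  labels <- check_binary_labels(labels, length(scores))
  pi_hat <- mean(labels == 1)
  pr <- compute_pr_auc(scores, labels)
  structure(
    list(
      auroc = compute_auroc(scores, labels),
      pr_auc = pr,
      prevalence = pi_hat,
      pr_auc_e = pr - pi_hat
    ),
    class = "ddr_eval"
  )
}

#' @export
print.ddr_eval <- function(x, ...) {
  cat(sprintf(
    "AUROC %.3f | PR-AUC %.3f | prevalence %.3f | PR-AUC-E %.3f\n",
    x$auroc, x$pr_auc, x$prevalence, x$pr_auc_e
  ))
  invisible(x)
}

check_binary_labels <- function(labels, n) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (length(labels) != n) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) {
    stop("labels must be binary (0/1)", call. = FALSE)
  }
  if (length(unique(labels)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  labels
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment across a family of p-values (the model
#' grid of one screen run).
#'
#' @param p numeric vector of p-values in (0, 1\].
#' @return q-values of the same length.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Shortlist models by effect size and significance
#'
#' A model is shortlisted when its out-of-fold PR-AUC-E exceeds
#' `pr_auc_e_min` and its FDR-adjusted q-value is below `q_max`.
#'
#' @param evaluations data frame with one row per model, containing at least
#'   `pr_auc_e` and `p` columns (`p` from the permutation test).
#' @param pr_auc_e_min effect-size gate (default 0.2).
#' @param q_max significance gate on the BH-adjusted p (default 0.05).
#' @return The input with added `q` and logical `shortlisted` columns.
#' @export
shortlist <- function(evaluations, pr_auc_e_min = 0.2, q_max = 0.05) {
  stopifnot(is.data.frame(evaluations),
            all(c("pr_auc_e", "p") %in% names(evaluations)))
  evaluations$q <- bh_fdr(evaluations$p)
  evaluations$shortlisted <-
    evaluations$pr_auc_e > pr_auc_e_min & evaluations$q < q_max
  evaluations
}
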