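#' Adaptive Monte Carlo permutation test for a deficiency model
#'
#' Shuffles the deficiency labels and reruns the full fitting procedure
#' (including cross-validated lambda selection and cap enforcement) on each
#' permuted label set, recording the permuted out-of-fold PR-AUC-E. The
#' observed statistic is computed by the same procedure, in the same mode,
#' so observed and null values are exchangeable under the null. After
#' `n_min` permutations, if fewer than `escalate_r` permuted statistics
#' reach the observed value, `n_step` further permutations are added,
#' repeating until `escalate_r` exceedances are seen or `n_max` permutations
#' have run. The p-value is `(r + 1) / n`.
#'
#' @param x feature matrix or `ddr_features` (see
#'   [fit_deficiency_model()]).
#' @param labels binary deficiency labels.
#' @param seed integer seed; permutation b uses a seed derived from it.
#' @param n_min,n_step,n_max adaptive schedule (10,000 / 10,000 / 30,000 in
#'   the screen's full configuration; reduce for tests).
#' @param escalate_r exceedance count below which the schedule escalates
#'   (default 5).
#' @param mode fitting mode for observed and permuted fits; `"fast"`
#'   (default) uses the reduced single-loop procedure, `"paper"` the full
#'   outer k-fold loop.
#' @param feature_cap optional cap override passed to the fitter.
#' @return List of class `ddr_perm`: `n`, `r`, `p`, `observed` (PR-AUC-E),
#'   `perm_stats`, `model` (the observed fit).
#' @export
permutation_test <- function(x, labels, seed = 1,
                             n_min = 10000, n_step = 10000, n_max = 30000,
                             escalate_r = 5, mode = c("fast", "paper"),
                             feature_cap = NULL) {
  mode <- match.arg(mode)
  if (n_min < 1) stop("n_min must be at least 1", call. = FALSE)
  if (inherits(x, "ddr_features")) x <- x$transformed
  x <- as.matrix(x)
  labels <- as.integer(labels)

  model <- fit_deficiency_model(x, labels, seed = derive_seed(seed, "obs"),
                                mode = mode, feature_cap = feature_cap)
  observed <- model$evaluation$pr_auc_e

  perm_stat <- function(b) {
    s <- derive_seed(seed, paste0("perm", b))
    y_perm <- with_seed(s, sample(labels))
    fit <- fit_deficiency_model(x, y_perm, seed = s, mode = mode,
                                feature_cap = feature_cap)
    fit$evaluation$pr_auc_e
  }

  stats_all <- numeric(0)
  n <- 0
  repeat {
    target <- if (n == 0) n_min else min(n + n_step, n_max)
    new_b <- seq.int(n + 1, target)
    stats_all <- c(stats_all,
                   suppressWarnings(vapply(new_b, perm_stat, numeric(1))))
    n <- target
    r <- sum(stats_all >= observed)
    if (r >= escalate_r || n >= n_max) break
  }
  structure(
    list(n = n, r = r, p = min(1, (r + 1) / n), observed = observed,
         perm_stats = stats_all, model = model),
    class = "ddr_perm"
  )
}

#' @export
print.ddr_perm <- function(x, ...) {
  cat(sprintf(
    "Permutation test: observed PR-AUC-E %.3f; r = %d of n = %d; p = %.3g\n",
    x$observed, x$r, x$n, x$p))
  invisible(x)
}

#' Evaluate a frozen model on the opposite data set
#'
#' Scores each sample of a held-out cohort with the fitted model (its frozen
#' coefficients and, when stored, its frozen feature transform), computes
#' the PR-AUC-E against the cohort's own deficiency labels, and assesses
#' significance by permuting the labels with the scores held fixed (the
#' model is not refitted): `p = (r + 1) / n_perm`.
#'
#' @param model a `ddr_model`.
#' @param newdata feature matrix for the opposite cohort; raw counts if the
#'   model stores a transform (`raw = TRUE`), transformed values otherwise.
#' @param labels deficiency labels of the opposite cohort.
#' @param n_perm number of label permutations (30,000 in the screen's full
#'   configuration).
#' @param seed integer seed.
#' @param raw passed to [predict.ddr_model()].
#' @return List: `pr_auc_e`, `evaluation` (full `ddr_eval`), `p`, `r`,
#'   `n_perm`, `scores`.
#' @export
cross_dataset_eval <- function(model, newdata, labels, n_perm = 1000,
                               seed = 1, raw = FALSE) {
  scores <- predict(model, newdata, raw = raw)
  labels <- as.integer(labels)
  ev <- compute_pr_auc_e(scores, labels)
  perm <- with_seed(derive_seed(seed, "xeval"), {
    vapply(seq_len(n_perm), function(b) {
      compute_pr_auc_e(scores, sample(labels))$pr_auc_e
    }, numeric(1))
  })
  r <- sum(perm >= ev$pr_auc_e)
  list(pr_auc_e = ev$pr_auc_e, evaluation = ev,
       p = min(1, (r + 1) / n_perm), r = r, n_perm = n_perm,
       scores = scores)
}
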