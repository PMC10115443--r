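#' Feature cap for a model with k deficient samples
#'
#' Models may select at most one feature per 10 mutated tumours, rounded up,
#' plus one: `ceiling(k / 10) + 1`. 12 mutated tumours give a cap of three
#' features.
#'
#' @param k number of positive (deficient) samples, >= 1.
#' @return Integer cap (>= 2).
#' @export
max_features <- function(k) {
  stopifnot(all(k >= 1))
  as.integer(ceiling(k / 10) + 1)
}

#' Class-balancing sample weights
#'
#' Each sample is weighted by one minus the proportion of samples sharing
#' its mutational status: positives get `1 - k/n`, background `k/n`, so the
#' two class weights sum to 1 and the rare class dominates the loss.
#'
#' @param labels binary vector (1 = deficient).
#' @return Numeric per-sample weight vector.
#' @export
compute_weights <- function(labels) {
  labels <- as.integer(labels)
  n <- length(labels)
  k <- sum(labels == 1)
  if (k == 0 || k == n) {
    stop("both classes must be present to compute weights", call. = FALSE)
  }
  ifelse(labels == 1, 1 - k / n, k / n)
}

#' Enumerate eligible model designs
#'
#' One candidate model per gene x cohort x data set x zygosity mode, gated on
#' class size: a biallelic model requires more than five biallelic tumours
#' (>= 6); a monoallelic model requires more than ten tumours carrying mono-
#' or biallelic events (>= 11, counting the biallelic tumours, which are
#' treated as a special case of monoallelic loss).
#'
#' @param calls zygosity calls (columns `sample`, `gene`, `status`),
#'   optionally with `cohort` and `dataset` columns.
#' @param seed base seed from which each design derives its own stream.
#' @return Data frame of designs: `gene`, `cohort`, `dataset`,
#'   `zygosity_mode`, `k`, `n`, `feature_cap`, `seed`.
#' @export
enumerate_eligible_models <- function(calls, seed = 1) {
  calls$cohort <- calls$cohort %||% "cohort"
  calls$dataset <- calls$dataset %||% "hmf"
  out <- list()
  for (grp in split(calls, list(calls$gene, calls$cohort, calls$dataset),
                    drop = TRUE)) {
    gene <- grp$gene[1]
    for (mode in c("biallelic", "monoallelic")) {
      strata <- stratify_cohort(grp, mode)
      k <- length(strata$positives)
      min_k <- if (mode == "biallelic") 6L else 11L
      if (k < min_k) next
      out[[length(out) + 1L]] <- data.frame(
        gene = gene, cohort = grp$cohort[1], dataset = grp$dataset[1],
        zygosity_mode = mode, k = k,
        n = k + length(strata$background),
        feature_cap = max_features(k),
        seed = derive_seed(seed, paste(gene, grp$cohort[1], grp$dataset[1],
                                       mode)),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(gene = character(0), cohort = character(0),
                      dataset = character(0), zygosity_mode = character(0),
                      k = integer(0), n = integer(0),
                      feature_cap = integer(0), seed = integer(0)))
  }
  do.call(rbind, out)
}

# Stratified fold assignment: permute within each class, deal folds
# round-robin so every fold sees both classes where possible.
stratified_foldid <- function(labels, nfolds) {
  foldid <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    foldid[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(nfolds), length(idx))
  }
  foldid
}

# Walk the regularisation path to the sparsest-enough solution: the smallest
# lambda >= lambda_sel whose active set fits within the cap. Returns the
# lambda to use; NA means not even the path start satisfies the cap.
cap_lambda <- function(glmnet_fit, lambda_sel, cap) {
  lam <- glmnet_fit$lambda
  df <- glmnet_fit$df
  ok <- lam >= lambda_sel - 1e-12 & df <= cap
  if (!any(ok)) return(NA_real_)
  min(lam[ok])
}

# One weighted LASSO fit with 5-fold CV lambda selection (largest lambda
# within one SE of the minimum weighted binomial deviance) and cap
# enforcement. Returns the cv.glmnet object plus the chosen lambda.
lasso_cv_fit <- function(x, y, weights, cap, inner_nfolds, nlambda,
                         lambda_min_ratio, keep = FALSE) {
  foldid <- stratified_foldid(y, inner_nfolds)
  cvfit <- glmnet::cv.glmnet(
    x, y, family = "binomial", alpha = 1, weights = weights,
    foldid = foldid, type.measure = "deviance",
    nlambda = nlambda, lambda.min.ratio = lambda_min_ratio,
    standardize = TRUE, keep = keep
  )
  lambda <- cap_lambda(cvfit$glmnet.fit, cvfit$lambda.1se, cap)
  if (is.na(lambda)) {
    warning("no lambda satisfies the feature cap; using intercept-only model",
            call. = FALSE)
    lambda <- max(cvfit$glmnet.fit$lambda)
  }
  list(cvfit = cvfit, lambda = lambda)
}

#' Fit a weighted LASSO-logistic deficiency model
#'
#' The core fitter of the screen. Labels are gene-deficiency indicators;
#' features are the transformed mutational summary statistics. The model is
#' an L1-penalised (alpha = 1) logistic regression with class-balancing
#' weights ([compute_weights()]). Lambda is chosen per fit by 5-fold
#' cross-validation as the largest value whose mean weighted binomial
#' deviance lies within one standard error of the minimum; if the active set
#' still exceeds the feature cap (`ceiling(k/10) + 1`), lambda is increased
#' along the path to the smallest value that satisfies the cap.
#'
#' Out-of-fold scores come from an outer loop with one fold per positive
#' sample (k folds): each fold holds out exactly one positive plus a
#' round-robin share of the background, the full procedure is rerun on the
#' remainder, and the held-out samples are scored. Every sample is scored
#' exactly once by a model that never saw it. In `mode = "fast"` the outer
#' loop is replaced by a single 5-fold cross-validated fit whose
#' prevalidated scores serve as the out-of-fold scores, over a shortened
#' lambda path; this mode exists for permutation replicates and tests and is
#' not the full procedure.
#'
#' @param x feature matrix (samples x features), or a `ddr_features` object
#'   (its `transformed` matrix is used and the transform is stored for later
#'   application to held-out cohorts).
#' @param labels binary deficiency labels (1 = deficient), in row order of
#'   `x`.
#' @param seed integer seed controlling fold assignment.
#' @param mode `"paper"` (outer k-fold loop, 100-value lambda path) or
#'   `"fast"`.
#' @param feature_cap override for the feature cap; default
#'   `max_features(k)`.
#' @param design optional metadata row (as from
#'   [enumerate_eligible_models()]) carried into the result.
#' @return Object of class `ddr_model`: selected `features` (named nonzero
#'   coefficients), `intercept`, `lambda`, `oof_scores`, `evaluation`
#'   (a `ddr_eval`), `design`, `mode`, and the frozen feature `transform`
#'   (if `x` was a `ddr_features`).
#' @export
fit_deficiency_model <- function(x, labels, seed = 1,
                                 mode = c("paper", "fast"),
                                 feature_cap = NULL, design = NULL) {
  mode <- match.arg(mode)
  transform <- NULL
  if (inherits(x, "ddr_features")) {
    transform <- list(center = x$center, scale = x$scale,
                      features = colnames(x$raw))
    x <- x$transformed
  }
  x <- as.matrix(x)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  n <- length(labels)
  k <- sum(labels == 1)
  cap <- feature_cap %||% max_features(k)
  weights <- compute_weights(labels)
  pars <- if (mode == "paper") {
    list(nlambda = 100, ratio = 1e-4, inner = 5)
  } else {
    list(nlambda = 30, ratio = 1e-3, inner = 5)
  }

  with_seed(seed, {
    oof <- rep(NA_real_, n)
    if (mode == "paper") {
      pos <- which(labels == 1)
      bg <- which(labels == 0)
      fold_of <- integer(n)
      fold_of[pos[sample.int(k)]] <- seq_len(k)
      fold_of[bg[sample.int(length(bg))]] <- rep_len(seq_len(k), length(bg))
      for (f in seq_len(k)) {
        test <- fold_of == f
        fit <- lasso_cv_fit(x[!test, , drop = FALSE], labels[!test],
                            weights[!test], cap, pars$inner, pars$nlambda,
                            pars$ratio)
        oof[test] <- as.numeric(stats::predict(
          fit$cvfit$glmnet.fit, newx = x[test, , drop = FALSE],
          s = fit$lambda, type = "response"))
      }
      final <- lasso_cv_fit(x, labels, weights, cap, pars$inner,
                            pars$nlambda, pars$ratio)
    } else {
      final <- lasso_cv_fit(x, labels, weights, cap, pars$inner,
                            pars$nlambda, pars$ratio, keep = TRUE)
      idx <- which.min(abs(final$cvfit$lambda - final$lambda))
      # prevalidated fits are on the link scale; map to probabilities
      oof <- stats::plogis(final$cvfit$fit.preval[, idx])
    }
    cf <- stats::coef(final$cvfit$glmnet.fit, s = final$lambda)
    cfv <- stats::setNames(as.numeric(cf), rownames(cf))
    nz <- cfv[-1][cfv[-1] != 0]
    if (!is.null(rownames(x))) names(oof) <- rownames(x)
    structure(
      list(features = nz, intercept = cfv[1], lambda = final$lambda,
           oof_scores = oof, evaluation = compute_pr_auc_e(oof, labels),
           labels = labels, design = design, mode = mode, seed = seed,
           feature_cap = cap, transform = transform),
      class = "ddr_model"
    )
  })
}

#' @export
print.ddr_model <- function(x, ...) {
  d <- x$design
  hdr <- if (!is.null(d)) {
    sprintf("%s %s model (%s, %s)", d$gene, d$zygosity_mode, d$cohort,
            d$dataset)
  } else {
    "Deficiency model"
  }
  cat(hdr, "\n")
  cat(sprintf("  k = %d positives of n = %d; feature cap %d; lambda %.4g\n",
              sum(x$labels == 1), length(x$labels), x$feature_cap, x$lambda))
  if (length(x$features)) {
    cat("  selected features:\n")
    for (f in names(x$features)) {
      cat(sprintf("    %-24s %+.3f\n", f, x$features[[f]]))
    }
  } else {
    cat("  intercept-only model (no features selected)\n")
  }
  print(x$evaluation)
  invisible(x)
}

#' @export
coef.ddr_model <- function(object, ...) {
  c("(Intercept)" = unname(object$intercept), object$features)
}

#' @export
summary.ddr_model <- function(object, ...) {
  out <- list(
    n = length(object$labels), k = sum(object$labels == 1),
    feature_cap = object$feature_cap, n_selected = length(object$features),
    coefficients = coef(object), evaluation = object$evaluation,
    mode = object$mode
  )
  class(out) <- "summary.ddr_model"
  out
}

#' @export
print.summary.ddr_model <- function(x, ...) {
  cat(sprintf(
    "Weighted LASSO-logistic deficiency model (%s mode)\n", x$mode))
  cat(sprintf("  n = %d, k = %d, %d/%d features selected\n",
              x$n, x$k, x$n_selected, x$feature_cap))
  print(round(x$coefficients, 4))
  print(x$evaluation)
  invisible(x)
}

#' Predict deficiency probabilities for new samples
#'
#' @param object a `ddr_model`.
#' @param newdata transformed feature matrix, or raw counts if the model
#'   stores a frozen transform (then `raw = TRUE`).
#' @param type `"response"` (probability) or `"link"`.
#' @param raw whether `newdata` holds raw counts to be passed through the
#'   model's stored transform.
#' @param ... unused.
#' @return Numeric vector of scores.
#' @export
predict.ddr_model <- function(object, newdata, type = c("response", "link"),
                              raw = FALSE, ...) {
  type <- match.arg(type)
  if (raw) {
    if (is.null(object$transform)) {
      stop("model stores no feature transform; supply transformed data",
           call. = FALSE)
    }
    tr <- object$transform
    fm <- structure(list(raw = matrix(nrow = 0, ncol = length(tr$features),
                                      dimnames = list(NULL, tr$features)),
                         center = tr$center, scale = tr$scale),
                    class = "ddr_features")
    newdata <- apply_feature_transform(fm, newdata)
  }
  newdata <- as.matrix(newdata)
  feats <- names(object$features)
  missing <- setdiff(feats, colnames(newdata))
  if (length(missing)) {
    stop("missing features in new data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  eta <- object$intercept +
    as.numeric(newdata[, feats, drop = FALSE] %*% object$features)
  if (type == "response") stats::plogis(eta) else eta
}
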