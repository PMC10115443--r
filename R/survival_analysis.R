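#' Build overall-survival records from a clinical table
#'
#' Applies the data-set-specific overall-survival rules. HMF dialect
#' (columns `biopsy_date`, `death_date`, `treatment_end_date`, `deceased`):
#' deceased patients contribute biopsy-to-death time with an observed event;
#' the rest contribute biopsy-to-treatment-end time, censored. PCAWG dialect
#' (columns `donor_survival_time`, `donor_vital_status`,
#' `donor_interval_of_last_followup`): the registered survival time is used
#' (event when vital status is `"deceased"`); records without a survival
#' time fall back to the last-followup interval, censored. Samples with
#' non-positive or missing times are dropped with a warning.
#'
#' @param clinical clinical data frame in one of the two dialects, with a
#'   `sample` column.
#' @param dataset `"hmf"` or `"pcawg"`.
#' @param lof_samples character vector of samples carrying the gene
#'   deficiency; all others are labelled `WT`.
#' @return Data frame: `sample`, `time` (days), `event` (1 = death), `group`
#'   (`"LOF"`/`"WT"`).
#' @export
build_survival_records <- function(clinical, dataset = c("hmf", "pcawg"),
                                   lof_samples = character(0)) {
  dataset <- match.arg(dataset)
  if (dataset == "hmf") {
    parse_date <- function(x) {
      x <- as.character(x)
      x[is.na(x) | !nzchar(trimws(x))] <- NA
      d <- as.Date(x, format = "%Y-%m-%d")
      bad <- which(!is.na(x) & is.na(d))
      if (length(bad)) {
        stop("unparseable date(s) for sample(s): ",
             paste(clinical$sample[bad], collapse = ", "), call. = FALSE)
      }
      d
    }
    biopsy <- parse_date(clinical$biopsy_date)
    death <- parse_date(clinical$death_date)
    trt_end <- parse_date(clinical$treatment_end_date)
    deceased <- as.integer(clinical$deceased) == 1
    time <- ifelse(deceased, as.numeric(death - biopsy),
                   as.numeric(trt_end - biopsy))
    event <- as.integer(deceased)
  } else {
    time <- suppressWarnings(as.numeric(clinical$donor_survival_time))
    event <- as.integer(tolower(as.character(
      clinical$donor_vital_status)) == "deceased")
    fallback <- is.na(time)
    time[fallback] <- suppressWarnings(as.numeric(
      clinical$donor_interval_of_last_followup[fallback]))
    event[fallback] <- 0L
  }
  out <- data.frame(
    sample = clinical$sample, time = time, event = event,
    group = ifelse(clinical$sample %in% lof_samples, "LOF", "WT"),
    stringsAsFactors = FALSE
  )
  drop <- is.na(out$time) | out$time <= 0 | is.na(out$event)
  if (any(drop)) {
    warning(sum(drop), " sample(s) dropped for missing or non-positive ",
            "survival time", call. = FALSE)
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Univariate Cox proportional-hazards model of deficiency status
#'
#' Fits overall survival on the binary LOF-vs-WT group by Cox partial
#' likelihood with Efron tie handling, and reports the hazard ratio of the
#' deficient group with a two-sided Wald p-value.
#'
#' @param records data frame from [build_survival_records()] (columns
#'   `time`, `event`, `group`).
#' @return List of class `ddr_surv`: `hazard_ratio` (LOF vs WT), `p`,
#'   `ci_lower`, `ci_upper`, `n_lof`, `n_wt`, `n_events`, `fit` (the
#'   underlying [survival::coxph] fit).
#' @export
cox_univariate <- function(records) {
  if (!all(c("LOF", "WT") %in% records$group)) {
    stop("both groups (LOF and WT) must be non-empty", call. = FALSE)
  }
  if (sum(records$event) < 1) {
    stop("at least one death event is required", call. = FALSE)
  }
  records$group <- factor(records$group, levels = c("WT", "LOF"))
  fit <- survival::coxph(
    survival::Surv(time, event) ~ group, data = records, ties = "efron")
  if (any(abs(stats::coef(fit)) > 15)) {
    warning("monotone likelihood: hazard ratio is effectively unbounded",
            call. = FALSE)
  }
  sm <- summary(fit)
  structure(
    list(hazard_ratio = unname(sm$coefficients[1, "exp(coef)"]),
         p = unname(sm$coefficients[1, "Pr(>|z|)"]),
         ci_lower = unname(sm$conf.int[1, "lower .95"]),
         ci_upper = unname(sm$conf.int[1, "upper .95"]),
         n_lof = sum(records$group == "LOF"),
         n_wt = sum(records$group == "WT"),
         n_events = sum(records$event), fit = fit),
    class = "ddr_surv"
  )
}

#' @export
print.ddr_surv <- function(x, ...) {
  cat(sprintf(
    "Cox PH (Efron ties): HR[LOF vs WT] = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
    x$hazard_ratio, x$ci_lower, x$ci_upper, x$p))
  cat(sprintf("  n = %d LOF / %d WT, %d events\n",
              x$n_lof, x$n_wt, x$n_events))
  invisible(x)
}
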