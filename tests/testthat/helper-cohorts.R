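# Shared fixtures: small cohorts and a compact feature catalogue used by the
# slower simulation-based tests.

small_catalogue <- function() {
  default_baseline_means()[c("SBS1", "SBS2", "SBS3", "SBS5", "SBS8",
                             "SBS13", "SBS17", "SBS18",
                             "ins", "del.mh", "del.rep", "del.other")]
}

small_cohort <- function(seed, n = 80, k = 6, null = TRUE, ...) {
  cfg <- cohort_config(n_samples = n, n_biallelic = k,
                       baseline_means = small_catalogue(),
                       decoys = FALSE, seed = seed, ...)
  if (null) generate_null_cohort(cfg) else generate_cohort(cfg)
}

# Deficiency labels and transformed features for the planted gene, keeping
# only biallelic positives and wild-type background.
cohort_xy <- function(cohort) {
  st <- cohort$truth$status$status
  keep <- which(st %in% c("biallelic", "wild_type"))
  fx <- cohort$features
  rownames(fx) <- fx$sample
  fm <- build_feature_matrix(fx[keep, ])
  list(fm = fm, y = as.integer(st[keep] == "biallelic"),
       samples = cohort$features$sample[keep])
}

# Truth statuses in the annotation module's vocabulary.
truth_status <- function(cohort) {
  st <- cohort$truth$status
  st$status[st$status == "vus"] <- "vus_carrier"
  st
}
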