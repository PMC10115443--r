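mk_variant <- function(origin = "germline", vaf = NA, cadd = 30,
                       gnomad = NA, recurrence = 1, filter = "PASS",
                       callers = 3, consequence = "non_synonymous",
                       clinvar = NA, sample = "S1", gene = "G1") {
  data.frame(sample = sample, gene = gene, chrom = "ctg1", pos = 100,
             ref = "A", alt = "T", origin = origin, vaf = vaf,
             cadd_phred = cadd, gnomad_af = gnomad, clinvar = clinvar,
             consequence = consequence, recurrence = recurrence,
             caller_support = callers, filter = filter,
             stringsAsFactors = FALSE)
}

test_that("variant filters enforce the curation thresholds strictly", {
  cfg <- annotation_config()
  kept <- function(v, dataset = "hmf") {
    nrow(apply_variant_filters(v, cfg, dataset))
  }
  expect_equal(kept(mk_variant("somatic", vaf = 0.15)), 0)
  expect_equal(kept(mk_variant("somatic", vaf = 0.2)), 1)
  expect_equal(kept(mk_variant(recurrence = 201)), 0)
  expect_equal(kept(mk_variant(recurrence = 200)), 1)
  expect_equal(kept(mk_variant(gnomad = 0.006)), 0)
  expect_equal(kept(mk_variant(gnomad = 0.005)), 1)
  expect_equal(kept(mk_variant(gnomad = NA)), 1)
  expect_equal(kept(mk_variant(filter = "LOWQUAL")), 0)
  expect_equal(kept(mk_variant(callers = 1), dataset = "pcawg"), 0)
  expect_equal(kept(mk_variant(callers = 2), dataset = "pcawg"), 1)
  expect_equal(kept(mk_variant(callers = 1), dataset = "hmf"), 1)
})

test_that("filtering is idempotent and order stable", {
  set.seed(1)
  v <- do.call(rbind, lapply(1:40, function(i) {
    mk_variant(origin = sample(c("germline", "somatic"), 1),
               vaf = runif(1), cadd = runif(1, 0, 50),
               gnomad = sample(c(NA, runif(1, 0, 0.02)), 1),
               recurrence = sample(c(1, 250), 1, prob = c(0.8, 0.2)),
               sample = paste0("S", i))
  }))
  once <- apply_variant_filters(v, annotation_config(), "hmf")
  twice <- apply_variant_filters(once, annotation_config(), "hmf")
  expect_identical(once, twice)
  expect_true(!is.unsorted(match(once$sample, v$sample)))
})

test_that("missing recurrence raises an error naming the variant", {
  v <- mk_variant(recurrence = NA)
  expect_error(apply_variant_filters(v, annotation_config(), "hmf"),
               "ctg1:100")
})

test_that("pathogenicity classes follow the CADD bands with ClinVar override", {
  expect_equal(classify_pathogenicity(30, "non_synonymous"), "pathogenic")
  expect_equal(classify_pathogenicity(25, "synonymous"), "pathogenic")
  expect_equal(classify_pathogenicity(18, "non_synonymous"), "vus")
  expect_equal(classify_pathogenicity(18, "synonymous"), "benign")
  expect_equal(classify_pathogenicity(10, "non_synonymous"), "benign")
  expect_equal(classify_pathogenicity(8, "non_synonymous"), "benign")
  expect_equal(classify_pathogenicity(18, "non_synonymous", "pathogenic"),
               "pathogenic")
  expect_equal(classify_pathogenicity(30, "non_synonymous", "benign"),
               "benign")
  expect_equal(classify_pathogenicity(18, "non_synonymous", "conflicting"),
               "vus")
})

test_that("raising the pathogenic threshold never adds pathogenic calls", {
  set.seed(2)
  cadd <- runif(200, 0, 50)
  csq <- sample(c("non_synonymous", "synonymous"), 200, replace = TRUE)
  n_path <- vapply(c(15, 20, 25, 30, 35), function(thr) {
    cfg <- annotation_config(cadd_pathogenic_min = thr)
    sum(classify_pathogenicity(cadd, csq, config = cfg) == "pathogenic")
  }, numeric(1))
  expect_true(all(diff(n_path) <= 0))
})

test_that("copy-number events use strict thresholds and any-overlap rule", {
  genes <- data.frame(gene = "G1", chrom = "ctg1", start = 1000, end = 2000)
  seg <- function(minor, major, start = 1500, end = 1600) {
    data.frame(sample = "S1", chrom = "ctg1", start = start, end = end,
               major_cn = major, minor_cn = minor)
  }
  ev <- call_copy_number_events(seg(0.1, 1.5), genes)
  expect_true(ev$loh); expect_false(ev$deep_deletion)
  ev <- call_copy_number_events(seg(0.2, 1.5), genes)
  expect_false(ev$loh)
  ev <- call_copy_number_events(seg(0.1, 0.15), genes)
  expect_true(ev$deep_deletion); expect_true(ev$loh)
  # 1-bp overlap at the gene edge counts
  ev <- call_copy_number_events(seg(0.1, 1.5, start = 2000, end = 3000),
                                genes)
  expect_true(ev$loh)
  ev <- call_copy_number_events(seg(0.1, 1.5, start = 2001, end = 3000),
                                genes)
  expect_false(ev$loh)
  expect_error(
    call_copy_number_events(seg(0.5, 0.4), genes), "malformed")
})

test_that("zygosity assignment covers all evidence combinations", {
  pv <- function(n, origin = "germline") {
    out <- data.frame(id = character(n), origin = character(n),
                      stringsAsFactors = FALSE)
    if (n > 0) {
      out$id <- paste0("v", seq_len(n))
      out$origin <- origin
    }
    out
  }
  none <- pv(0)
  call <- function(...) classify_gene_zygosity("S1", "G1", ...)$status
  expect_equal(call(pv(1), none, loh = TRUE), "biallelic")
  expect_equal(call(pv(2), none, loh = FALSE), "biallelic")
  expect_equal(call(none, none, loh = FALSE, deep_deletion = TRUE),
               "biallelic")
  expect_equal(call(pv(1), none, loh = FALSE), "monoallelic")
  expect_equal(call(none, pv(1), loh = FALSE), "vus_carrier")
  expect_equal(call(none, none, loh = TRUE), "wild_type")
  expect_equal(call(none, none, loh = FALSE), "wild_type")
})

test_that("annotation recovers the planted truth exactly, including from disk", {
  co <- generate_cohort(cohort_config(n_samples = 80, n_biallelic = 8,
                                      n_monoallelic = 4, n_vus = 6,
                                      seed = 77))
  calls <- annotate_zygosity(co$variants, co$segments, co$genes,
                             co$features$sample)
  b <- calls[calls$gene == "BRCA2", ]
  truth <- truth_status(co)
  expect_equal(b$status[match(truth$sample, b$sample)], truth$status)

  dir <- file.path(tempdir(), "rt_cohort")
  write_cohort(co, dir)
  rc <- read_cohort(dir)
  calls2 <- annotate_zygosity(rc$variants, rc$segments, rc$genes, rc$samples)
  b2 <- calls2[calls2$gene == "BRCA2", ]
  expect_equal(b2$status[match(truth$sample, b2$sample)], truth$status)
  unlink(dir, recursive = TRUE)
})

test_that("stratification partitions the cohort disjointly and exhaustively", {
  calls <- data.frame(
    sample = paste0("S", 1:10),
    status = c("biallelic", "biallelic", "monoallelic", "vus_carrier",
               rep("wild_type", 6)), stringsAsFactors = FALSE)
  bi <- stratify_cohort(calls, "biallelic")
  expect_equal(sort(bi$positives), c("S1", "S2"))
  expect_equal(sort(bi$excluded), c("S3", "S4"))
  expect_length(bi$background, 6)
  mono <- stratify_cohort(calls, "monoallelic")
  expect_equal(sort(mono$positives), c("S1", "S2", "S3"))
  expect_equal(mono$excluded, "S4")
  all_samples <- sort(c(mono$positives, mono$background, mono$excluded))
  expect_equal(all_samples, sort(calls$sample))
  expect_error(stratify_cohort(rbind(calls, calls[1, ]), "biallelic"),
               "duplicate")
  no_vus <- calls[calls$status != "vus_carrier", ]
  expect_length(stratify_cohort(no_vus, "monoallelic")$excluded, 0)
})
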