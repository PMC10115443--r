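#' Default gene coordinate table for synthetic cohorts
#'
#' A small set of DDR-like gene intervals laid out over three synthetic
#' contigs totalling ~1 Mb. Coordinates are scaled down from genome scale so
#' that the bundled reference stays desk sized while the interval arithmetic
#' (gene-segment overlap, variant placement) is exercised for real.
#'
#' @param n_genes number of genes (2..12).
#' @return Data frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
default_gene_table <- function(n_genes = 8) {
  stopifnot(n_genes >= 2, n_genes <= 12)
  genes <- c("BRCA2", "BRCA1", "TP53", "CDK12", "ATM", "PALB2", "CHEK2",
             "MLH1", "MSH2", "RAD51C", "BARD1", "FANCA")[seq_len(n_genes)]
  chroms <- rep(c("ctg1", "ctg2", "ctg3"), length.out = n_genes)
  starts <- integer(n_genes)
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    starts[idx] <- seq(10000, 250000, length.out = length(idx))
  }
  data.frame(
    gene = genes, chrom = chroms,
    start = as.integer(starts),
    end = as.integer(starts + 20000L),
    stringsAsFactors = FALSE
  )
}

#' Default feature catalogue and baseline means
#'
#' Per-sample mutational features: eight SBS signature exposures, the four
#' indel categories, and the 32 SV categories. Baselines approximate counts
#' typical of a whole-genome breast-cancer cohort; in particular the
#' wild-type microhomology-deletion baseline is 81 per genome.
#'
#' @return Named numeric vector of baseline means.
#' @export
default_baseline_means <- function() {
  sig <- c(SBS1 = 300, SBS2 = 80, SBS3 = 150, SBS5 = 400, SBS8 = 60,
           SBS13 = 70, SBS17 = 40, SBS18 = 50)
  indel <- c(ins = 100, del.mh = 81, del.rep = 150, del.other = 120)
  sv <- stats::setNames(rep(c(2, 6), each = 16), sv_categories())
  c(sig, indel, sv)
}

#' Configure a synthetic cohort
#'
#' Describes a cohort of tumours with a planted gene deficiency: how many
#' samples carry biallelic, monoallelic, or VUS-only events in the planted
#' gene, which mutational features shift (multiplicatively) in the biallelic
#' samples, and the negative-binomial noise model for the feature counts.
#'
#' @param n_samples cohort size.
#' @param planted_gene gene receiving the planted events (must be in
#'   `genes`).
#' @param n_biallelic,n_monoallelic,n_vus planted status counts; their sum
#'   must not exceed `n_samples`.
#' @param effect_features named numeric vector of multiplicative effects
#'   (>= 0) applied to the feature means of biallelic samples, e.g.
#'   `c(del.mh = 6)`.
#' @param baseline_means named non-negative per-feature baseline means.
#' @param dispersion negative-binomial size parameter (> 0); smaller is more
#'   overdispersed.
#' @param germline_fraction expected fraction of planted pathogenic variant
#'   hits that are germline.
#' @param genes gene coordinate table (see [default_gene_table()]).
#' @param hazard_ratio hazard ratio of biallelic-deficient vs wild-type
#'   samples for the exponential survival times.
#' @param decoys add filter-fodder variants (low-VAF somatic, common
#'   germline, hyper-recurrent, non-PASS) that curation must remove.
#' @param seed integer seed; the entire bundle is a deterministic function of
#'   the config including this seed.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_samples,
                          planted_gene = "BRCA2",
                          n_biallelic = 0,
                          n_monoallelic = 0,
                          n_vus = 0,
                          effect_features = c(del.mh = 6),
                          baseline_means = default_baseline_means(),
                          dispersion = 2,
                          germline_fraction = 0.7,
                          genes = default_gene_table(),
                          hazard_ratio = 1,
                          decoys = TRUE,
                          seed = 1) {
  if (n_samples < 1) stop_field("n_samples", "must be positive")
  if (any(c(n_biallelic, n_monoallelic, n_vus) < 0)) {
    stop_field("n_biallelic/n_monoallelic/n_vus", "must be non-negative")
  }
  if (n_biallelic + n_monoallelic + n_vus > n_samples) {
    stop_field("n_biallelic",
               "n_biallelic + n_monoallelic + n_vus exceeds n_samples")
  }
  if (!planted_gene %in% genes$gene) {
    stop_field("planted_gene", "not present in the gene table")
  }
  if (length(effect_features) &&
      !all(names(effect_features) %in% names(baseline_means))) {
    stop_field("effect_features",
               "names must exist in the feature catalogue")
  }
  if (any(effect_features < 0)) {
    stop_field("effect_features", "multipliers must be >= 0")
  }
  if (any(baseline_means < 0)) {
    stop_field("baseline_means", "must be non-negative")
  }
  if (dispersion <= 0) stop_field("dispersion", "must be > 0")
  if (germline_fraction < 0 || germline_fraction > 1) {
    stop_field("germline_fraction", "must lie in [0, 1]")
  }
  structure(
    list(n_samples = as.integer(n_samples), planted_gene = planted_gene,
         n_biallelic = as.integer(n_biallelic),
         n_monoallelic = as.integer(n_monoallelic),
         n_vus = as.integer(n_vus),
         effect_features = effect_features,
         baseline_means = baseline_means, dispersion = dispersion,
         germline_fraction = germline_fraction, genes = genes,
         hazard_ratio = hazard_ratio, decoys = decoys,
         seed = as.integer(seed),
         exact_origins = NULL),
    class = "cohort_config"
  )
}

random_contigs <- function(lengths) {
  seqs <- vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(stats::setNames(seqs, names(lengths)))
}

# Draw origins (germline/somatic) for n planted hits; exact counts when the
# config pins them (the worked-example fixture), binomial otherwise.
draw_origins <- function(n, frac, exact = NULL) {
  if (n == 0) return(character(0))
  if (!is.null(exact)) {
    stopifnot(sum(exact) == n)
    origins <- rep(c("germline", "somatic"), times = exact)
  } else {
    origins <- ifelse(stats::runif(n) < frac, "germline", "somatic")
  }
  sample(origins)
}

new_variant_row <- function(sample, gene, chrom, pos, ref, alt, origin,
                            cadd, consequence, vaf = NA_real_,
                            gnomad = NA_real_, clinvar = NA_character_,
                            recurrence = 1L, callers = 3L, filter = "PASS") {
  data.frame(sample = sample, gene = gene, chrom = chrom, pos = pos,
             ref = ref, alt = alt, origin = origin, vaf = vaf,
             cadd_phred = cadd, gnomad_af = gnomad, clinvar = clinvar,
             consequence = consequence, recurrence = recurrence,
             caller_support = callers, filter = filter,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort with planted deficiencies
#'
#' Emits a full cohort bundle: a synthetic reference, germline and somatic
#' gene variants (with CADD-like pathogenicity scores, population
#' frequencies, VAFs and recurrence annotations), allele-specific copy-number
#' segments carrying the planted LOH/deep-deletion events, an illustrative
#' structural-variant breakpoint table, negative-binomial per-sample feature
#' counts whose means shift multiplicatively in the biallelic samples, an
#' exponential survival table, and the ground truth. Planted biallelic
#' samples carry one of: a pathogenic variant plus overlapping LOH, two
#' pathogenic variants, or a deep deletion. Planted pathogenic variants score
#' in \[25, 50\], VUS in (10, 25), benign in \[0, 10).
#'
#' @param config a [cohort_config()].
#' @return List of class `ddr_cohort` with elements `config`, `reference`,
#'   `genes`, `variants`, `segments`, `svs`, `features` (data frame,
#'   `sample` + one column per feature), `survival`, `truth` (list:
#'   `status` data frame, `means` matrix, `variant_ids`, `segment_ids`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  genes <- config$genes

  contig_names <- unique(genes$chrom)
  contig_len <- stats::setNames(
    vapply(contig_names, function(ch) {
      max(genes$end[genes$chrom == ch]) + 50000L
    }, integer(1)), contig_names)
  reference <- random_contigs(contig_len)

  # --- planted statuses -------------------------------------------------
  status <- rep("wild_type", n)
  planted_idx <- sample(n, config$n_biallelic + config$n_monoallelic +
                          config$n_vus)
  bi_idx <- planted_idx[seq_len(config$n_biallelic)]
  mono_idx <- planted_idx[config$n_biallelic + seq_len(config$n_monoallelic)]
  vus_idx <- planted_idx[config$n_biallelic + config$n_monoallelic +
                           seq_len(config$n_vus)]
  status[bi_idx] <- "biallelic"
  status[mono_idx] <- "monoallelic"
  status[vus_idx] <- "vus"

  g <- genes[genes$gene == config$planted_gene, ]
  gene_positions <- sample(seq(g$start, g$end))  # unique draw pool
  pos_cursor <- 0L
  next_pos <- function(k = 1L) {
    out <- gene_positions[pos_cursor + seq_len(k)]
    pos_cursor <<- pos_cursor + k
    out
  }
  base_at <- function(chrom, pos) {
    vapply(pos, function(p) {
      as.character(Biostrings::subseq(reference[[chrom]], p, p))
    }, character(1))
  }
  alt_base <- function(ref) {
    vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
           character(1))
  }

  variants <- list()
  segments <- list()
  seg_ids <- character(0)

  # biallelic mechanisms: variant+LOH / two variants / deep deletion
  mech <- if (length(bi_idx)) {
    if (!is.null(config$exact_origins)) {
      rep("var_loh", length(bi_idx))
    } else {
      sample(c("var_loh", "two_var", "deep_del"), length(bi_idx),
             replace = TRUE, prob = c(0.6, 0.25, 0.15))
    }
  } else {
    character(0)
  }
  n_hits_bi <- sum(mech == "var_loh") + 2L * sum(mech == "two_var")
  bi_origins <- draw_origins(n_hits_bi, config$germline_fraction,
                             config$exact_origins$biallelic)
  hit_cursor <- 0L
  for (j in seq_along(bi_idx)) {
    s <- samples[bi_idx[j]]
    if (mech[j] == "deep_del") {
      segments[[length(segments) + 1L]] <- data.frame(
        sample = s, chrom = g$chrom,
        start = max(1L, g$start - 2000L), end = g$end + 2000L,
        major_cn = stats::runif(1, 0.05, 0.14),
        minor_cn = stats::runif(1, 0, 0.05), stringsAsFactors = FALSE)
      seg_ids <- c(seg_ids, paste0(s, ":deep_del"))
      next
    }
    n_var <- if (mech[j] == "two_var") 2L else 1L
    for (v in seq_len(n_var)) {
      hit_cursor <- hit_cursor + 1L
      origin <- bi_origins[hit_cursor]
      pos <- next_pos()
      ref <- base_at(g$chrom, pos)
      variants[[length(variants) + 1L]] <- new_variant_row(
        s, g$gene, g$chrom, pos, ref, alt_base(ref), origin,
        cadd = stats::runif(1, 25, 50), consequence = "non_synonymous",
        vaf = if (origin == "somatic") stats::runif(1, 0.3, 0.9) else NA,
        gnomad = if (origin == "germline") stats::runif(1, 0, 0.004) else NA)
    }
    if (mech[j] == "var_loh") {
      segments[[length(segments) + 1L]] <- data.frame(
        sample = s, chrom = g$chrom,
        start = max(1L, g$start - 5000L), end = g$end + 5000L,
        major_cn = stats::runif(1, 0.9, 2.2),
        minor_cn = stats::runif(1, 0, 0.19), stringsAsFactors = FALSE)
      seg_ids <- c(seg_ids, paste0(s, ":loh"))
    }
  }

  mono_origins <- draw_origins(length(mono_idx), config$germline_fraction,
                               config$exact_origins$monoallelic)
  for (j in seq_along(mono_idx)) {
    s <- samples[mono_idx[j]]
    origin <- mono_origins[j]
    pos <- next_pos()
    ref <- base_at(g$chrom, pos)
    variants[[length(variants) + 1L]] <- new_variant_row(
      s, g$gene, g$chrom, pos, ref, alt_base(ref), origin,
      cadd = stats::runif(1, 25, 50), consequence = "non_synonymous",
      vaf = if (origin == "somatic") stats::runif(1, 0.3, 0.9) else NA,
      gnomad = if (origin == "germline") stats::runif(1, 0, 0.004) else NA)
  }

  vus_origins <- draw_origins(length(vus_idx), config$germline_fraction,
                              config$exact_origins$vus)
  for (j in seq_along(vus_idx)) {
    s <- samples[vus_idx[j]]
    origin <- vus_origins[j]
    pos <- next_pos()
    ref <- base_at(g$chrom, pos)
    variants[[length(variants) + 1L]] <- new_variant_row(
      s, g$gene, g$chrom, pos, ref, alt_base(ref), origin,
      cadd = stats::runif(1, 10.5, 24.5), consequence = "non_synonymous",
      vaf = if (origin == "somatic") stats::runif(1, 0.3, 0.9) else NA,
      gnomad = if (origin == "germline") stats::runif(1, 0, 0.004) else NA)
  }

  # benign passenger variants scattered over all genes / samples
  n_benign <- max(5L, round(n / 4))
  benign_samples <- sample(samples, n_benign, replace = TRUE)
  for (j in seq_len(n_benign)) {
    gi <- genes[sample(nrow(genes), 1), ]
    pos <- sample(seq(gi$start, gi$end), 1)
    ref <- base_at(gi$chrom, pos)
    origin <- sample(c("germline", "somatic"), 1)
    variants[[length(variants) + 1L]] <- new_variant_row(
      benign_samples[j], gi$gene, gi$chrom, pos, ref, alt_base(ref), origin,
      cadd = stats::runif(1, 0, 9.9),
      consequence = sample(c("synonymous", "other"), 1),
      vaf = if (origin == "somatic") stats::runif(1, 0.3, 0.9) else NA)
  }

  # LOH-only wild-type samples: LOH with no variant must stay wild type
  wt_idx <- which(status == "wild_type")
  n_loh_only <- min(length(wt_idx), max(2L, round(n * 0.05)))
  for (s in samples[wt_idx[sample.int(length(wt_idx), n_loh_only)]]) {
    segments[[length(segments) + 1L]] <- data.frame(
      sample = s, chrom = g$chrom,
      start = max(1L, g$start - 5000L), end = g$end + 5000L,
      major_cn = stats::runif(1, 0.9, 2.2),
      minor_cn = stats::runif(1, 0, 0.19), stringsAsFactors = FALSE)
  }

  # decoy variants that curation must filter out (planted in WT samples)
  if (isTRUE(config$decoys) && length(wt_idx) >= 4) {
    ds <- samples[wt_idx[sample.int(length(wt_idx), 4)]]
    pos <- next_pos(4L)
    ref <- base_at(g$chrom, pos)
    alt <- alt_base(ref)
    variants[[length(variants) + 1L]] <- new_variant_row(  # low-VAF somatic
      ds[1], g$gene, g$chrom, pos[1], ref[1], alt[1], "somatic",
      cadd = 30, consequence = "non_synonymous", vaf = 0.1)
    variants[[length(variants) + 1L]] <- new_variant_row(  # common germline
      ds[2], g$gene, g$chrom, pos[2], ref[2], alt[2], "germline",
      cadd = 30, consequence = "non_synonymous", gnomad = 0.02)
    variants[[length(variants) + 1L]] <- new_variant_row(  # hyper-recurrent
      ds[3], g$gene, g$chrom, pos[3], ref[3], alt[3], "germline",
      cadd = 30, consequence = "non_synonymous", recurrence = 250L)
    variants[[length(variants) + 1L]] <- new_variant_row(  # failed filters
      ds[4], g$gene, g$chrom, pos[4], ref[4], alt[4], "somatic",
      cadd = 30, consequence = "non_synonymous", vaf = 0.5,
      filter = "LOWQUAL")
  }

  variants <- if (length(variants)) do.call(rbind, variants) else
    new_variant_row(character(0), character(0), character(0), integer(0),
                    character(0), character(0), character(0), numeric(0),
                    character(0))[0, ]
  segments <- if (length(segments)) do.call(rbind, segments) else
    data.frame(sample = character(0), chrom = character(0),
               start = integer(0), end = integer(0),
               major_cn = numeric(0), minor_cn = numeric(0))
  rownames(variants) <- NULL
  rownames(segments) <- NULL

  # --- feature counts ---------------------------------------------------
  feats <- names(config$baseline_means)
  means <- matrix(rep(config$baseline_means, each = n), nrow = n,
                  dimnames = list(samples, feats))
  deficient <- status == "biallelic"
  for (f in names(config$effect_features)) {
    means[deficient, f] <- means[deficient, f] * config$effect_features[[f]]
  }
  counts <- matrix(stats::rnbinom(n * length(feats),
                                  size = config$dispersion, mu = means),
                   nrow = n, dimnames = dimnames(means))
  features <- data.frame(sample = samples, counts, check.names = FALSE,
                         stringsAsFactors = FALSE)
  rownames(features) <- NULL

  # --- illustrative SV breakpoint table ---------------------------------
  svs <- local({
    n_sv <- stats::rpois(n, 5)
    rows <- lapply(seq_len(n), function(i) {
      if (n_sv[i] == 0) return(NULL)
      type <- sample(c("del", "tds", "inv", "trans"), n_sv[i],
                     replace = TRUE, prob = c(0.35, 0.3, 0.25, 0.1))
      chrom1 <- sample(contig_names, n_sv[i], replace = TRUE)
      pos1 <- sample.int(5e7, n_sv[i])
      size <- round(exp(stats::runif(n_sv[i], log(2e3), log(2e7))))
      chrom2 <- ifelse(type == "trans",
                       sample(contig_names, n_sv[i], replace = TRUE), chrom1)
      pos2 <- ifelse(type == "trans", sample.int(5e7, n_sv[i]), pos1 + size)
      data.frame(sample = samples[i], chrom1 = chrom1, pos1 = pos1,
                 chrom2 = chrom2, pos2 = pos2, type = type,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })

  # --- survival ---------------------------------------------------------
  base_rate <- 1 / 500  # wild-type mean survival 500 days
  rate <- ifelse(deficient, base_rate * config$hazard_ratio, base_rate)
  death <- stats::rexp(n, rate)
  censor <- stats::runif(n, 1, 1500)
  time <- pmax(1, round(pmin(death, censor)))
  event <- as.integer(death <= censor)
  biopsy <- as.Date("2015-01-01")
  survival <- data.frame(
    sample = samples,
    biopsy_date = as.character(biopsy),
    death_date = ifelse(event == 1, as.character(biopsy + time), ""),
    treatment_end_date = ifelse(event == 0, as.character(biopsy + time), ""),
    deceased = event, stringsAsFactors = FALSE)

  truth <- list(
    status = data.frame(sample = samples, status = status,
                        stringsAsFactors = FALSE),
    means = means,
    variant_ids = sprintf("%s:%s:%s>%s[%s]", variants$chrom, variants$pos,
                          variants$ref, variants$alt, variants$origin),
    segment_ids = seg_ids
  )

  structure(
    list(config = config, reference = reference, genes = genes,
         variants = variants, segments = segments, svs = svs,
         features = features, survival = survival, truth = truth),
    class = "ddr_cohort"
  )
}

#' Generate a matched null cohort
#'
#' Identical to [generate_cohort()] but with every multiplicative effect
#' forced to 1, so the planted labels are independent of the feature counts.
#' Used for permutation-calibration and false-discovery property checks.
#'
#' @inheritParams generate_cohort
#' @export
generate_null_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  config$effect_features[] <- 1
  config$hazard_ratio <- 1
  generate_cohort(config)
}

#' @export
print.ddr_cohort <- function(x, ...) {
  st <- table(factor(x$truth$status$status,
                     c("biallelic", "monoallelic", "vus", "wild_type")))
  cat(sprintf("Synthetic cohort: %d samples, planted gene %s\n",
              x$config$n_samples, x$config$planted_gene))
  cat(sprintf("  biallelic %d | monoallelic %d | VUS %d | wild-type %d\n",
              st[1], st[2], st[3], st[4]))
  cat(sprintf("  %d variants, %d CN segments, %d SVs, %d features\n",
              nrow(x$variants), nrow(x$segments), nrow(x$svs),
              ncol(x$features) - 1L))
  invisible(x)
}

#' The 645-sample worked-example fixture
#'
#' A breast-cancer-sized cohort whose planted BRCA2 ground truth is 17
#' biallelic samples (14 via germline, 3 via somatic pathogenic variants,
#' each with accompanying LOH), 7 monoallelic (4 germline, 3 somatic), 53
#' VUS-only carriers (42 germline, 11 somatic), and 568 wild-type samples.
#' The microhomology-deletion effect is 7.5-fold over a wild-type baseline
#' of 81 (deficient mean ~608).
#'
#' @param seed integer seed.
#' @param dir optional directory; when given the bundle is also written to
#'   disk via [write_cohort()].
#' @return A `ddr_cohort` bundle.
#' @export
write_brca2_fixture <- function(seed = 20150101, dir = NULL) {
  config <- cohort_config(
    n_samples = 645, planted_gene = "BRCA2",
    n_biallelic = 17, n_monoallelic = 7, n_vus = 53,
    effect_features = c(del.mh = 7.5),
    seed = seed
  )
  config$exact_origins <- list(
    biallelic = c(germline = 14, somatic = 3),
    monoallelic = c(germline = 4, somatic = 3),
    vus = c(germline = 42, somatic = 11)
  )
  cohort <- generate_cohort(config)
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}
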