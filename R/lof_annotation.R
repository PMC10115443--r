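#' Annotation thresholds
#'
#' Bundles the filtering and classification thresholds used throughout the
#' loss-of-function annotation. Defaults follow the screen's curation rules:
#' somatic variants need a variant allele fraction of at least 0.2; variants
#' seen in more than 200 carriers across both data sets are treated as
#' polymorphisms/artefacts; germline variants with population frequency above
#' 0.5% are presumed benign; CADD phred >= 25 is pathogenic and < 10 benign,
#' with non-synonymous variants in between classed as variants of unknown
#' significance (VUS); loss of heterozygosity (LOH) is called when the minor
#' allele copy number falls below 0.2 and a deep deletion when the total
#' tumour copy number falls below 0.3. All comparisons are strict as written.
#'
#' @param cadd_pathogenic_min,cadd_benign_max CADD phred class boundaries.
#' @param gnomad_max maximum germline population allele frequency.
#' @param vaf_min minimum somatic variant allele fraction.
#' @param recurrence_max maximum carrier count across data sets.
#' @param loh_minor_cn_max minor-allele copy number below which a segment is
#'   LOH.
#' @param deepdel_total_cn_max total copy number below which a segment is a
#'   deep deletion.
#' @param pcawg_min_callers minimum supporting variant callers (PCAWG only).
#' @return List of class `annotation_config`.
#' @export
annotation_config <- function(cadd_pathogenic_min = 25,
                              cadd_benign_max = 10,
                              gnomad_max = 0.005,
                              vaf_min = 0.2,
                              recurrence_max = 200,
                              loh_minor_cn_max = 0.2,
                              deepdel_total_cn_max = 0.3,
                              pcawg_min_callers = 2) {
  cfg <- list(
    cadd_pathogenic_min = cadd_pathogenic_min,
    cadd_benign_max = cadd_benign_max,
    gnomad_max = gnomad_max,
    vaf_min = vaf_min,
    recurrence_max = recurrence_max,
    loh_minor_cn_max = loh_minor_cn_max,
    deepdel_total_cn_max = deepdel_total_cn_max,
    pcawg_min_callers = pcawg_min_callers
  )
  if (any(unlist(cfg) <= 0)) {
    stop("all thresholds must be positive", call. = FALSE)
  }
  if (cadd_benign_max >= cadd_pathogenic_min) {
    stop_field("cadd_benign_max", "must be below cadd_pathogenic_min")
  }
  structure(cfg, class = "annotation_config")
}

#' Filter curated variants
#'
#' Applies the variant-level curation filters, in a stable order: keep
#' PASS-filtered records (and, for the PCAWG dialect, records supported by at
#' least `pcawg_min_callers` callers); drop variants carried by more than
#' `recurrence_max` samples across both data sets; drop somatic variants with
#' VAF below `vaf_min`; drop variants with gnomAD population frequency above
#' `gnomad_max` (missing frequency is treated as rare). Idempotent.
#'
#' @param variants data frame with columns `sample`, `gene`, `origin`
#'   (`"germline"`/`"somatic"`), `vaf` (somatic only; NA otherwise),
#'   `cadd_phred`, `gnomad_af` (NA allowed), `recurrence`, `filter`
#'   (`"PASS"`/other), and for PCAWG `caller_support`. Extra columns pass
#'   through.
#' @param config an [annotation_config()].
#' @param dataset `"hmf"` or `"pcawg"`.
#' @return Filtered data frame, original row order preserved.
#' @export
apply_variant_filters <- function(variants, config = annotation_config(),
                                  dataset = c("hmf", "pcawg")) {
  dataset <- match.arg(dataset)
  if (nrow(variants) == 0) return(variants)
  if (any(is.na(variants$recurrence))) {
    i <- which(is.na(variants$recurrence))[1]
    stop(sprintf(
      "recurrence missing for variant %s:%s %s>%s (sample %s)",
      variants$chrom[i] %||% "?", variants$pos[i] %||% "?",
      variants$ref[i] %||% "?", variants$alt[i] %||% "?", variants$sample[i]
    ), call. = FALSE)
  }
  keep <- variants$filter == "PASS"
  if (dataset == "pcawg") {
    keep <- keep & variants$caller_support >= config$pcawg_min_callers
  }
  keep <- keep & variants$recurrence <= config$recurrence_max
  somatic <- variants$origin == "somatic"
  keep <- keep & (!somatic | (!is.na(variants$vaf) &
                                variants$vaf >= config$vaf_min))
  af <- variants$gnomad_af
  keep <- keep & (is.na(af) | af <= config$gnomad_max)
  variants[keep, , drop = FALSE]
}

#' Classify variant pathogenicity
#'
#' Combines ClinVar status with the CADD phred score. A ClinVar
#' pathogenic/benign assertion overrides the score; a conflicting or missing
#' ClinVar status falls back to the score rule: phred >= 25 is pathogenic,
#' phred in (10, 25) is VUS when the consequence is non-synonymous, and
#' everything else is benign.
#'
#' @param cadd_phred numeric vector of CADD phred scores.
#' @param consequence character vector: `"synonymous"`, `"non_synonymous"`,
#'   or `"other"`.
#' @param clinvar character vector: `"pathogenic"`, `"benign"`,
#'   `"conflicting"`, or NA.
#' @param config an [annotation_config()].
#' @return Character vector: `"pathogenic"`, `"vus"`, or `"benign"`.
#' @export
classify_pathogenicity <- function(cadd_phred, consequence,
                                   clinvar = NA_character_,
                                   config = annotation_config()) {
  n <- length(cadd_phred)
  clinvar <- rep_len(clinvar, n)
  consequence <- rep_len(consequence, n)
  if (any(is.na(cadd_phred))) {
    stop("cadd_phred must be present for every variant", call. = FALSE)
  }
  out <- ifelse(
    cadd_phred >= config$cadd_pathogenic_min, "pathogenic",
    ifelse(cadd_phred > config$cadd_benign_max &
             consequence == "non_synonymous", "vus", "benign")
  )
  out[!is.na(clinvar) & clinvar == "pathogenic"] <- "pathogenic"
  out[!is.na(clinvar) & clinvar == "benign"] <- "benign"
  out
}

#' Call LOH and deep-deletion status per sample and gene
#'
#' Any overlap (>= 1 bp) between a gene interval and a copy-number segment
#' with minor-allele copy number below the LOH threshold flags the gene as
#' LOH in that sample; overlap with a segment whose total copy number
#' (major + minor) is below the deep-deletion threshold flags a deep
#' deletion. A deep deletion implies LOH.
#'
#' @param segments data frame with columns `sample`, `chrom`, `start`, `end`
#'   (1-based inclusive), `major_cn`, `minor_cn`.
#' @param genes data frame with columns `gene`, `chrom`, `start`, `end`.
#' @param config an [annotation_config()].
#' @return Data frame `sample`, `gene`, `loh`, `deep_deletion` for every
#'   sample appearing in `segments` crossed with every gene.
#' @export
call_copy_number_events <- function(segments, genes,
                                    config = annotation_config()) {
  if (nrow(segments) > 0) {
    bad <- segments$start > segments$end | segments$minor_cn > segments$major_cn |
      segments$minor_cn < 0
    if (any(bad)) {
      stop("malformed segment(s) at row(s) ",
           paste(which(bad), collapse = ", "), call. = FALSE)
    }
  }
  samples <- unique(segments$sample)
  grid <- expand.grid(sample = samples, gene = genes$gene,
                      stringsAsFactors = FALSE)
  grid$loh <- FALSE
  grid$deep_deletion <- FALSE
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    hit <- genes$chrom == seg$chrom & genes$start <= seg$end &
      genes$end >= seg$start
    if (!any(hit)) next
    is_deep <- (seg$major_cn + seg$minor_cn) < config$deepdel_total_cn_max
    is_loh <- seg$minor_cn < config$loh_minor_cn_max || is_deep
    if (!is_loh) next
    rows <- grid$sample == seg$sample & grid$gene %in% genes$gene[hit]
    grid$loh[rows] <- grid$loh[rows] | is_loh
    grid$deep_deletion[rows] <- grid$deep_deletion[rows] | is_deep
  }
  grid
}

#' Assign mono-/biallelic zygosity for one sample and gene
#'
#' Combines pathogenic-variant counts with copy-number flags: a deep deletion,
#' two or more pathogenic variants (assumed in trans), or one pathogenic
#' variant accompanied by LOH each constitute biallelic loss; a single
#' unaccompanied pathogenic variant is monoallelic; a sample carrying only
#' VUS is a VUS carrier; an LOH segment alone never counts as a hit
#' (LOH is frequent and broad, so on its own it is not evidence of gene
#' loss), leaving the sample wild type.
#'
#' @param sample,gene identifiers carried into the output.
#' @param pathogenic data frame of this sample/gene's pathogenic variants
#'   (needs columns `origin` and an identifier column `id`; may have 0 rows).
#' @param vus like `pathogenic`, for VUS variants.
#' @param loh,deep_deletion logical copy-number flags for this sample/gene.
#' @return One-row data frame: `sample`, `gene`, `status`, `evidence`
#'   (semicolon-joined identifiers), `n_germline`, `n_somatic`.
#' @export
classify_gene_zygosity <- function(sample, gene, pathogenic, vus,
                                   loh = FALSE, deep_deletion = FALSE) {
  np <- nrow(pathogenic)
  ev <- character(0)
  if (deep_deletion) {
    status <- "biallelic"
    ev <- c("deep_deletion", pathogenic$id)
  } else if (np >= 2) {
    status <- "biallelic"
    ev <- pathogenic$id
  } else if (np == 1 && loh) {
    status <- "biallelic"
    ev <- c(pathogenic$id, "loh")
  } else if (np == 1) {
    status <- "monoallelic"
    ev <- pathogenic$id
  } else if (nrow(vus) >= 1) {
    status <- "vus_carrier"
    ev <- vus$id
  } else {
    status <- "wild_type"
  }
  data.frame(
    sample = sample, gene = gene, status = status,
    evidence = paste(ev, collapse = ";"),
    n_germline = sum(pathogenic$origin == "germline"),
    n_somatic = sum(pathogenic$origin == "somatic"),
    stringsAsFactors = FALSE
  )
}

#' Annotate zygosity across a cohort
#'
#' End-to-end annotation: filters variants, classifies pathogenicity, calls
#' copy-number events, and assigns a [classify_gene_zygosity()] status for
#' every sample x gene pair.
#'
#' @param variants curated variant data frame (see [apply_variant_filters()];
#'   additionally needs `chrom`, `pos`, `ref`, `alt`, `consequence`,
#'   `clinvar`).
#' @param segments copy-number segment data frame.
#' @param genes gene coordinate table.
#' @param samples character vector of all cohort samples (so samples without
#'   any variant still receive wild-type calls).
#' @param config an [annotation_config()].
#' @param dataset `"hmf"` or `"pcawg"`.
#' @return Data frame of zygosity calls, one row per sample x gene.
#' @export
annotate_zygosity <- function(variants, segments, genes, samples,
                              config = annotation_config(),
                              dataset = c("hmf", "pcawg")) {
  dataset <- match.arg(dataset)
  v <- apply_variant_filters(variants, config, dataset)
  if (nrow(v) > 0) {
    v$pclass <- classify_pathogenicity(v$cadd_phred, v$consequence,
                                       v$clinvar, config)
    v$id <- sprintf("%s:%s:%s>%s[%s]", v$chrom, v$pos, v$ref, v$alt, v$origin)
  } else {
    v$pclass <- character(0)
    v$id <- character(0)
  }
  cn <- call_copy_number_events(segments, genes, config)
  cn_key <- paste(cn$sample, cn$gene)
  out <- vector("list", length(samples) * nrow(genes))
  k <- 0L
  for (s in samples) {
    vs <- v[v$sample == s, , drop = FALSE]
    for (g in genes$gene) {
      vg <- vs[vs$gene == g, , drop = FALSE]
      idx <- match(paste(s, g), cn_key)
      loh <- if (is.na(idx)) FALSE else cn$loh[idx]
      deep <- if (is.na(idx)) FALSE else cn$deep_deletion[idx]
      k <- k + 1L
      out[[k]] <- classify_gene_zygosity(
        s, g,
        pathogenic = vg[vg$pclass == "pathogenic", , drop = FALSE],
        vus = vg[vg$pclass == "vus", , drop = FALSE],
        loh = loh, deep_deletion = deep
      )
    }
  }
  do.call(rbind, out[seq_len(k)])
}

#' Stratify a cohort for modelling
#'
#' Splits one gene's zygosity calls into model positives, background, and
#' excluded samples. In biallelic mode the positives are the biallelic
#' samples; monoallelic-only samples are excluded alongside the VUS carriers
#' (neither positive nor clean background). In monoallelic mode biallelic
#' samples join the positives, since biallelic loss is a special case of
#' monoallelic loss. The wild-type samples form the background; the three
#' sets partition the cohort.
#'
#' @param calls zygosity calls for a single gene (columns `sample`,
#'   `status`).
#' @param zygosity_mode `"biallelic"` or `"monoallelic"`.
#' @return List with character vectors `positives`, `background`, `excluded`.
#' @export
stratify_cohort <- function(calls,
                            zygosity_mode = c("biallelic", "monoallelic")) {
  zygosity_mode <- match.arg(zygosity_mode)
  if (anyDuplicated(calls$sample)) {
    stop("duplicate sample ids in zygosity calls", call. = FALSE)
  }
  st <- calls$status
  if (zygosity_mode == "biallelic") {
    positives <- calls$sample[st == "biallelic"]
    excluded <- calls$sample[st %in% c("vus_carrier", "monoallelic")]
  } else {
    positives <- calls$sample[st %in% c("biallelic", "monoallelic")]
    excluded <- calls$sample[st == "vus_carrier"]
  }
  list(
    positives = positives,
    background = calls$sample[st == "wild_type"],
    excluded = excluded
  )
}
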