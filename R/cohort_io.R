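# Cohort bundle file I/O: FASTA via Biostrings, VCF v4.2 (written by a small
# emitter for the generator's records, read back with vcfR), and
# tab-delimited segment / SV / survival / feature tables.

vcf_info_string <- function(v) {
  fmt_opt <- function(key, val, fmt = "%s") {
    ifelse(is.na(val), "", sprintf(paste0(";", key, "=", fmt), val))
  }
  paste0(
    "GENE=", v$gene,
    ";CADD=", sprintf("%.4f", v$cadd_phred),
    fmt_opt("GNOMAD_AF", v$gnomad_af, "%.6f"),
    fmt_opt("CLINVAR", v$clinvar),
    ";CSQ=", v$consequence,
    ";RECURRENCE=", v$recurrence,
    ";CALLERS=", v$caller_support
  )
}

write_variant_vcf <- function(variants, samples, path, somatic = FALSE) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"CADD phred score\">",
    "##INFO=<ID=GNOMAD_AF,Number=1,Type=Float,Description=\"gnomAD population allele frequency\">",
    "##INFO=<ID=CLINVAR,Number=1,Type=String,Description=\"ClinVar class\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Coding consequence\">",
    "##INFO=<ID=RECURRENCE,Number=1,Type=Integer,Description=\"Carrier count across data sets\">",
    "##INFO=<ID=CALLERS,Number=1,Type=Integer,Description=\"Supporting variant callers\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (somatic) "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  lines <- character(0)
  if (nrow(variants) > 0) {
    key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
    ord <- order(variants$chrom, variants$pos, variants$ref, variants$alt)
    variants <- variants[ord, , drop = FALSE]
    key <- key[ord]
    fmt <- if (somatic) "GT:AF" else "GT"
    lines <- vapply(unique(key), function(k) {
      rows <- variants[key == k, , drop = FALSE]
      first <- rows[1, ]
      gt <- rep(if (somatic) "./.:." else "./.", length(samples))
      idx <- match(rows$sample, samples)
      gt[idx] <- if (somatic) {
        sprintf("0/1:%.4f", rows$vaf)
      } else {
        "0/1"
      }
      first$recurrence <- max(rows$recurrence)
      paste(c(first$chrom, first$pos, ".", first$ref, first$alt, ".",
              first$filter, vcf_info_string(first), fmt, gt),
            collapse = "\t")
    }, character(1))
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

info_field <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(?:^|;)", key, "=([^;]*)"), info))
  out <- rep(NA_character_, length(info))
  hit <- grepl(paste0("(?:^|;)", key, "="), info)
  out[hit] <- sub(paste0(".*(?:^|;)", key, "=([^;]*).*"), "\\1", info[hit])
  out
}

read_variant_vcf <- function(path, origin) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  n_rec <- nrow(fix)
  if (n_rec == 0) {
    return(new_variant_row(character(0), character(0), character(0),
                           integer(0), character(0), character(0),
                           character(0), numeric(0), character(0))[0, ])
  }
  info <- vcf@fix[, "INFO"]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  af <- if (origin == "somatic") {
    suppressWarnings(vcfR::extract.gt(vcf, element = "AF", as.numeric = TRUE))
  } else {
    NULL
  }
  rows <- lapply(seq_len(n_rec), function(i) {
    carriers <- colnames(gt)[!is.na(gt[i, ]) & gt[i, ] != "./."]
    if (!length(carriers)) return(NULL)
    data.frame(
      sample = carriers,
      gene = info_field(info[i], "GENE"),
      chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
      ref = fix$REF[i], alt = fix$ALT[i], origin = origin,
      vaf = if (origin == "somatic") as.numeric(af[i, carriers]) else
        NA_real_,
      cadd_phred = as.numeric(info_field(info[i], "CADD")),
      gnomad_af = as.numeric(info_field(info[i], "GNOMAD_AF")),
      clinvar = info_field(info[i], "CLINVAR"),
      consequence = info_field(info[i], "CSQ"),
      recurrence = as.integer(info_field(info[i], "RECURRENCE")),
      caller_support = as.integer(info_field(info[i], "CALLERS")),
      filter = fix$FILTER[i],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a cohort bundle to disk
#'
#' Serialises the bundle into standard plain-text formats: `ref.fa`,
#' `genes.tsv`, `germline.vcf` / `somatic.vcf` (multi-sample VCF v4.2 with
#' INFO keys CADD, GNOMAD_AF, CLINVAR and a FORMAT AF field carrying the
#' somatic VAF), `cn_segments.tsv`, `sv.tsv`, `survival.tsv`,
#' `features.tsv`, and `truth.tsv`.
#'
#' @param cohort a `ddr_cohort` bundle.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ddr_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(cohort$reference, file.path(dir, "ref.fa"))
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(cohort$genes, "genes.tsv")
  samples <- cohort$features$sample
  v <- cohort$variants
  write_variant_vcf(v[v$origin == "germline", , drop = FALSE], samples,
                    file.path(dir, "germline.vcf"), somatic = FALSE)
  write_variant_vcf(v[v$origin == "somatic", , drop = FALSE], samples,
                    file.path(dir, "somatic.vcf"), somatic = TRUE)
  tsv(cohort$segments, "cn_segments.tsv")
  tsv(cohort$svs, "sv.tsv")
  tsv(cohort$survival, "survival.tsv")
  tsv(cohort$features, "features.tsv")
  tsv(cohort$truth$status, "truth.tsv")
  invisible(dir)
}

#' Read a cohort bundle from disk
#'
#' Re-assembles the data frames written by [write_cohort()] (ground truth is
#' not read back; the returned object holds only what a real cohort would
#' provide). Variant records are expanded to one row per carrier sample.
#'
#' @param dir directory written by [write_cohort()].
#' @return List with `reference`, `genes`, `variants`, `segments`, `svs`,
#'   `survival`, `features`, `samples`.
#' @export
read_cohort <- function(dir) {
  tsv <- function(name, ...) {
    utils::read.table(file.path(dir, name), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE, ...)
  }
  features <- tsv("features.tsv")
  variants <- rbind(
    read_variant_vcf(file.path(dir, "germline.vcf"), "germline"),
    read_variant_vcf(file.path(dir, "somatic.vcf"), "somatic")
  )
  list(
    reference = Biostrings::readDNAStringSet(file.path(dir, "ref.fa")),
    genes = tsv("genes.tsv"),
    variants = variants,
    segments = tsv("cn_segments.tsv"),
    svs = tsv("sv.tsv"),
    survival = tsv("survival.tsv"),
    features = features,
    samples = features$sample
  )
}
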