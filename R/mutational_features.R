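#' SBS-96 channel names
#'
#' The 96 single-base-substitution channels in COSMIC order: the six
#' pyrimidine-strand base changes (C>A, C>G, C>T, T>A, T>C, T>G), each across
#' the 16 trinucleotide contexts with 5' and 3' flanks cycling A, C, G, T.
#'
#' @return Character vector of length 96, e.g. `"A[C>A]A"`.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(b5, b3) {
      paste0(b5, "[", s, "]", b3)
    })))
  }))
}

#' Count SNVs in trinucleotide context (SBS-96)
#'
#' Maps each single-nucleotide variant to its pyrimidine-strand channel.
#' Variants whose reference base is a purine are reverse-complemented together
#' with their flanking context, so the counts are strand symmetric.
#'
#' @param snvs data frame with columns `chrom`, `pos` (1-based), `ref`, `alt`;
#'   biallelic single-base substitutions only.
#' @param reference a [Biostrings::DNAStringSet] whose names match `chrom`.
#' @return Named integer vector over [sbs96_channels()]; attribute `n_snv`
#'   holds the total count.
#' @export
count_sbs96 <- function(snvs, reference) {
  channels <- sbs96_channels()
  counts <- stats::setNames(integer(96), channels)
  if (nrow(snvs) == 0) {
    attr(counts, "n_snv") <- 0L
    return(counts)
  }
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(snvs)))
  bad_allele <- nchar(snvs$ref) != 1 | nchar(snvs$alt) != 1
  if (any(bad_allele)) {
    stop("non-SNV record at row(s) ", paste(which(bad_allele), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(snvs))) {
    chrom <- as.character(snvs$chrom[i])
    pos <- snvs$pos[i]
    if (!chrom %in% names(reference)) {
      stop("chromosome not in reference: ", chrom, call. = FALSE)
    }
    ctx <- as.character(Biostrings::subseq(reference[[chrom]],
                                           start = pos - 1L, end = pos + 1L))
    ref <- toupper(snvs$ref[i])
    alt <- toupper(snvs$alt[i])
    if (substr(ctx, 2, 2) != ref) {
      stop(sprintf("reference mismatch at %s:%d (VCF ref %s, FASTA %s)",
                   chrom, pos, ref, substr(ctx, 2, 2)), call. = FALSE)
    }
    if (ref %in% c("A", "G")) {
      ctx <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(ctx)))
      ref <- chartr("ACGT", "TGCA", ref)
      alt <- chartr("ACGT", "TGCA", alt)
    }
    channel <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]",
                      substr(ctx, 3, 3))
    counts[channel] <- counts[channel] + 1L
  }
  attr(counts, "n_snv") <- nrow(snvs)
  counts
}

#' Classify an indel by its 3' DNA context
#'
#' Deletions are separated by the sequence immediately 3' of the breakpoint:
#' if the full deleted sequence recurs there the deletion is
#' repeat-mediated (`del.rep`); otherwise a deletion of length >= 2 sharing at
#' least a 1-bp prefix with the 3' flank is microhomology-mediated
#' (`del.mh`, the footprint of microhomology-mediated end joining); remaining
#' deletions are `del.other`. Insertions are counted as a single class.
#' Repeat context takes precedence over microhomology.
#'
#' @param ref,alt VCF-style left-anchored alleles (e.g. ref "ATAG", alt "A"
#'   deletes "TAG").
#' @param flank3 reference sequence immediately 3' of the deleted bases; must
#'   be at least as long as the deletion.
#' @param min_mh_del_len minimum deletion length for a microhomology call
#'   (default 2).
#' @return One of `"ins"`, `"del.mh"`, `"del.rep"`, `"del.other"`.
#' @export
classify_indel <- function(ref, alt, flank3, min_mh_del_len = 2L) {
  if (!nzchar(ref) || !nzchar(alt)) {
    stop("empty ref or alt allele", call. = FALSE)
  }
  ref <- toupper(ref); alt <- toupper(alt); flank3 <- toupper(flank3)
  if (nchar(alt) > nchar(ref)) {
    return("ins")
  }
  if (nchar(alt) >= nchar(ref)) {
    stop("not an indel: ref and alt have equal length", call. = FALSE)
  }
  if (substr(ref, 1, nchar(alt)) != alt) {
    stop("alleles are not left-anchored (alt must be a prefix of ref)",
         call. = FALSE)
  }
  deleted <- substr(ref, nchar(alt) + 1L, nchar(ref))
  dlen <- nchar(deleted)
  if (nchar(flank3) < dlen) {
    stop("3' flank shorter than the deletion", call. = FALSE)
  }
  if (substr(flank3, 1, dlen) == deleted) {
    return("del.rep")
  }
  if (dlen >= min_mh_del_len &&
      substr(flank3, 1, 1) == substr(deleted, 1, 1)) {
    return("del.mh")
  }
  "del.other"
}

#' Indel category names
#' @return `c("ins", "del.mh", "del.rep", "del.other")`.
#' @export
indel_categories <- function() c("ins", "del.mh", "del.rep", "del.other")

sv_size_bins <- function() {
  c("1-10kb", "10-100kb", "100kb-1Mb", "1-10Mb", ">10Mb")
}

#' Structural-variant category names
#'
#' The 32 SV categories: \{clustered, non-clustered\} x (\{deletion, tandem
#' duplication, inversion\} x five size bins, plus translocations which carry
#' no size bin).
#'
#' @return Character vector of length 32.
#' @export
sv_categories <- function() {
  typed <- as.vector(t(outer(c("del", "tds", "inv"), sv_size_bins(), paste,
                             sep = ".")))
  unlist(lapply(c("clust", "nonclust"), function(cl) {
    paste(cl, c(typed, "trans"), sep = ".")
  }))
}

#' Classify one structural variant by type and size
#'
#' Inter-chromosomal records are translocations and carry no size bin.
#' Intra-chromosomal deletions, tandem duplications and inversions are binned
#' by `pos2 - pos1` into left-closed, right-open intervals
#' \[1 kb, 10 kb), \[10 kb, 100 kb), \[100 kb, 1 Mb), \[1 Mb, 10 Mb),
#' \[10 Mb, Inf); events shorter than 1 kb fall in the smallest bin.
#'
#' @param chrom1,pos1,chrom2,pos2 breakpoint coordinates (`pos2 > pos1` for
#'   intra-chromosomal records).
#' @param type one of `"del"`, `"tds"`, `"inv"`, `"trans"`.
#' @return list with `type`, `size_bin` (NA for translocations) and
#'   `category` (unprefixed, i.e. without the cluster flag).
#' @export
classify_sv <- function(chrom1, pos1, chrom2, pos2, type) {
  type <- match.arg(type, c("del", "tds", "inv", "trans"))
  if (chrom1 != chrom2 || type == "trans") {
    return(list(type = "trans", size_bin = NA_character_, category = "trans"))
  }
  if (pos2 <= pos1) {
    stop("intra-chromosomal SV must have pos2 > pos1", call. = FALSE)
  }
  size <- pos2 - pos1
  bin_idx <- findInterval(size, c(1e4, 1e5, 1e6, 1e7)) + 1L
  bin <- sv_size_bins()[bin_idx]
  list(type = type, size_bin = bin, category = paste(type, bin, sep = "."))
}

#' Flag clustered structural-variant breakpoints
#'
#' A sample's mean inter-rearrangement distance `dbar` is the genome-wide
#' average of gaps between consecutive sorted breakpoints within each
#' chromosome. Consecutive breakpoints whose gap is at most `dbar/10` are
#' chained into runs; runs of at least `min_run` breakpoints form clusters.
#'
#' @param breakpoints data frame with columns `chrom`, `pos`, one row per
#'   breakpoint of one sample.
#' @param min_run minimum breakpoints per cluster (default 10).
#' @param ratio distance shrinkage defining a clustered gap (default 10).
#' @return Logical vector in input row order; `TRUE` for breakpoints inside a
#'   cluster. Fewer than two breakpoints yield all `FALSE`.
#' @export
detect_sv_clusters <- function(breakpoints, min_run = 10L, ratio = 10) {
  n <- nrow(breakpoints)
  out <- logical(n)
  if (n < 2) return(out)
  ord <- order(breakpoints$chrom, breakpoints$pos)
  chrom <- breakpoints$chrom[ord]
  pos <- breakpoints$pos[ord]
  same <- chrom[-1] == chrom[-n]
  gaps <- (pos[-1] - pos[-n])[same]
  if (length(gaps) == 0) return(out)
  dbar <- mean(gaps)
  linked <- same & (pos[-1] - pos[-n]) <= dbar / ratio
  # runs of chained breakpoints: breakpoint i is in the run if linked to i-1
  # or i+1; count run lengths over maximal chains
  run_id <- cumsum(c(TRUE, !linked))
  run_len <- tabulate(run_id)
  clustered_sorted <- run_len[run_id] >= min_run
  out[ord] <- clustered_sorted
  out
}

#' Count structural variants into the 32 categories
#'
#' Classifies each SV record by type and size and by whether either of its
#' breakpoints lies in a breakpoint cluster, then tallies the 32 categories.
#'
#' @param svs data frame with columns `chrom1`, `pos1`, `chrom2`, `pos2`,
#'   `type` for one sample.
#' @inheritParams detect_sv_clusters
#' @return Named integer vector over [sv_categories()].
#' @export
count_sv_categories <- function(svs, min_run = 10L, ratio = 10) {
  cats <- sv_categories()
  counts <- stats::setNames(integer(length(cats)), cats)
  if (nrow(svs) == 0) return(counts)
  bp <- data.frame(
    chrom = c(svs$chrom1, svs$chrom2),
    pos = c(svs$pos1, svs$pos2)
  )
  flag <- detect_sv_clusters(bp, min_run = min_run, ratio = ratio)
  n <- nrow(svs)
  sv_clustered <- flag[seq_len(n)] | flag[n + seq_len(n)]
  for (i in seq_len(n)) {
    cl <- classify_sv(svs$chrom1[i], svs$pos1[i], svs$chrom2[i], svs$pos2[i],
                      svs$type[i])
    name <- paste(if (sv_clustered[i]) "clust" else "nonclust", cl$category,
                  sep = ".")
    counts[name] <- counts[name] + 1L
  }
  counts
}

#' Assemble and transform the per-sample feature matrix
#'
#' Combines per-sample mutational summary statistics (signature exposures,
#' indel categories, SV categories) into the modelling matrix. The age-related
#' signature SBS1 is dropped (it proxies patient age rather than a repair
#' phenotype); signature 5 is retained. Counts are transformed as
#' `log(x + 1)` and then z-scored per feature over the fitting scope, so a
#' model's transform can be frozen and applied to held-out samples without
#' leakage.
#'
#' @param counts numeric matrix or data frame, samples x features; row names
#'   (or a `sample` column) identify samples.
#' @param drop_features feature names excluded from modelling
#'   (default `"SBS1"`).
#' @param fit_samples samples used to estimate the per-feature centre/scale;
#'   default all rows.
#' @return Object of class `ddr_features`: list with `raw` (counts after
#'   feature drop), `transformed` (log, z-scored), `center`, `scale`.
#' @export
build_feature_matrix <- function(counts, drop_features = "SBS1",
                                 fit_samples = NULL) {
  if (is.data.frame(counts)) {
    if ("sample" %in% names(counts)) {
      rn <- counts$sample
      counts <- as.matrix(counts[setdiff(names(counts), "sample")])
      rownames(counts) <- rn
    } else {
      counts <- as.matrix(counts)
    }
  }
  if (anyDuplicated(colnames(counts))) {
    stop("feature names must be unique", call. = FALSE)
  }
  keep <- setdiff(colnames(counts), drop_features)
  raw <- counts[, keep, drop = FALSE]
  lg <- log(raw + 1)
  fit_samples <- fit_samples %||% rownames(raw)
  fit_lg <- lg[fit_samples, , drop = FALSE]
  center <- colMeans(fit_lg)
  scale_ <- apply(fit_lg, 2, stats::sd)
  flat <- !is.finite(scale_) | scale_ == 0
  if (any(flat)) {
    warning("constant feature(s) z-scored to zero: ",
            paste(colnames(raw)[flat], collapse = ", "), call. = FALSE)
    scale_[flat] <- 1
    center[flat] <- colMeans(lg)[flat]
  }
  transformed <- sweep(sweep(lg, 2, center), 2, scale_, `/`)
  transformed[, flat] <- 0
  structure(
    list(raw = raw, transformed = transformed,
         center = center, scale = scale_),
    class = "ddr_features"
  )
}

#' Apply a frozen feature transform to new samples
#'
#' @param fm a `ddr_features` object (supplies the centre/scale).
#' @param new_counts samples x features count matrix with the same feature
#'   names.
#' @return Transformed matrix for the new samples.
#' @export
apply_feature_transform <- function(fm, new_counts) {
  stopifnot(inherits(fm, "ddr_features"))
  missing <- setdiff(colnames(fm$raw), colnames(new_counts))
  if (length(missing)) {
    stop("missing features in new data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(new_counts[, colnames(fm$raw), drop = FALSE])
  sweep(sweep(log(x + 1), 2, fm$center), 2, fm$scale, `/`)
}
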