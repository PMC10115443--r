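# Independent base-R oracle for trinucleotide channel assignment, used to
# check the Biostrings-based counter.
oracle_channel <- function(ctx, ref, alt) {
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                                 collapse = ""))
  if (ref %in% c("A", "G")) {
    ctx <- rc(ctx); ref <- chartr("ACGT", "TGCA", ref)
    alt <- chartr("ACGT", "TGCA", alt)
  }
  paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]", substr(ctx, 3, 3))
}

test_that("SBS-96 counting matches a brute-force oracle on an enumerated contig", {
  contig <- paste0("ACATGCTTAGCATTGACCAGTAGCATGGACCT",
                   "TGACGTACGATCCAGGATCGATTACGGATCAA")  # 64 bp
  ref <- Biostrings::DNAStringSet(c(ctgX = contig))
  set.seed(9)
  pos <- sample(2:(nchar(contig) - 1), 10)
  ref_base <- substring(contig, pos, pos)
  alt_base <- vapply(ref_base, function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  snvs <- data.frame(chrom = "ctgX", pos = pos, ref = ref_base,
                     alt = alt_base, stringsAsFactors = FALSE)
  counts <- count_sbs96(snvs, ref)

  expected <- stats::setNames(integer(96), sbs96_channels())
  for (i in seq_len(10)) {
    ctx <- substring(contig, pos[i] - 1, pos[i] + 1)
    ch <- oracle_channel(ctx, ref_base[i], alt_base[i])
    expected[ch] <- expected[ch] + 1L
  }
  expect_equal(as.integer(counts), as.integer(expected))
  expect_equal(sum(counts), 10)
  expect_equal(attr(counts, "n_snv"), 10L)
})

test_that("pyrimidine-strand rule maps the two strands to one channel", {
  ref <- Biostrings::DNAStringSet(c(c1 = "AACAT", c2 = "ATGTA"))
  # C>T at ACA on c1; G>A at TGT on c2 is its reverse complement
  fwd <- count_sbs96(data.frame(chrom = "c1", pos = 3, ref = "C", alt = "T"),
                     ref)
  rev <- count_sbs96(data.frame(chrom = "c2", pos = 3, ref = "G", alt = "A"),
                     ref)
  expect_equal(fwd[["A[C>T]A"]], 1L)
  expect_equal(as.integer(fwd), as.integer(rev))
})

test_that("reference mismatch is reported with its position", {
  ref <- Biostrings::DNAStringSet(c(c1 = "AACAT"))
  expect_error(
    count_sbs96(data.frame(chrom = "c1", pos = 3, ref = "G", alt = "A"), ref),
    "c1:3")
})

test_that("indel classification follows the 3'-context rules", {
  # deletion TAG with a full downstream copy -> repeat-mediated
  expect_equal(classify_indel("ATAG", "A", "TAGC"), "del.rep")
  # deletion TAG with 1-bp prefix match and length >= 2 -> microhomology
  expect_equal(classify_indel("ATAG", "A", "TACC"), "del.mh")
  # single-base deletion with no context match -> other
  expect_equal(classify_indel("AT", "A", "GCA"), "del.other")
  # single-base deletion with downstream copy is still repeat-mediated
  expect_equal(classify_indel("AT", "A", "TGG"), "del.rep")
  # 1-bp deletions never qualify for microhomology
  expect_equal(classify_indel("AT", "A", "TAA"), "del.rep")
  expect_equal(classify_indel("AC", "A", "CGA", min_mh_del_len = 2),
               "del.rep")
  expect_equal(classify_indel("A", "AT", "whatever"), "ins")
  expect_error(classify_indel("", "A", "TTT"), "empty")
  expect_error(classify_indel("ATAG", "A", "TA"), "flank")
})

test_that("SV typing and size bins use left-closed boundaries", {
  expect_equal(classify_sv("c1", 1000, "c1", 51000, "tds")$category,
               "tds.10-100kb")
  expect_equal(classify_sv("c1", 1000, "c2", 51000, "del")$category, "trans")
  expect_equal(classify_sv("c1", 1000, "c1", 11000, "del")$category,
               "del.10-100kb")  # exactly 10 kb -> left-closed upper bin
  expect_equal(classify_sv("c1", 1000, "c1", 10999, "del")$category,
               "del.1-10kb")
  expect_equal(classify_sv("c1", 1000, "c1", 1500, "inv")$category,
               "inv.1-10kb")  # < 1 kb falls into the smallest bin
  expect_equal(classify_sv("c1", 1, "c1", 2e7 + 1, "del")$category,
               "del.>10Mb")
  expect_error(classify_sv("c1", 100, "c1", 50, "del"), "pos2")
  expect_length(sv_categories(), 32)
})

test_that("cluster detection matches the brute-force oracle on random inputs", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(20:200, 1)
    bp <- data.frame(
      chrom = sample(c("c1", "c2"), n, replace = TRUE),
      pos = sample.int(1e7, n))
    # sprinkle a tight run half the time
    if (rep %% 2 == 0) {
      k <- sample(8:15, 1)
      bp$pos[1:k] <- 5e6 + cumsum(sample(50:200, k, replace = TRUE))
      bp$chrom[1:k] <- "c1"
    }
    expect_equal(detect_sv_clusters(bp), oracle_clusters(bp))
  }
})

test_that("cluster rule edge cases: run length 10 vs 9, uniform spacing", {
  mk <- function(n_tight) {
    tight <- 1e6 + (0:(n_tight - 1)) * 100
    rest <- seq(2e6, 9e6, length.out = 40)
    data.frame(chrom = "c1", pos = c(tight, rest))
  }
  f10 <- detect_sv_clusters(mk(10))
  expect_equal(sum(f10), 10)
  expect_true(all(f10[1:10]))
  f9 <- detect_sv_clusters(mk(9))
  expect_false(any(f9))
  uniform <- data.frame(chrom = "c1", pos = seq(1e5, 1e6, by = 1e4))
  expect_false(any(detect_sv_clusters(uniform)))
  expect_false(any(detect_sv_clusters(data.frame(chrom = "c1", pos = 5))))
})

test_that("SV category counting conserves totals and splits by clusterness", {
  set.seed(8)
  svs <- data.frame(
    chrom1 = "c1", pos1 = seq(1e6, 8e6, length.out = 30),
    chrom2 = "c1", type = sample(c("del", "tds", "inv"), 30, replace = TRUE))
  svs$pos2 <- svs$pos1 + sample(c(5e3, 5e4, 5e5), 30, replace = TRUE)
  counts <- count_sv_categories(svs)
  expect_equal(sum(counts), 30)
  trans <- data.frame(chrom1 = "c1", pos1 = 1e6, chrom2 = "c2", pos2 = 2e6,
                      type = "trans")
  ct <- count_sv_categories(trans)
  expect_equal(unname(ct["nonclust.trans"]), 1L)
  expect_equal(sum(ct), 1)
})

test_that("NNLS recovers constructed exposures and matches a grid oracle", {
  set.seed(4)
  S <- matrix(stats::rexp(96 * 4), nrow = 96)
  S <- sweep(S, 2, colSums(S), `/`)
  colnames(S) <- paste0("SIG", 1:4)
  e_star <- c(120, 0, 35, 60)
  fit <- fit_exposures(as.numeric(S %*% e_star), S)
  expect_lt(max(abs(fit$exposures - e_star)) / max(e_star), 1e-6)
  expect_lt(fit$residual, 1e-8)

  # zero counts -> zero exposures
  fit0 <- fit_exposures(rep(0, 96), S)
  expect_equal(unname(fit0$exposures), rep(0, 4))
  expect_equal(fit0$residual, 0)

  # counts proportional to one column load fully on that signature
  fit1 <- fit_exposures(50 * S[, 2], S)
  expect_equal(unname(fit1$exposures[2]), 50, tolerance = 1e-8)
  expect_lt(max(fit1$exposures[-2]), 1e-8)

  # exhaustive integer grid oracle on 3 signatures, exposures 0..6
  S3 <- S[, 1:3]
  S3 <- sweep(S3, 2, colSums(S3), `/`)
  grid <- as.matrix(expand.grid(0:6, 0:6, 0:6))
  set.seed(10)
  noisy <- as.numeric(S3 %*% c(2, 5, 1)) + stats::rnorm(96, sd = 0.01)
  noisy <- pmax(noisy, 0)
  resid <- apply(grid, 1, function(e) sum((noisy - S3 %*% e)^2))
  fit_n <- fit_exposures(noisy, S3)
  expect_lte(fit_n$residual^2, min(resid) + 1e-10)
  expect_equal(round(unname(fit_n$exposures)), unname(grid[which.min(resid), ]))
})

test_that("signature column normalisation and dimensions are enforced", {
  S <- matrix(stats::rexp(96 * 2), nrow = 96)
  expect_error(fit_exposures(rep(1, 96), S), "sum to 1")
  S <- sweep(S, 2, colSums(S), `/`)
  expect_error(fit_exposures(rep(1, 95), S), "conform")
  expect_warning(fit_exposures(rep(1, 96), cbind(a = S[, 1], b = S[, 1])),
                 "rank deficient")
})

test_that("exposure conversion is linear with pass-through for novel labels", {
  conv <- diag(3)
  rownames(conv) <- c("O1", "O2", "O3")
  colnames(conv) <- c("R1", "R2", "R3")
  e <- c(O1 = 2, O2 = 5, O3 = 1)
  expect_equal(unname(convert_exposures(e, conv)), unname(e))

  conv2 <- matrix(c(1, 1), nrow = 2, dimnames = list(c("O1", "O2"), "R1"))
  expect_equal(unname(convert_exposures(c(O1 = 3, O2 = 5), conv2)), 8)

  e_novel <- c(O1 = 3, O2 = 5, N1 = 7)
  out <- convert_exposures(e_novel, conv2)
  expect_equal(unname(out["N1"]), 7)
  expect_equal(unname(out["R1"]), 8)
})

test_that("feature matrix drops SBS1, transforms and freezes the scaling", {
  set.seed(12)
  counts <- matrix(rpois(60, 20), nrow = 10,
                   dimnames = list(paste0("S", 1:10),
                                   c("SBS1", "SBS3", "del.mh", "ins",
                                     "flat", "sv")))
  counts[, "flat"] <- 7
  expect_warning(fm <- build_feature_matrix(counts), "constant")
  expect_false("SBS1" %in% colnames(fm$transformed))
  expect_equal(unname(colMeans(fm$transformed[, c("SBS3", "del.mh")])),
               c(0, 0), tolerance = 1e-8)
  expect_equal(unname(apply(fm$transformed[, c("SBS3", "del.mh")], 2, sd)),
               c(1, 1), tolerance = 1e-8)
  expect_true(all(fm$transformed[, "flat"] == 0))
  # log(0 + 1) = 0 before scaling
  zero_row <- matrix(0, 1, 6, dimnames = list("Z", colnames(counts)))
  tr <- apply_feature_transform(fm, zero_row)
  expect_equal(unname(tr[1, "SBS3"]),
               unname((0 - fm$center["SBS3"]) / fm$scale["SBS3"]))
  expect_error(apply_feature_transform(fm, zero_row[, 1:3, drop = FALSE]),
               "missing features")
})

test_that("bundled signature and conversion matrices round-trip the fit", {
  sig_path <- system.file("extdata", "synthetic_signatures.tsv",
                          package = "ddrscreen")
  S <- read_signature_matrix(sig_path)
  expect_equal(dim(S), c(96L, 3L))
  expect_equal(rownames(S), sbs96_channels())
  expect_equal(unname(colSums(S)), rep(1, 3))
  e_star <- c(SBS2 = 30, SBS3 = 120, SBS13 = 15)
  fit <- fit_exposures(as.numeric(S %*% e_star), S)
  expect_equal(fit$exposures, e_star, tolerance = 1e-8)

  conv <- read_conversion_matrix(system.file(
    "extdata", "synthetic_conversion.tsv", package = "ddrscreen"))
  out <- convert_exposures(c(Organ.A = 4, Organ.C = 2), conv)
  expect_equal(unname(out["SBS2"]), 4 + 2 * 0.5)
  expect_equal(unname(out["SBS3"]), 2 * 0.5)
})
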