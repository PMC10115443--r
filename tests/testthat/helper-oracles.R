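# Brute-force breakpoint-cluster oracle: for each breakpoint, grow the
# maximal chain of neighbours with gaps at most (mean gap)/ratio and flag
# chains of at least min_run members. Quadratic, independent of the
# package's chaining implementation.
oracle_clusters <- function(bp, min_run = 10, ratio = 10) {
  n <- nrow(bp)
  if (n < 2) return(logical(n))
  ord <- order(bp$chrom, bp$pos)
  chrom <- bp$chrom[ord]; pos <- bp$pos[ord]
  gaps <- c()
  for (i in 2:n) if (chrom[i] == chrom[i - 1]) {
    gaps <- c(gaps, pos[i] - pos[i - 1])
  }
  if (!length(gaps)) return(logical(n))
  thr <- mean(gaps) / ratio
  flag_sorted <- logical(n)
  for (i in seq_len(n)) {
    members <- i
    j <- i
    while (j > 1 && chrom[j - 1] == chrom[j] && pos[j] - pos[j - 1] <= thr) {
      j <- j - 1; members <- c(j, members)
    }
    j <- i
    while (j < n && chrom[j + 1] == chrom[j] && pos[j + 1] - pos[j] <= thr) {
      j <- j + 1; members <- c(members, j)
    }
    if (length(members) >= min_run) flag_sorted[i] <- TRUE
  }
  out <- logical(n)
  out[ord] <- flag_sorted
  out
}
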