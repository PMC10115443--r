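#' Read a signature matrix from a tab-delimited file
#'
#' Expects a header row of signature names and a first column of the 96
#' SBS channel labels (any order; rows are re-ordered to
#' [sbs96_channels()]). Columns are renormalised to sum to exactly 1 to
#' absorb rounding in the stored file. A small synthetic example ships with
#' the package:
#' `system.file("extdata", "synthetic_signatures.tsv", package = "ddrscreen")`.
#'
#' @param path file path.
#' @return 96 x S numeric matrix with channel rownames.
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  channels <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- channels
  missing <- setdiff(sbs96_channels(), channels)
  if (length(missing)) {
    stop("signature matrix lacks channel(s): ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  m <- m[sbs96_channels(), , drop = FALSE]
  sweep(m, 2, colSums(m), `/`)
}

#' Read an exposure conversion matrix from a tab-delimited file
#'
#' Expects a header row of reference signature names and a first column of
#' organ-specific signature names, as consumed by [convert_exposures()].
#'
#' @param path file path.
#' @return Numeric matrix, organ signatures x reference signatures.
#' @export
read_conversion_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
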