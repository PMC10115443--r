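#' Fit signature exposures by non-negative least squares
#'
#' Decomposes a 96-channel SBS count vector into non-negative exposures over
#' a catalogue of signatures: `e = argmin ||c - S e||_2, e >= 0`, solved by
#' the Lawson-Hanson active-set algorithm, which is deterministic (ties in a
#' rank-deficient catalogue are resolved by its fixed active-set order).
#'
#' @param counts numeric vector of 96 channel counts (as from
#'   [count_sbs96()]).
#' @param signatures 96 x S numeric matrix; each column a signature summing
#'   to 1 (checked to 1e-6). Column names are the signature labels.
#' @return Object of class `signature_fit`: list with `exposures` (named,
#'   non-negative), `residual` (Euclidean norm of `c - S e`), and
#'   `signatures`.
#' @export
fit_exposures <- function(counts, signatures) {
  signatures <- as.matrix(signatures)
  if (length(counts) != nrow(signatures)) {
    stop("counts and signature matrix dimensions do not conform",
         call. = FALSE)
  }
  colsum <- colSums(signatures)
  if (any(abs(colsum - 1) > 1e-6)) {
    stop("signature columns must sum to 1 (within 1e-6)", call. = FALSE)
  }
  if (any(signatures < 0)) {
    stop("signature matrix must be non-negative", call. = FALSE)
  }
  if (qr(signatures)$rank < ncol(signatures)) {
    warning("signature matrix is rank deficient; exposures may not be unique",
            call. = FALSE)
  }
  counts <- as.numeric(counts)
  if (all(counts == 0)) {
    e <- stats::setNames(numeric(ncol(signatures)), colnames(signatures))
    return(structure(list(exposures = e, residual = 0,
                          signatures = signatures),
                     class = "signature_fit"))
  }
  fit <- pracma::lsqnonneg(signatures, counts)
  e <- stats::setNames(as.numeric(fit$x), colnames(signatures))
  structure(
    list(exposures = e,
         residual = sqrt(sum((counts - signatures %*% e)^2)),
         signatures = signatures),
    class = "signature_fit"
  )
}

#' @export
print.signature_fit <- function(x, ...) {
  cat("Signature exposure fit (NNLS)\n")
  nz <- x$exposures[x$exposures > 0]
  print(round(nz, 2))
  cat(sprintf("residual norm: %.4g\n", x$residual))
  invisible(x)
}

#' Convert organ-specific exposures to reference-signature exposures
#'
#' Applies a linear conversion matrix mapping organ-specific signature
#' exposures onto reference (COSMIC-style) signatures. Exposures whose labels
#' are absent from the conversion matrix (novel signatures such as N1-N12, or
#' the mismatch-repair signatures MMR1/MMR2) pass through unchanged under
#' their original labels.
#'
#' @param exposures named numeric vector of organ-specific exposures.
#' @param conversion numeric matrix; rows named by organ-specific signatures,
#'   columns by reference signatures. Entry (o, r) is the fraction of organ
#'   signature o attributed to reference signature r.
#' @return Named numeric vector: converted reference exposures followed by
#'   any passed-through novel exposures.
#' @export
convert_exposures <- function(exposures, conversion) {
  conversion <- as.matrix(conversion)
  convertible <- names(exposures)[names(exposures) %in% rownames(conversion)]
  novel <- setdiff(names(exposures), convertible)
  out <- numeric(0)
  if (length(convertible)) {
    e <- exposures[convertible]
    ref <- as.numeric(t(conversion[convertible, , drop = FALSE]) %*% e)
    out <- stats::setNames(ref, colnames(conversion))
  }
  c(out, exposures[novel])
}
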