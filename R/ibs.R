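#' Identity-by-state similarity of two genotype vectors
#'
#' Over sites where both samples are non-missing, IBS is the fraction of
#' shared alleles: `sum(2 - |g1 - g2|) / (2 * n_sites)`. Sites are compared
#' pairwise-complete per pair of samples, matching the behaviour expected
#' when IBS is computed before imputation.
#'
#' @param g1,g2 Dosage vectors of equal length.
#' @return Similarity in `[0, 1]`, or `NA` when no site is complete in both.
#' @export
ibs_pair <- function(g1, g2) {
  if (length(g1) != length(g2)) {
    stop("dosage vectors must have equal length", call. = FALSE)
  }
  ok <- !is.na(g1) & !is.na(g2)
  if (!any(ok)) return(NA_real_)
  sum(2 - abs(g1[ok] - g2[ok])) / (2 * sum(ok))
}

#' Pairwise identity-by-state similarity matrix
#'
#' @param x A [geno_matrix].
#' @param labels Optional label subset (e.g. `"hybrid"`) restricting which
#'   samples enter the matrix.
#' @return A symmetric numeric matrix with unit diagonal, sample ids as
#'   dimnames.
#' @export
ibs_matrix <- function(x, labels = NULL) {
  stopifnot(inherits(x, "geno_matrix"))
  idx <- if (is.null(labels)) seq_len(n_samples(x)) else which_label(x, labels)
  if (length(idx) < 2L) {
    stop("need at least two samples for an IBS matrix", call. = FALSE)
  }
  d <- x$dosage[idx, , drop = FALSE]
  n <- nrow(d)
  out <- diag(1, n)
  dimnames(out) <- list(x$samples[idx], x$samples[idx])
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      out[i, j] <- out[j, i] <- ibs_pair(d[i, ], d[j, ])
    }
  }
  out
}
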