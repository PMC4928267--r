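#' Curation thresholds
#'
#' Bundles every threshold of the genotype curation chain. Defaults follow
#' the GBS curation workflow this package implements: per-genotype minimum
#' read depth 8; sites retained only when their missing fraction is strictly
#' below 0.20; samples removed when their missing fraction exceeds 0.20;
#' sites with minor allele frequency below 0.05 removed; heterozygote-excess
#' Hardy-Weinberg exact test at alpha 0.001; after imputation and panel
#' balancing, only sites with MAF strictly above 0.10 in the pooled ancestral
#' panels retained.
#'
#' @param min_depth Minimum per-genotype read depth; calls below it are
#'   masked to missing.
#' @param max_site_missing Site missing-fraction threshold (strict: a site at
#'   exactly this fraction is dropped).
#' @param max_sample_missing Sample missing-fraction threshold (non-strict:
#'   a sample at exactly this fraction is kept).
#' @param min_maf Minor-allele-frequency threshold over all samples
#'   (non-strict: MAF equal to it is kept).
#' @param hwe_alpha Significance level of the heterozygote-excess exact test.
#' @param ancestral_min_maf MAF threshold on the pooled ancestral panels
#'   (strict: MAF equal to it is dropped).
#' @return A list of class `curation_config`.
#' @export
curation_config <- function(min_depth = 8L, max_site_missing = 0.20,
                            max_sample_missing = 0.20, min_maf = 0.05,
                            hwe_alpha = 0.001, ancestral_min_maf = 0.10) {
  stopifnot(min_depth >= 0,
            max_site_missing >= 0, max_site_missing <= 1,
            max_sample_missing >= 0, max_sample_missing <= 1,
            min_maf >= 0, min_maf <= 0.5,
            hwe_alpha > 0, hwe_alpha < 1,
            ancestral_min_maf >= 0, ancestral_min_maf <= 0.5)
  structure(list(min_depth = as.integer(min_depth),
                 max_site_missing = max_site_missing,
                 max_sample_missing = max_sample_missing,
                 min_maf = min_maf, hwe_alpha = hwe_alpha,
                 ancestral_min_maf = ancestral_min_maf),
            class = "curation_config")
}

#' Mask low-depth genotype calls
#'
#' Sets every cell whose read depth is below `min_depth` to missing; all
#' other cells, and the depth matrix itself, are unchanged. A call at exactly
#' `min_depth` reads is retained.
#'
#' @param x A [geno_matrix] with depth data.
#' @param min_depth Minimum number of supporting reads.
#' @return A `geno_matrix`.
#' @export
mask_low_depth <- function(x, min_depth = 8L) {
  stopifnot(inherits(x, "geno_matrix"), min_depth >= 0)
  if (is.null(x$depth)) {
    stop("matrix has no depth data; skip the depth-masking step",
         call. = FALSE)
  }
  low <- !is.na(x$depth) & x$depth < min_depth
  x$dosage[low] <- NA_integer_
  x
}

#' Filter sites by missing-data fraction
#'
#' Keeps sites whose missing fraction over the current samples is strictly
#' below `max_missing`; a site at exactly the threshold is dropped. Site
#' order is preserved.
#'
#' @param x A [geno_matrix].
#' @param max_missing Missing-fraction threshold in `[0, 1]`.
#' @return A `geno_matrix`.
#' @export
filter_sites_by_missingness <- function(x, max_missing = 0.20) {
  stopifnot(inherits(x, "geno_matrix"), max_missing >= 0, max_missing <= 1)
  x[, site_missingness(x) < max_missing]
}

#' Filter samples by missing-data fraction
#'
#' Removes samples whose missing fraction is strictly above `max_missing`;
#' a sample at exactly the threshold is kept. The site list is unchanged.
#'
#' @inheritParams filter_sites_by_missingness
#' @return A `geno_matrix`.
#' @export
filter_samples_by_missingness <- function(x, max_missing = 0.20) {
  stopifnot(inherits(x, "geno_matrix"), max_missing >= 0, max_missing <= 1)
  keep <- sample_missingness(x) <= max_missing
  if (!any(keep)) {
    stop("all samples exceed the missingness threshold", call. = FALSE)
  }
  x[keep, ]
}

#' Per-site minor allele frequency
#'
#' MAF is `min(f_alt, 1 - f_alt)` with `f_alt` the alternate-allele frequency
#' over non-missing calls in the chosen samples. The minor allele is
#' recomputed per call; it is never assumed to be the alternate allele. Sites
#' with zero non-missing calls get `NA`.
#'
#' @param x A [geno_matrix].
#' @param samples Optional sample ids (or indices) to restrict to.
#' @return Numeric vector of per-site MAF in `[0, 0.5]`, `NA` where undefined.
#' @export
site_maf <- function(x, samples = NULL) {
  stopifnot(inherits(x, "geno_matrix"))
  d <- x$dosage
  if (!is.null(samples)) {
    if (is.character(samples)) {
      idx <- match(samples, x$samples)
      if (anyNA(idx)) {
        stop("unknown sample id(s): ",
             paste(samples[is.na(idx)], collapse = ", "), call. = FALSE)
      }
      samples <- idx
    }
    if (length(samples) == 0L) stop("empty sample subset", call. = FALSE)
    d <- d[samples, , drop = FALSE]
  }
  n_obs <- colSums(!is.na(d))
  f_alt <- colSums(d, na.rm = TRUE) / (2 * n_obs)
  maf <- pmin(f_alt, 1 - f_alt)
  maf[n_obs == 0L] <- NA_real_
  maf
}

#' Filter sites by minor allele frequency
#'
#' With `strict = FALSE` (the genome-wide filter) sites with MAF below
#' `min_maf` are removed, so a site at exactly the threshold is kept. With
#' `strict = TRUE` (the ancestral-panel filter) only sites with MAF strictly
#' above `min_maf` are retained, so a site at exactly the threshold is
#' dropped. The frequency is computed on `samples` when given (e.g. the
#' pooled ancestral panels) but failing sites are removed from the whole
#' matrix. Sites with undefined MAF count as MAF 0.
#'
#' @param x A [geno_matrix].
#' @param min_maf Threshold in `[0, 0.5]`.
#' @param samples Optional sample subset on which the frequency is computed.
#' @param strict Use the strict (`>`) comparison?
#' @return A `geno_matrix`.
#' @export
filter_by_maf <- function(x, min_maf = 0.05, samples = NULL, strict = FALSE) {
  stopifnot(inherits(x, "geno_matrix"), min_maf >= 0, min_maf <= 0.5)
  maf <- site_maf(x, samples)
  maf[is.na(maf)] <- 0
  keep <- if (strict) maf > min_maf else maf >= min_maf
  x[, keep]
}

#' Filter sites by the heterozygote-excess exact test
#'
#' Removes sites whose exact Hardy-Weinberg p-value (by default one-sided
#' toward heterozygote excess, the signature of collapsed paralogous GBS
#' loci) is below `alpha`. Genotype counts are taken over the current
#' non-missing calls at each site.
#'
#' @param x A [geno_matrix].
#' @param alpha Significance level in `(0, 1)`.
#' @param alternative `"excess"` (default) or `"two_sided"`.
#' @return A `geno_matrix`.
#' @export
#' @seealso [hwe_het_excess_pvalue()]
filter_hwe <- function(x, alpha = 0.001,
                       alternative = c("excess", "two_sided")) {
  stopifnot(inherits(x, "geno_matrix"), alpha > 0, alpha < 1)
  alternative <- match.arg(alternative)
  p <- site_hwe_pvalues(x, alternative)
  x[, is.na(p) | p >= alpha]
}

#' @rdname filter_hwe
#' @return For `site_hwe_pvalues`: a numeric vector of per-site p-values
#'   (`NA` for sites with no non-missing calls).
#' @export
site_hwe_pvalues <- function(x, alternative = c("excess", "two_sided")) {
  alternative <- match.arg(alternative)
  d <- x$dosage
  n0 <- colSums(d == 0L, na.rm = TRUE)
  n1 <- colSums(d == 1L, na.rm = TRUE)
  n2 <- colSums(d == 2L, na.rm = TRUE)
  p <- rep(NA_real_, n_sites(x))
  testable <- (n0 + n1 + n2) > 0L
  p[testable] <- vapply(which(testable), function(j) {
    hwe_het_excess_pvalue(hwe_counts(n0[j], n1[j], n2[j]), alternative)
  }, numeric(1))
  p
}
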