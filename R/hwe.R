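#' Genotype counts at one biallelic site
#'
#' @param n_hom_ref,n_het,n_hom_alt Non-negative genotype counts.
#' @return A list of class `hwe_counts`.
#' @export
hwe_counts <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0)) stop("genotype counts must be >= 0", call. = FALSE)
  if (sum(counts) == 0) stop("no genotypes to test", call. = FALSE)
  structure(list(n_hom_ref = as.integer(n_hom_ref),
                 n_het = as.integer(n_het),
                 n_hom_alt = as.integer(n_hom_alt)),
            class = "hwe_counts")
}

#' Exact Hardy-Weinberg test for heterozygote excess
#'
#' Conditional exact test: given `n` diploids carrying `nA` copies of one
#' allele (and `2n - nA` of the other), the number of heterozygotes `h`
#' ranges over the values of the same parity as `nA` with
#' `0 <= h <= min(nA, 2n - nA)`, with probability
#' \deqn{P(h) = \frac{n!\,2^h\,n_A!\,n_B!}{n_0!\,h!\,n_2!\,(2n)!}}
#' (the Levene-Haldane distribution, with `n0`/`n2` the implied homozygote
#' counts). The one-sided "excess" p-value sums `P(h')` over `h'` at or above
#' the observed heterozygote count; the two-sided p-value sums `P(h')` over
#' all `h'` whose probability does not exceed that of the observed count.
#'
#' @param counts An [hwe_counts] object (or a length-3 vector of hom-ref,
#'   het, hom-alt counts).
#' @param alternative `"excess"` (default) or `"two_sided"`.
#' @return A p-value in `(0, 1]`.
#' @export
#' @examples
#' hwe_het_excess_pvalue(hwe_counts(5, 9, 0))
hwe_het_excess_pvalue <- function(counts,
                                  alternative = c("excess", "two_sided")) {
  alternative <- match.arg(alternative)
  if (!inherits(counts, "hwe_counts")) {
    counts <- hwe_counts(counts[[1]], counts[[2]], counts[[3]])
  }
  n <- counts$n_hom_ref + counts$n_het + counts$n_hom_alt
  n_alt <- counts$n_het + 2L * counts$n_hom_alt
  dist <- hwe_het_distribution(n, n_alt)
  obs <- counts$n_het
  p_obs <- dist$prob[match(obs, dist$h)]
  p <- switch(alternative,
    # complement of the strictly-smaller tail: exactly 1 when obs is minimal
    excess = 1 - sum(dist$prob[dist$h < obs]),
    two_sided = sum(dist$prob[dist$prob <= p_obs * (1 + 1e-7)])
  )
  min(1, p)
}

# Levene-Haldane distribution of the heterozygote count given n diploids and
# n_alt copies of one allele. Computed in log space for stability at n >> 1.
hwe_het_distribution <- function(n, n_alt) {
  n_other <- 2L * n - n_alt
  h_max <- min(n_alt, n_other)
  h <- seq.int(n_alt %% 2L, h_max, by = 2L)
  n2 <- (n_alt - h) / 2L          # hom for the counted allele
  n0 <- n - h - n2                # hom for the other allele
  logw <- lgamma(n + 1) - lgamma(n0 + 1) - lgamma(h + 1) - lgamma(n2 + 1) +
    h * log(2) +
    lgamma(n_alt + 1) + lgamma(n_other + 1) - lgamma(2 * n + 1)
  logw <- logw - max(logw)
  prob <- exp(logw) / sum(exp(logw))
  data.frame(h = h, prob = prob)
}
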