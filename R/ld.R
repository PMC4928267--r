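#' Windowed LD-pruning parameters
#'
#' Defaults mirror the classic `indep-pairwise 10 3 0.5` pruning: windows of
#' 10 sites, shifted by 3 sites, removing one member of any pair with
#' dosage r-squared above 0.5.
#'
#' @param window_size Window width in sites (>= 2).
#' @param step Window shift in sites (1 <= step <= window_size).
#' @param r2_max r-squared threshold above which a pair is thinned.
#' @return A list of class `prune_params`.
#' @export
prune_params <- function(window_size = 10L, step = 3L, r2_max = 0.5) {
  stopifnot(window_size >= 2, step >= 1, step <= window_size,
            r2_max >= 0, r2_max <= 1)
  structure(list(window_size = as.integer(window_size),
                 step = as.integer(step), r2_max = r2_max),
            class = "prune_params")
}

#' Squared dosage correlation between two sites
#'
#' Squared Pearson correlation of genotype dosages over pairwise-complete
#' entries (both non-missing). Undefined — fewer than two complete pairs, or
#' zero variance in either vector — returns `NA`; pruning treats `NA` as no
#' evidence of correlation.
#'
#' @param x,y Dosage vectors of equal length (values 0/1/2 or `NA`).
#' @return r-squared in `[0, 1]`, or `NA`.
#' @export
dosage_r2 <- function(x, y) {
  if (length(x) != length(y)) {
    stop("dosage vectors must have equal length", call. = FALSE)
  }
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Windowed r-squared LD pruning
#'
#' Slides a window of `window_size` sites along each chromosome in steps of
#' `step` sites. Within each window every pair of still-kept sites is
#' checked in site order; when a pair's dosage r-squared exceeds `r2_max`
#' the member with the lower minor allele frequency is removed (ties are
#' broken by removing the later position). Windows never span chromosomes.
#' The procedure is deterministic for a fixed input.
#'
#' @param x A [geno_matrix] with sites ordered by (chrom, pos).
#' @param params A [prune_params] object.
#' @return Integer vector of surviving site indices, in original order.
#' @export
window_prune <- function(x, params = prune_params()) {
  stopifnot(inherits(x, "geno_matrix"), inherits(params, "prune_params"))
  ord <- order(x$sites$chrom, x$sites$pos)
  if (!identical(ord, seq_len(n_sites(x)))) {
    stop("sites must be ordered by (chrom, pos) before pruning", call. = FALSE)
  }
  maf <- site_maf(x)
  maf[is.na(maf)] <- 0
  kept <- rep(TRUE, n_sites(x))
  for (chrom in unique(x$sites$chrom)) {
    idx <- which(x$sites$chrom == chrom)
    m <- length(idx)
    if (m < 2L) next
    starts <- seq.int(1L, m, by = params$step)
    for (s in starts) {
      win <- idx[s:min(s + params$window_size - 1L, m)]
      if (length(win) < 2L) next
      for (a in seq_len(length(win) - 1L)) {
        i <- win[a]
        if (!kept[i]) next
        for (b in seq.int(a + 1L, length(win))) {
          j <- win[b]
          if (!kept[j]) next
          r2 <- dosage_r2(x$dosage[, i], x$dosage[, j])
          if (!is.na(r2) && r2 > params$r2_max) {
            # drop the lower-MAF member; tie -> the later position
            drop <- if (maf[i] < maf[j]) i else j
            kept[drop] <- FALSE
            if (drop == i) break
          }
        }
      }
    }
  }
  which(kept)
}

#' Distances between consecutive sites
#'
#' Base-pair distances between consecutive sites on the same chromosome
#' (chromosome boundaries contribute nothing). The median of this vector is
#' the usual summary of marker spacing after filtering.
#'
#' @param x A [geno_matrix].
#' @return Integer vector of distances (possibly empty).
#' @export
inter_site_distances <- function(x) {
  stopifnot(inherits(x, "geno_matrix"))
  unlist(lapply(split(x$sites$pos, x$sites$chrom), function(p) {
    if (length(p) < 2L) integer(0) else diff(sort(p))
  }), use.names = FALSE)
}
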