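#' LD-kNNi imputation parameters
#'
#' @param l Number of highest-LD sites used to measure sample similarity
#'   around the target site (default 6).
#' @param k Number of nearest-neighbour samples that vote (default 17).
#' @param epsilon Small positive floor applied to distances so that a
#'   zero-distance neighbour gets a large finite weight.
#' @return A list of class `imputation_params`.
#' @export
imputation_params <- function(l = 6L, k = 17L, epsilon = 1e-9) {
  stopifnot(l >= 1, k >= 1, epsilon > 0)
  structure(list(l = as.integer(l), k = as.integer(k), epsilon = epsilon),
            class = "imputation_params")
}

#' Sites in highest LD with a target site
#'
#' Ranks all other sites by squared dosage correlation with the target site
#' and returns the top `l`; ties are broken by site order, undefined
#' correlations rank last. Fewer than `l` indices are returned when the
#' matrix is smaller.
#'
#' @param x A [geno_matrix].
#' @param site Target site index.
#' @param l Number of sites to return.
#' @param r2 Optional precomputed vector of r-squared of every site with the
#'   target (used internally to avoid recomputation).
#' @return Integer vector of site indices, highest LD first.
#' @export
top_ld_sites <- function(x, site, l = 6L, r2 = NULL) {
  stopifnot(inherits(x, "geno_matrix"), l >= 1)
  if (is.null(r2)) {
    r2 <- suppressWarnings(
      as.vector(stats::cor(x$dosage[, site], x$dosage,
                           use = "pairwise.complete.obs"))^2
    )
  }
  r2[site] <- NA_real_
  ord <- order(-r2, seq_along(r2), na.last = TRUE)
  ord <- setdiff(ord, site)
  ord[seq_len(min(l, length(ord)))]
}

#' Impute one missing genotype by LD-kNN
#'
#' Distance from the target sample to each candidate sample is the mean
#' absolute dosage difference over the `l` highest-LD sites where both are
#' non-missing (floored at `epsilon`); candidates with no comparable LD site
#' or missing at the target site are excluded. The `k` nearest candidates
#' vote for their dosage class with weight `1/distance^2`; the class with
#' the largest summed weight wins, ties going to the smaller dosage.
#'
#' @param x A [geno_matrix].
#' @param sample Target sample index.
#' @param site Target site index (must be missing in `x`).
#' @param params An [imputation_params] object.
#' @param ld_sites Optional precomputed [top_ld_sites()] result.
#' @return Imputed dosage in `{0, 1, 2}`, or `NA` when no candidate carries
#'   data at the site.
#' @export
impute_cell <- function(x, sample, site, params = imputation_params(),
                        ld_sites = NULL) {
  stopifnot(inherits(x, "geno_matrix"))
  if (!is.na(x$dosage[sample, site])) {
    stop("target cell is not missing", call. = FALSE)
  }
  if (is.null(ld_sites)) ld_sites <- top_ld_sites(x, site, params$l)
  knn_vote(x$dosage, sample, site, ld_sites, params)
}

# Core voting step shared by impute_cell / impute_all; works on the raw
# dosage matrix so one pass never sees its own imputations.
knn_vote <- function(dosage, sample, site, ld_sites, params) {
  candidates <- which(!is.na(dosage[, site]))
  candidates <- candidates[candidates != sample]
  if (length(candidates) == 0L) return(NA_integer_)
  target <- dosage[sample, ld_sites, drop = TRUE]
  cand_geno <- dosage[candidates, ld_sites, drop = FALSE]
  diff <- abs(sweep(cand_geno, 2L, target, "-"))
  n_comp <- rowSums(!is.na(diff))
  usable <- n_comp > 0L
  if (!any(usable)) return(NA_integer_)
  candidates <- candidates[usable]
  d <- pmax(rowMeans(diff[usable, , drop = FALSE], na.rm = TRUE),
            params$epsilon)
  ord <- order(d, seq_along(d))
  take <- ord[seq_len(min(params$k, length(ord)))]
  votes <- dosage[candidates[take], site]
  weights <- 1 / d[take]^2
  score <- vapply(0:2, function(g) sum(weights[votes == g]), numeric(1))
  as.integer(which.max(score) - 1L)   # which.max ties -> smaller dosage
}

#' Impute all missing genotypes by LD-kNN
#'
#' Single-pass imputation: every imputable missing cell is filled using only
#' the original (pre-imputation) genotypes, so results do not depend on cell
#' order. Cells with no informative neighbour are left missing.
#'
#' @param x A [geno_matrix].
#' @param params An [imputation_params] object.
#' @return A `geno_matrix` with missing cells filled where possible.
#' @export
impute_all <- function(x, params = imputation_params()) {
  stopifnot(inherits(x, "geno_matrix"))
  miss <- which(is.na(x$dosage), arr.ind = TRUE)
  if (nrow(miss) == 0L) return(x)
  r2 <- suppressWarnings(
    stats::cor(x$dosage, use = "pairwise.complete.obs")^2
  )
  out <- x$dosage
  for (site in unique(miss[, 2L])) {
    ld_sites <- top_ld_sites(x, site, params$l, r2 = r2[, site])
    for (sample in miss[miss[, 2L] == site, 1L]) {
      out[sample, site] <- knn_vote(x$dosage, sample, site, ld_sites, params)
    }
  }
  x$dosage <- out
  x
}

#' Masking-based imputation accuracy
#'
#' Masks `n_mask` randomly chosen non-missing cells, imputes them (with
#' LD-kNN or, as a baseline, the per-site modal genotype) and returns the
#' proportion recovered exactly. The mask depends only on `seed`, so
#' different methods or parameter settings can be compared on identical
#' masks.
#'
#' @param x A [geno_matrix].
#' @param params An [imputation_params] object.
#' @param n_mask Number of cells to mask (>= 1).
#' @param seed Integer seed for the mask.
#' @param method `"ldknni"` (default) or `"mode"` (per-site most frequent
#'   genotype among unmasked calls; ties to the smaller dosage).
#' @return Fraction of masked cells recovered exactly.
#' @export
estimate_accuracy <- function(x, params = imputation_params(),
                              n_mask = 1000L, seed = 1L,
                              method = c("ldknni", "mode")) {
  stopifnot(inherits(x, "geno_matrix"))
  if (n_mask <= 0) stop("n_mask must be positive", call. = FALSE)
  method <- match.arg(method)
  observed <- which(!is.na(x$dosage))
  if (length(observed) < n_mask) {
    stop("fewer than n_mask non-missing cells", call. = FALSE)
  }
  cells <- with_seed_or_not(seed, sample(observed, n_mask))
  truth <- x$dosage[cells]
  masked <- x
  masked$dosage[cells] <- NA_integer_
  if (method == "ldknni") {
    filled <- impute_all(masked, params)$dosage[cells]
  } else {
    modes <- apply(masked$dosage, 2L, dosage_mode)
    filled <- modes[((cells - 1L) %/% nrow(x$dosage)) + 1L]
  }
  mean(!is.na(filled) & filled == truth)
}

dosage_mode <- function(d) {
  d <- d[!is.na(d)]
  if (length(d) == 0L) return(NA_integer_)
  counts <- tabulate(d + 1L, nbins = 3L)
  as.integer(which.max(counts) - 1L)
}

#' Grid search for LD-kNN parameters
#'
#' Evaluates [estimate_accuracy()] for every `(l, k)` grid point on one
#' fixed mask (same `seed` and `n_mask` throughout) and returns the argmax;
#' ties prefer the smaller `l`, then the smaller `k`.
#'
#' @param x A [geno_matrix].
#' @param l_grid,k_grid Integer vectors of candidate values.
#' @param n_mask Number of cells masked for every evaluation.
#' @param seed Integer seed fixing the mask.
#' @return A list with `l`, `k`, `accuracy` and the full `grid` data frame.
#' @export
optimize_parameters <- function(x, l_grid = c(2L, 4L, 6L, 8L),
                                k_grid = c(5L, 11L, 17L, 23L),
                                n_mask = 1000L, seed = 1L) {
  stopifnot(length(l_grid) >= 1, length(k_grid) >= 1)
  grid <- expand.grid(l = sort(unique(as.integer(l_grid))),
                      k = sort(unique(as.integer(k_grid))))
  grid$accuracy <- mapply(function(l, k) {
    estimate_accuracy(x, imputation_params(l = l, k = k),
                      n_mask = n_mask, seed = seed)
  }, grid$l, grid$k)
  ord <- order(-grid$accuracy, grid$l, grid$k)
  best <- grid[ord[1L], ]
  list(l = best$l, k = best$k, accuracy = best$accuracy, grid = grid)
}
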