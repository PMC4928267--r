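#' Balance the ancestral panels by random downsampling
#'
#' PCA-projection ancestry estimation requires equal-sized ancestral panels;
#' the larger of the wild and vinifera panels is randomly downsampled
#' (seeded) to the size of the smaller. Hybrids and unknowns are untouched.
#'
#' @param x A labelled [geno_matrix].
#' @param seed Integer seed for the random removal.
#' @return A `geno_matrix`; the removed sample ids are attached as
#'   `attr(, "removed")`.
#' @export
downsample_equal <- function(x, seed = 1L) {
  stopifnot(inherits(x, "geno_matrix"))
  wild <- which_label(x, "wild")
  vin <- which_label(x, "vinifera")
  if (length(wild) == 0L || length(vin) == 0L) {
    stop("both ancestral panels (wild, vinifera) must be present",
         call. = FALSE)
  }
  n_keep <- min(length(wild), length(vin))
  drop <- integer(0)
  for (panel in list(wild, vin)) {
    if (length(panel) > n_keep) {
      drop <- c(drop, with_seed_or_not(
        seed, sample(panel, length(panel) - n_keep)))
    }
  }
  out <- if (length(drop)) x[-drop, ] else x
  attr(out, "removed") <- x$samples[drop]
  out
}

#' Fit PCA on the ancestral panels
#'
#' Restricts the matrix to the wild and vinifera samples, normalizes each
#' site as `(g - mean) / sqrt(p(1 - p))` with the adjusted allele-frequency
#' estimate `p = (1 + sum(g)) / (2 + 2n)` (never exactly 0 or 1), and takes
#' the singular value decomposition of the normalized panel matrix. PC1 is
#' oriented so that the vinifera panel mean exceeds the wild panel mean;
#' the stored panel means are the means of the fitting samples' own scores.
#'
#' @param x A fully observed [geno_matrix] whose wild/vinifera samples form
#'   the ancestral panels. Panels must be equal-sized (see
#'   [downsample_equal()]) and every site polymorphic within the pooled
#'   panel (see [filter_by_maf()] with `strict = TRUE`).
#' @param n_components Number of PCs to retain (default 2).
#' @return An object of class `pca_model` with elements `site_means`,
#'   `norm_factors`, `loadings` (sites x PCs, unit-norm columns),
#'   `eigenvalues`, `variance_explained`, `ancestral_scores` (with labels),
#'   `mean_vinifera_pc1`, `mean_wild_pc1`, and the model's `sites`.
#' @export
fit_pca <- function(x, n_components = 2L) {
  stopifnot(inherits(x, "geno_matrix"), n_components >= 1)
  wild <- which_label(x, "wild")
  vin <- which_label(x, "vinifera")
  if (length(wild) < 2L || length(vin) < 2L) {
    stop("need at least two samples in each ancestral panel", call. = FALSE)
  }
  if (length(wild) != length(vin)) {
    stop("ancestral panels must be equal-sized; run downsample_equal() first",
         call. = FALSE)
  }
  anc <- c(wild, vin)
  g <- x$dosage[anc, , drop = FALSE]
  if (anyNA(g)) {
    stop("ancestral panel has missing dosages; impute before fitting",
         call. = FALSE)
  }
  n <- nrow(g)
  csum <- colSums(g)
  mono <- csum == 0L | csum == 2L * n
  if (any(mono)) {
    stop("monomorphic site(s) in the ancestral panel (e.g. ",
         site_ids(x$sites)[which(mono)[1L]],
         "); apply the ancestral MAF filter first", call. = FALSE)
  }
  site_means <- csum / n
  p_hat <- (1 + csum) / (2 + 2 * n)
  norm_factors <- sqrt(p_hat * (1 - p_hat))
  z <- sweep(sweep(g, 2L, site_means, "-"), 2L, norm_factors, "/")
  n_components <- min(n_components, n - 1L, ncol(z))
  sv <- svd(z, nu = n_components, nv = n_components)
  loadings <- sv$v
  scores <- z %*% loadings
  eig <- sv$d^2 / (n - 1L)
  # orient PC1: vinifera panel mean above wild panel mean
  labels <- x$labels[anc]
  if (mean(scores[labels == "vinifera", 1L]) <
      mean(scores[labels == "wild", 1L])) {
    loadings[, 1L] <- -loadings[, 1L]
    scores[, 1L] <- -scores[, 1L]
  }
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(n_components))
  rownames(scores) <- x$samples[anc]
  structure(list(
    site_means = site_means,
    norm_factors = norm_factors,
    loadings = loadings,
    eigenvalues = eig[seq_len(n_components)],
    variance_explained = (eig / sum(eig))[seq_len(n_components)],
    ancestral_scores = scores,
    ancestral_labels = labels,
    mean_vinifera_pc1 = mean(scores[labels == "vinifera", 1L]),
    mean_wild_pc1 = mean(scores[labels == "wild", 1L]),
    sites = x$sites
  ), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d sites, %d PCs (PC1 explains %.1f%%)\n",
              length(x$site_means), ncol(x$loadings),
              100 * x$variance_explained[1L]))
  cat(sprintf("  PC1 panel means: wild %.3f, vinifera %.3f\n",
              x$mean_wild_pc1, x$mean_vinifera_pc1))
  invisible(x)
}

#' Project samples onto fitted PC axes
#'
#' Scores are the dot product of the site-normalized genotypes with the
#' fitted loadings. Missing dosages (when imputation was skipped) are
#' handled by restricting the dot product to observed sites and rescaling by
#' `n_sites / n_observed`; affected rows are flagged in the `"rescaled"`
#' attribute.
#'
#' @param model A [fit_pca()] model.
#' @param dosage A dosage matrix (samples x sites, same sites as the model)
#'   or a [geno_matrix].
#' @return A scores matrix (samples x PCs).
#' @export
project_samples <- function(model, dosage) {
  stopifnot(inherits(model, "pca_model"))
  if (inherits(dosage, "geno_matrix")) {
    if (!identical(site_ids(dosage$sites), site_ids(model$sites))) {
      stop("sites of the matrix do not match the fitted model", call. = FALSE)
    }
    dosage <- dosage$dosage
  }
  if (is.null(dim(dosage))) dosage <- matrix(dosage, nrow = 1L)
  if (ncol(dosage) != length(model$site_means)) {
    stop("dosage has ", ncol(dosage), " sites; model was fitted on ",
         length(model$site_means), call. = FALSE)
  }
  z <- sweep(sweep(dosage, 2L, model$site_means, "-"),
             2L, model$norm_factors, "/")
  miss <- is.na(z)
  rescaled <- rowSums(miss) > 0L
  if (any(rescaled)) {
    z[miss] <- 0
    scores <- z %*% model$loadings
    scale <- ncol(dosage) / (ncol(dosage) - rowSums(miss))
    scores <- scores * scale
  } else {
    scores <- z %*% model$loadings
  }
  colnames(scores) <- colnames(model$loadings)
  rownames(scores) <- rownames(dosage)
  attr(scores, "rescaled") <- rescaled
  scores
}

#' PC1 distance-ratio ancestry coefficient
#'
#' For a PC1 score `s`, with `a = |s - mean_vinifera_pc1|` and
#' `b = |s - mean_wild_pc1|`, the estimated ancestry is
#' `percent_vinifera = b / (a + b) * 100`. Scores outside the interval
#' between the two panel means are reported as computed and flagged.
#'
#' @param model A [fit_pca()] model.
#' @param pc1_score Numeric vector of PC1 scores.
#' @param sample Optional sample ids for the output.
#' @return Data frame with columns `sample`, `pc1_score`, `dist_vinifera`
#'   (a), `dist_wild` (b), `percent_vinifera`, `out_of_interval`.
#' @export
ancestry_percent <- function(model, pc1_score, sample = NULL) {
  stopifnot(inherits(model, "pca_model"))
  mv <- model$mean_vinifera_pc1
  mw <- model$mean_wild_pc1
  if (mv == mw) {
    stop("degenerate model: coincident panel means on PC1", call. = FALSE)
  }
  a <- abs(pc1_score - mv)
  b <- abs(pc1_score - mw)
  if (is.null(sample)) {
    sample <- names(pc1_score)
    if (is.null(sample)) sample <- paste0("sample", seq_along(pc1_score))
  }
  data.frame(
    sample = sample,
    pc1_score = as.numeric(pc1_score),
    dist_vinifera = a,
    dist_wild = b,
    percent_vinifera = b / (a + b) * 100,
    out_of_interval = pc1_score < min(mv, mw) | pc1_score > max(mv, mw),
    row.names = NULL
  )
}

#' Full ancestry estimation on a curated matrix
#'
#' Runs the estimation chain on a curated, imputed, labelled matrix:
#' balance the ancestral panels, retain sites with pooled ancestral MAF
#' strictly above `ancestral_min_maf`, LD-prune, fit PCA on the panels,
#' project the hybrid samples and compute the PC1 distance-ratio ancestry
#' for each.
#'
#' @param x A labelled [geno_matrix].
#' @param n_components PCs to retain.
#' @param ancestral_min_maf Pooled ancestral MAF threshold (strict).
#' @param prune A [prune_params] object, or `NULL` to skip pruning.
#' @param seed Integer seed (panel downsampling).
#' @return A list of class `ancestry_result`: `estimates` (the
#'   [ancestry_percent()] table for hybrids), `scores` (all samples x PCs,
#'   with labels), `model`, and the post-filter `matrix`.
#' @export
estimate_all <- function(x, n_components = 2L, ancestral_min_maf = 0.10,
                         prune = prune_params(), seed = 1L) {
  stopifnot(inherits(x, "geno_matrix"))
  x <- downsample_equal(x, seed = seed)
  anc <- c(which_label(x, "wild"), which_label(x, "vinifera"))
  x <- filter_by_maf(x, ancestral_min_maf, samples = anc, strict = TRUE)
  if (!is.null(prune)) x <- x[, window_prune(x, prune)]
  model <- fit_pca(x, n_components = n_components)
  scores <- project_samples(model, x)
  # fitting samples keep their fitting scores; others their projections
  anc_idx <- match(rownames(model$ancestral_scores), x$samples)
  scores[anc_idx, ] <- model$ancestral_scores
  hyb <- which_label(x, "hybrid")
  estimates <- ancestry_percent(model, scores[hyb, 1L],
                                sample = x$samples[hyb])
  structure(list(
    estimates = estimates,
    scores = data.frame(sample = x$samples, label = x$labels, scores,
                        row.names = NULL),
    model = model,
    matrix = x
  ), class = "ancestry_result")
}

#' @export
print.ancestry_result <- function(x, ...) {
  cat(sprintf("ancestry_result: %d sites, %d hybrids estimated\n",
              n_sites(x$matrix), nrow(x$estimates)))
  if (nrow(x$estimates)) {
    cat(sprintf("  percent vinifera: min %.1f, median %.1f, max %.1f\n",
                min(x$estimates$percent_vinifera),
                stats::median(x$estimates$percent_vinifera),
                max(x$estimates$percent_vinifera)))
  }
  invisible(x)
}

#' Midparent ancestry expectation from a pedigree
#'
#' The expected percent vinifera of an offspring is the mean of its parents'
#' percentages; the result is rounded half away from zero to `digits`
#' decimals (so a midparent value of 15.5 reports as 16).
#'
#' @param parent1,parent2 Parental percent-vinifera values (0-100).
#' @param digits Decimals to keep (default 0).
#' @return Expected offspring percent vinifera.
#' @export
#' @examples
#' midparent_expectation(100, 46)  # 73
midparent_expectation <- function(parent1, parent2, digits = 0L) {
  stopifnot(parent1 >= 0, parent1 <= 100, parent2 >= 0, parent2 <= 100)
  mid <- (parent1 + parent2) / 2
  scale <- 10^digits
  sign(mid) * floor(abs(mid) * scale + 0.5) / scale
}
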