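#' Run the genotype curation chain
#'
#' Applies the curation steps in their canonical order on a labelled matrix
#' of biallelic calls: depth masking (when depth data are present), site
#' missingness, sample missingness, genome-wide MAF, heterozygote-excess
#' HWE, an IBS relatedness report, LD-kNN imputation, ancestral panel
#' balancing, the strict ancestral MAF filter and windowed LD pruning.
#' Every step logs sites/samples before and after.
#'
#' @param x A labelled [geno_matrix] (see [read_vcf()], [read_labels()]).
#' @param config A [curation_config].
#' @param impute A [imputation_params] object, or `NULL` to skip imputation.
#' @param prune A [prune_params] object, or `NULL` to skip pruning.
#' @param seed Integer seed (panel downsampling).
#' @return A list of class `curation_result`: `matrix` (curated
#'   `geno_matrix`), `log` (data frame: step, sites_before, sites_after,
#'   samples_before, samples_after) and `ibs` (IBS matrix of all samples, or
#'   `NULL` if fewer than two).
#' @export
run_curation <- function(x, config = curation_config(),
                         impute = imputation_params(),
                         prune = prune_params(), seed = 1L) {
  stopifnot(inherits(x, "geno_matrix"), inherits(config, "curation_config"))
  log <- data.frame(step = character(0), sites_before = integer(0),
                    sites_after = integer(0), samples_before = integer(0),
                    samples_after = integer(0))
  step <- function(name, f) {
    before <- c(n_sites(x), n_samples(x))
    x <<- tryCatch(f(x), error = function(e) {
      stop("curation step '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log[nrow(log) + 1L, ] <<- list(name, before[1L], n_sites(x),
                                   before[2L], n_samples(x))
    invisible(NULL)
  }
  if (!is.null(x$depth)) {
    step("depth_mask", function(m) mask_low_depth(m, config$min_depth))
  }
  step("site_missingness",
       function(m) filter_sites_by_missingness(m, config$max_site_missing))
  step("sample_missingness",
       function(m) filter_samples_by_missingness(m, config$max_sample_missing))
  step("maf", function(m) filter_by_maf(m, config$min_maf, strict = FALSE))
  step("hwe_excess_het", function(m) filter_hwe(m, config$hwe_alpha))
  ibs <- if (n_samples(x) >= 2L) ibs_matrix(x) else NULL
  if (!is.null(impute)) {
    step("impute_ldknni", function(m) impute_all(m, impute))
  }
  step("downsample_equal", function(m) downsample_equal(m, seed = seed))
  if (config$ancestral_min_maf > 0) {  # zero disables the (strict) step
    anc <- c(which_label(x, "wild"), which_label(x, "vinifera"))
    step("ancestral_maf", function(m)
      filter_by_maf(m, config$ancestral_min_maf, samples = anc, strict = TRUE))
  }
  if (!is.null(prune)) {
    step("ld_prune", function(m) m[, window_prune(m, prune)])
  }
  structure(list(matrix = x, log = log, ibs = ibs),
            class = "curation_result")
}

#' @export
print.curation_result <- function(x, ...) {
  cat("curation_result:\n")
  print(x$log, row.names = FALSE)
  invisible(x)
}

#' Ancestry estimation on a curated matrix
#'
#' Thin orchestration over [fit_pca()], [project_samples()] and
#' [ancestry_percent()] for a matrix that has already been curated (e.g. by
#' [run_curation()]), plus a histogram-ready binning of the hybrid
#' estimates. Returns an empty estimate table, with a warning, when no
#' hybrids are present.
#'
#' @param x A curated, labelled [geno_matrix] with equal ancestral panels.
#' @param n_components PCs to retain.
#' @param binwidth Width (percent) of the histogram bins.
#' @return A list of class `ancestry_report`: `estimates`, `scores`,
#'   `model`, `histogram` (data frame: bin_low, bin_high, count).
#' @export
run_ancestry <- function(x, n_components = 2L, binwidth = 5) {
  stopifnot(inherits(x, "geno_matrix"))
  model <- fit_pca(x, n_components = n_components)
  scores <- project_samples(model, x)
  anc_idx <- match(rownames(model$ancestral_scores), x$samples)
  scores[anc_idx, ] <- model$ancestral_scores
  hyb <- which_label(x, "hybrid")
  if (length(hyb) == 0L) {
    warning("no hybrid samples present; estimate table is empty",
            call. = FALSE)
  }
  estimates <- ancestry_percent(model, scores[hyb, 1L],
                                sample = x$samples[hyb])
  breaks <- seq(0, 100 + binwidth, by = binwidth)
  counts <- if (nrow(estimates)) {
    table(cut(pmin(pmax(estimates$percent_vinifera, 0), 100),
              breaks, right = FALSE, include.lowest = TRUE))
  } else {
    table(cut(numeric(0), breaks, right = FALSE))
  }
  histogram <- data.frame(bin_low = breaks[-length(breaks)],
                          bin_high = breaks[-1L],
                          count = as.integer(counts))
  structure(list(
    estimates = estimates,
    scores = data.frame(sample = x$samples, label = x$labels, scores,
                        row.names = NULL),
    model = model,
    histogram = histogram
  ), class = "ancestry_report")
}

#' Validate the estimator with simulated F1 and backcross cohorts
#'
#' Fits the PCA model on the curated ancestral panels, simulates F1,
#' F1-x-wild and F1-x-vinifera cohorts from those same panel genotypes,
#' projects every offspring and summarizes the PC1 distance-ratio estimates
#' per design (mean and empirical 95% interval). Optionally classifies
#' hybrid estimates by the cohort interval they fall in.
#'
#' @param x A curated, labelled [geno_matrix] with equal, fully observed
#'   ancestral panels.
#' @param n_offspring Offspring per design (default 10000).
#' @param seed Integer seed.
#' @param hybrid_estimates Optional numeric vector of percent-vinifera
#'   estimates to classify against the simulated intervals.
#' @return A list of class `simulation_validation`: `summary` (data frame:
#'   design, expected, n, mean, ci_low, ci_high), `estimates` (per-offspring
#'   percents by design), `model` and, when hybrid estimates were given,
#'   `classification` (design interval containing each estimate, or
#'   `"none"`).
#' @export
run_simulation_validation <- function(x, n_offspring = 10000L, seed = 1L,
                                      hybrid_estimates = NULL) {
  stopifnot(inherits(x, "geno_matrix"))
  model <- fit_pca(x)
  wild <- x$dosage[which_label(x, "wild"), , drop = FALSE]
  vin <- x$dosage[which_label(x, "vinifera"), , drop = FALSE]
  designs <- c(F1 = "F1", BC_wild = "BC_wild", BC_vinifera = "BC_vinifera")
  estimates <- lapply(seq_along(designs), function(i) {
    cohort <- simulate_cohort(wild, vin, designs[[i]],
                              n_offspring = n_offspring, seed = seed + i)
    scores <- project_samples(model, cohort$dosage)
    ancestry_percent(model, scores[, 1L])$percent_vinifera
  })
  names(estimates) <- names(designs)
  summaries <- lapply(estimates, summarize_cohort)
  summary <- data.frame(
    design = names(designs),
    expected = c(50, 25, 75),
    n = vapply(summaries, `[[`, numeric(1), "n"),
    mean = vapply(summaries, `[[`, numeric(1), "mean"),
    ci_low = vapply(summaries, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(summaries, `[[`, numeric(1), "ci_high"),
    row.names = NULL
  )
  classification <- NULL
  if (!is.null(hybrid_estimates)) {
    classification <- vapply(hybrid_estimates, function(e) {
      hit <- summary$design[e >= summary$ci_low & e <= summary$ci_high]
      if (length(hit)) hit[1L] else "none"
    }, character(1))
  }
  structure(list(summary = summary, estimates = estimates, model = model,
                 classification = classification),
            class = "simulation_validation")
}

#' @export
print.simulation_validation <- function(x, ...) {
  cat("simulation_validation:\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
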