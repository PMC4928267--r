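#' Synthetic-dataset configuration
#'
#' Describes a genotype dataset with the structure the analysis assumes: two
#' strongly diverged ancestral panels under a Balding-Nichols divergence
#' model, admixed "hybrid" samples with known vinifera fraction, optional
#' haplotype-block LD, uniform missingness and Poisson read depth. Defaults
#' emulate the curated GBS dataset shape the method targets: 7 wild + 7
#' vinifera ancestral samples, 64 hybrids spanning roughly 10-80% vinifera
#' ancestry, 2,500 biallelic sites spread over 19 chromosomes, FST 0.3.
#'
#' @param n_sites Number of biallelic sites.
#' @param n_wild,n_vinifera Ancestral panel sizes.
#' @param n_hybrids Number of admixed samples.
#' @param hybrid_alphas True vinifera fractions of the hybrids; recycled to
#'   `n_hybrids`. Default: evenly spaced on `[0.1, 0.8]`.
#' @param fst Balding-Nichols divergence between the panels, in `(0, 1)`.
#' @param base_freq_range Interval from which ancestral base frequencies are
#'   drawn uniformly.
#' @param n_blocks,haplotypes_per_block Optional LD-block structure: sites
#'   are grouped into `n_blocks` blocks and individuals draw two haplotypes
#'   per block from a finite per-population pool, inducing within-block
#'   correlation. `NULL` (default) gives independent sites.
#' @param missing_rate Fraction of cells masked to missing, uniformly.
#' @param depth_mean Mean of the Poisson per-cell read depth; `NULL` skips
#'   depth simulation.
#' @param n_chrom Number of chromosomes positions are spread over.
#' @param seed Integer seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_sites = 2500L, n_wild = 7L, n_vinifera = 7L,
                         n_hybrids = 64L, hybrid_alphas = NULL, fst = 0.3,
                         base_freq_range = c(0.1, 0.9), n_blocks = NULL,
                         haplotypes_per_block = 4L, missing_rate = 0,
                         depth_mean = NULL, n_chrom = 19L, seed = 1L) {
  stopifnot(n_sites >= 1, n_wild >= 1, n_vinifera >= 1, n_hybrids >= 0,
            fst > 0, fst < 1,
            length(base_freq_range) == 2L,
            base_freq_range[1] >= 0, base_freq_range[2] <= 1,
            base_freq_range[1] <= base_freq_range[2],
            missing_rate >= 0, missing_rate < 1, n_chrom >= 1)
  if (is.null(hybrid_alphas) && n_hybrids > 0L) {
    hybrid_alphas <- seq(0.1, 0.8, length.out = n_hybrids)
  }
  if (n_hybrids > 0L) {
    hybrid_alphas <- rep_len(hybrid_alphas, n_hybrids)
    stopifnot(all(hybrid_alphas >= 0), all(hybrid_alphas <= 1))
  }
  structure(list(
    n_sites = as.integer(n_sites), n_wild = as.integer(n_wild),
    n_vinifera = as.integer(n_vinifera), n_hybrids = as.integer(n_hybrids),
    hybrid_alphas = hybrid_alphas, fst = fst,
    base_freq_range = base_freq_range, n_blocks = n_blocks,
    haplotypes_per_block = as.integer(haplotypes_per_block),
    missing_rate = missing_rate, depth_mean = depth_mean,
    n_chrom = as.integer(n_chrom), seed = as.integer(seed)
  ), class = "synth_config")
}

#' Draw diverged per-population allele frequencies
#'
#' Balding-Nichols model: per site, a base frequency `p` is drawn uniformly
#' from `base_freq_range`; each population's frequency is then drawn from a
#' Beta distribution with mean `p` and variance `fst * p * (1 - p)`
#' (shapes `p(1-F)/F` and `(1-p)(1-F)/F`).
#'
#' @param config A [synth_config].
#' @return A list with numeric vectors `base`, `wild`, `vinifera`.
#' @export
draw_population_frequencies <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed_or_not(config$seed, {
    p <- stats::runif(config$n_sites, config$base_freq_range[1],
                      config$base_freq_range[2])
    ratio <- (1 - config$fst) / config$fst
    list(
      base = p,
      wild = stats::rbeta(config$n_sites, p * ratio, (1 - p) * ratio),
      vinifera = stats::rbeta(config$n_sites, p * ratio, (1 - p) * ratio)
    )
  })
}

#' Sample a panel of diploids from site frequencies
#'
#' Each dosage is an independent `Binomial(2, freq)` draw.
#'
#' @param freqs Per-site allele frequencies in `[0, 1]`.
#' @param n Number of individuals.
#' @return Integer dosage matrix (`n` x sites).
#' @export
sample_panel <- function(freqs, n) {
  stopifnot(all(freqs >= 0), all(freqs <= 1), n >= 1)
  matrix(stats::rbinom(n * length(freqs), 2L, rep(freqs, each = n)), nrow = n)
}

#' Sample admixed individuals with known ancestry
#'
#' Each of the two allele copies at every site independently originates from
#' the vinifera frequency with probability `alpha` and from the wild
#' frequency otherwise, giving individuals with true vinifera fraction
#' `alpha` in expectation at every site.
#'
#' @param freqs_wild,freqs_vinifera Per-site allele frequencies.
#' @param alpha True vinifera fraction in `[0, 1]`.
#' @param n Number of individuals.
#' @return A list: `dosage` (n x sites) and `truth` (data frame with column
#'   `alpha`).
#' @export
sample_admixed <- function(freqs_wild, freqs_vinifera, alpha, n) {
  stopifnot(length(freqs_wild) == length(freqs_vinifera),
            alpha >= 0, alpha <= 1, n >= 1)
  p_sites <- length(freqs_wild)
  copy_one <- admixed_copies(freqs_wild, freqs_vinifera, alpha, n)
  copy_two <- admixed_copies(freqs_wild, freqs_vinifera, alpha, n)
  list(dosage = copy_one + copy_two,
       truth = data.frame(alpha = rep(alpha, n)))
}

admixed_copies <- function(fw, fv, alpha, n) {
  p_sites <- length(fw)
  from_vin <- matrix(stats::rbinom(n * p_sites, 1L, alpha), nrow = n)
  f <- ifelse(from_vin == 1L, rep(fv, each = n), rep(fw, each = n))
  matrix(stats::rbinom(n * p_sites, 1L, f), nrow = n)
}

#' Empirical allele frequencies of a labelled panel
#'
#' Alternate-allele frequency per site over the non-missing calls of the
#' samples carrying `label`. Drawing allele copies from these frequencies is
#' the marginal equivalent of sampling alleles from the panel's gene pool,
#' as the in-silico crosses do.
#'
#' @param x A [geno_matrix].
#' @param label Panel label ("wild" or "vinifera").
#' @return Numeric vector of per-site frequencies.
#' @export
empirical_frequencies <- function(x, label) {
  stopifnot(inherits(x, "geno_matrix"))
  idx <- which_label(x, label)
  if (length(idx) == 0L) stop("no samples labelled '", label, "'",
                              call. = FALSE)
  d <- x$dosage[idx, , drop = FALSE]
  colSums(d, na.rm = TRUE) / (2 * colSums(!is.na(d)))
}

#' Generate a full synthetic dataset with ancestry truth
#'
#' Assembles wild and vinifera panels plus admixed hybrids according to a
#' [synth_config]: Balding-Nichols frequencies, optional haplotype-block LD,
#' optional uniform missingness and Poisson depth. Site positions are drawn
#' uniformly over `n_chrom` chromosomes and sorted, so distance and pruning
#' code paths are exercised. Roughly 2% of sites are emitted as short
#' indels, the rest as SNPs.
#'
#' @param config A [synth_config].
#' @return A list: `geno` (a labelled [geno_matrix]) and `truth` (data frame
#'   `sample`, `alpha`, `origin`).
#' @export
make_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  freqs <- draw_population_frequencies(config)
  with_seed_or_not(config$seed + 1L, {
    if (is.null(config$n_blocks)) {
      wild <- sample_panel(freqs$wild, config$n_wild)
      vin <- sample_panel(freqs$vinifera, config$n_vinifera)
      hyb <- NULL
      if (config$n_hybrids > 0L) {
        hyb <- do.call(rbind, lapply(config$hybrid_alphas, function(a) {
          sample_admixed(freqs$wild, freqs$vinifera, a, 1L)$dosage
        }))
      }
    } else {
      # finite haplotype pool per block and population; every individual
      # (panel or hybrid) is two pool draws per block, hybrids choosing the
      # vinifera pool with probability alpha per copy
      pools <- lapply(freqs[c("wild", "vinifera")], haplotype_pools, config)
      wild <- block_individuals(pools, rep(0, config$n_wild), config)
      vin <- block_individuals(pools, rep(1, config$n_vinifera), config)
      hyb <- if (config$n_hybrids > 0L) {
        block_individuals(pools, config$hybrid_alphas, config)
      }
    }
    alphas <- if (config$n_hybrids > 0L) config$hybrid_alphas else numeric(0)
    dosage <- rbind(wild, vin, hyb)
    samples <- c(sprintf("wild_%02d", seq_len(config$n_wild)),
                 sprintf("vinifera_%02d", seq_len(config$n_vinifera)),
                 if (config$n_hybrids > 0L)
                   sprintf("hybrid_%02d", seq_len(config$n_hybrids)))
    labels <- rep(c("wild", "vinifera", "hybrid"),
                  c(config$n_wild, config$n_vinifera, config$n_hybrids))
    sites <- synth_sites(config)
    depth <- NULL
    if (!is.null(config$depth_mean)) {
      depth <- matrix(stats::rpois(length(dosage), config$depth_mean),
                      nrow = nrow(dosage))
    }
    if (config$missing_rate > 0) {
      mask <- matrix(stats::runif(length(dosage)) < config$missing_rate,
                     nrow = nrow(dosage))
      dosage[mask] <- NA_integer_
    }
    geno <- geno_matrix(dosage, sites, samples = samples, labels = labels,
                        depth = depth)
    truth <- data.frame(
      sample = samples,
      alpha = c(rep(0, config$n_wild), rep(1, config$n_vinifera), alphas),
      origin = labels
    )
    list(geno = geno, truth = truth)
  })
}

block_assignment <- function(config) {
  sort(rep(seq_len(config$n_blocks), length.out = config$n_sites))
}

# One binary haplotype pool per block, drawn from the population frequencies.
haplotype_pools <- function(freqs, config) {
  block <- block_assignment(config)
  lapply(split(seq_along(freqs), block), function(sites_b) {
    matrix(
      stats::rbinom(config$haplotypes_per_block * length(sites_b), 1L,
                    rep(freqs[sites_b], each = config$haplotypes_per_block)),
      nrow = config$haplotypes_per_block)
  })
}

# Individuals as two pool haplotypes per block; each copy comes from the
# vinifera pool with probability alpha, inducing within-block LD for panels
# and hybrids alike.
block_individuals <- function(pools, alphas, config) {
  n <- length(alphas)
  out <- matrix(0L, nrow = n, ncol = config$n_sites)
  block <- block_assignment(config)
  for (b in seq_len(config$n_blocks)) {
    sites_b <- which(block == b)
    for (copy in 1:2) {
      from_vin <- stats::rbinom(n, 1L, alphas) == 1L
      pick <- sample.int(config$haplotypes_per_block, n, replace = TRUE)
      hap <- matrix(0L, nrow = n, ncol = length(sites_b))
      if (any(from_vin)) {
        hap[from_vin, ] <- pools$vinifera[[b]][pick[from_vin], , drop = FALSE]
      }
      if (any(!from_vin)) {
        hap[!from_vin, ] <- pools$wild[[b]][pick[!from_vin], , drop = FALSE]
      }
      out[, sites_b] <- out[, sites_b] + hap
    }
  }
  out
}

synth_sites <- function(config) {
  chrom <- sprintf("chr%02d", sort(sample.int(config$n_chrom, config$n_sites,
                                              replace = TRUE)))
  pos <- unlist(lapply(split(seq_len(config$n_sites), chrom), function(idx) {
    sort(sample.int(2e7L, length(idx)))
  }), use.names = FALSE)
  is_indel <- stats::runif(config$n_sites) < 0.02
  ref <- ifelse(is_indel, "AT", "A")
  alt <- ifelse(is_indel, "A", "G")
  data.frame(chrom = sort(chrom), pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}
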