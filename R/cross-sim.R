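#' Sample a gamete from a diploid parent
#'
#' One allele is drawn per site: dosage 0 always transmits the reference
#' allele, dosage 2 always the alternate, dosage 1 a fair coin. Sites are
#' independent (linkage between sites is ignored).
#'
#' @param parent Dosage vector (0/1/2, no missing).
#' @return Integer vector of transmitted alternate-allele counts (0/1).
#' @export
gamete <- function(parent) {
  if (anyNA(parent)) {
    stop("parent has missing dosages; impute before simulating crosses",
         call. = FALSE)
  }
  stats::rbinom(length(parent), 1L, parent / 2)
}

#' Cross two diploid parents
#'
#' Offspring dosage is the sum of one independent gamete from each parent.
#'
#' @param p1,p2 Parental dosage vectors over identical site sets.
#' @return Integer offspring dosage vector.
#' @export
cross_offspring <- function(p1, p2) {
  if (length(p1) != length(p2)) {
    stop("parents must share the same site set", call. = FALSE)
  }
  gamete(p1) + gamete(p2)
}

#' Simulate an F1 or backcross cohort
#'
#' For the `"F1"` design each offspring crosses one random wild parent with
#' one random vinifera parent. For backcross designs each offspring crosses
#' a freshly simulated F1 (new random ancestral parents) with a random
#' individual of the stated panel. Parents are drawn with replacement;
#' alleles are sampled independently per site. True expected vinifera
#' ancestry is 0.5 (F1), 0.25 (BC to wild) or 0.75 (BC to vinifera).
#'
#' @param wild,vinifera Fully observed dosage matrices (samples x sites) for
#'   the two ancestral panels, sharing the same site set.
#' @param design `"F1"`, `"BC_wild"` or `"BC_vinifera"`.
#' @param n_offspring Cohort size (default 10000).
#' @param seed Integer seed; the full cohort is reproducible from it.
#' @return A list of class `simulated_cohort`: `dosage` (offspring x sites),
#'   `parents` (data frame of parent indices), `design`,
#'   `true_expected_ancestry`.
#' @export
simulate_cohort <- function(wild, vinifera,
                            design = c("F1", "BC_wild", "BC_vinifera"),
                            n_offspring = 10000L, seed = 1L) {
  design <- match.arg(design)
  wild <- as.matrix(wild); vinifera <- as.matrix(vinifera)
  if (nrow(wild) == 0L || nrow(vinifera) == 0L) {
    stop("both ancestral panels must be non-empty", call. = FALSE)
  }
  if (ncol(wild) != ncol(vinifera)) {
    stop("panels must share the same site set", call. = FALSE)
  }
  if (anyNA(wild) || anyNA(vinifera)) {
    stop("panels must be fully observed; impute first", call. = FALSE)
  }
  stopifnot(n_offspring >= 1)
  n <- as.integer(n_offspring)
  p <- ncol(wild)
  with_seed_or_not(seed, {
    iw <- sample.int(nrow(wild), n, replace = TRUE)
    iv <- sample.int(nrow(vinifera), n, replace = TRUE)
    f1 <- gamete_matrix(wild[iw, , drop = FALSE]) +
      gamete_matrix(vinifera[iv, , drop = FALSE])
    if (design == "F1") {
      dosage <- f1
      parents <- data.frame(wild_parent = iw, vinifera_parent = iv)
      truth <- 0.5
    } else {
      panel <- if (design == "BC_wild") wild else vinifera
      ib <- sample.int(nrow(panel), n, replace = TRUE)
      dosage <- gamete_matrix(f1) + gamete_matrix(panel[ib, , drop = FALSE])
      parents <- data.frame(f1_wild_parent = iw, f1_vinifera_parent = iv,
                            backcross_parent = ib)
      truth <- if (design == "BC_wild") 0.25 else 0.75
    }
    colnames(dosage) <- colnames(wild)
    rownames(dosage) <- sprintf("%s_%06d", tolower(design), seq_len(n))
    structure(list(dosage = dosage, parents = parents, design = design,
                   true_expected_ancestry = truth),
              class = "simulated_cohort")
  })
}

# One gamete per row of a dosage matrix, drawn independently per site.
gamete_matrix <- function(parents) {
  matrix(stats::rbinom(length(parents), 1L, parents / 2),
         nrow = nrow(parents))
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf(
    "simulated_cohort: %s, %d offspring x %d sites (expected vinifera %.0f%%)\n",
    x$design, nrow(x$dosage), ncol(x$dosage),
    100 * x$true_expected_ancestry))
  invisible(x)
}

#' Summarize a cohort's ancestry estimates
#'
#' Mean percent vinifera with an empirical 95% interval: the 2.5th and
#' 97.5th percentiles of the per-offspring estimates (linear interpolation,
#' [stats::quantile()] type 7).
#'
#' @param estimates Numeric vector of percent-vinifera estimates.
#' @return A list with `mean`, `ci_low`, `ci_high`, `n`.
#' @export
summarize_cohort <- function(estimates) {
  estimates <- as.numeric(estimates)
  if (length(estimates) < 1L) stop("no estimates to summarize", call. = FALSE)
  q <- if (length(estimates) == 1L) {
    c(estimates, estimates)
  } else {
    stats::quantile(estimates, c(0.025, 0.975), names = FALSE, type = 7)
  }
  list(mean = mean(estimates), ci_low = q[1L], ci_high = q[2L],
       n = length(estimates))
}
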