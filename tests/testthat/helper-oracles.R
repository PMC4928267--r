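# Independent oracles the implementation is checked against. These stay
# deliberately naive: choose()-based enumeration for the exact HWE test, and
# a literal restart-on-removal sliding-window reimplementation of pruning.

# Exhaustive Levene-Haldane enumeration over all genotype configurations
# compatible with the observed allele counts.
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt,
                       alternative = c("excess", "two_sided")) {
  alternative <- match.arg(alternative)
  n <- n_hom_ref + n_het + n_hom_alt
  n_alt <- n_het + 2 * n_hom_alt
  cfgs <- expand.grid(n2 = 0:n, h = 0:n)
  cfgs$n0 <- n - cfgs$n2 - cfgs$h
  cfgs <- cfgs[cfgs$n0 >= 0 & (2 * cfgs$n2 + cfgs$h) == n_alt, ]
  w <- choose(n, cfgs$n0) * choose(n - cfgs$n0, cfgs$h) * 2^cfgs$h
  prob <- w / sum(w)
  p_obs <- prob[cfgs$h == n_het]
  p <- switch(alternative,
    excess = sum(prob[cfgs$h >= n_het]),
    two_sided = sum(prob[prob <= p_obs * (1 + 1e-7)])
  )
  min(1, p)
}

# Literal sliding-window pruning: within each window, scan kept pairs in
# site order and restart the window scan after every removal.
prune_oracle <- function(g, window_size = 10L, step = 3L, r2_max = 0.5) {
  n_obs <- colSums(!is.na(g$dosage))
  f_alt <- colSums(g$dosage, na.rm = TRUE) / (2 * n_obs)
  maf <- pmin(f_alt, 1 - f_alt)
  maf[n_obs == 0] <- 0
  kept <- rep(TRUE, ncol(g$dosage))
  r2_of <- function(i, j) {
    ok <- !is.na(g$dosage[, i]) & !is.na(g$dosage[, j])
    if (sum(ok) < 2) return(NA_real_)
    xi <- g$dosage[ok, i]; yj <- g$dosage[ok, j]
    if (length(unique(xi)) < 2 || length(unique(yj)) < 2) return(NA_real_)
    cor(xi, yj)^2
  }
  for (chrom in unique(g$sites$chrom)) {
    idx <- which(g$sites$chrom == chrom)
    start <- 1L
    while (start <= length(idx)) {
      win <- idx[start:min(start + window_size - 1L, length(idx))]
      repeat {
        alive <- win[kept[win]]
        removed_one <- FALSE
        if (length(alive) >= 2) {
          for (ii in seq_len(length(alive) - 1L)) {
            for (jj in seq.int(ii + 1L, length(alive))) {
              i <- alive[ii]; j <- alive[jj]
              r2 <- r2_of(i, j)
              if (!is.na(r2) && r2 > r2_max) {
                kept[if (maf[i] < maf[j]) i else j] <- FALSE
                removed_one <- TRUE
                break
              }
            }
            if (removed_one) break
          }
        }
        if (!removed_one) break
      }
      start <- start + step
    }
  }
  which(kept)
}

# Plain textbook Pearson correlation on complete pairs, squared.
pearson2_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  (num / den)^2
}
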