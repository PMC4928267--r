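make_panel_geno <- function(n_wild = 4, n_vin = 4, p = 30, fst_like = TRUE,
                            seed = 50) {
  withr::with_seed(seed, {
    fw <- runif(p, 0.05, 0.45)
    fv <- runif(p, 0.55, 0.95)
    d <- rbind(sample_panel(fw, n_wild), sample_panel(fv, n_vin))
    toy_geno(d, labels = rep(c("wild", "vinifera"), c(n_wild, n_vin)))
  })
}

test_that("panel downsampling balances the ancestral panels", {
  g <- toy_geno(matrix(rep(0:2, length.out = 32), nrow = 16, ncol = 2),
                labels = rep(c("wild", "vinifera"), c(7, 9)))
  out <- downsample_equal(g, seed = 5L)
  expect_equal(sum(out$labels == "vinifera"), 7L)
  expect_equal(sum(out$labels == "wild"), 7L)
  expect_length(attr(out, "removed"), 2L)
  expect_identical(attr(downsample_equal(g, seed = 5L), "removed"),
                   attr(out, "removed"))
  # already equal panels untouched; hybrids never removed
  eq <- toy_geno(matrix(0L, 5, 2),
                 labels = c("wild", "wild", "vinifera", "vinifera", "hybrid"))
  expect_identical(downsample_equal(eq, seed = 1L)$samples, eq$samples)
  expect_error(downsample_equal(toy_geno(matrix(0L, 2, 2)), 1L),
               "ancestral")
})

test_that("PCA separates maximally diverged panels on PC1", {
  d <- rbind(matrix(0L, 4, 20), matrix(2L, 4, 20))
  g <- toy_geno(d, labels = rep(c("wild", "vinifera"), each = 4))
  model <- fit_pca(g)
  s <- model$ancestral_scores[, 1]
  expect_gt(min(s[5:8]), max(s[1:4]))          # orientation: vinifera higher
  expect_lt(stats::var(s[1:4]), 1e-18)         # within-panel variance ~ 0
  expect_true(all(diff(model$variance_explained) <= 1e-12))
  expect_lte(sum(model$variance_explained), 1 + 1e-12)
})

test_that("fitted scores match a brute-force eigendecomposition", {
  g <- make_panel_geno(n_wild = 2, n_vin = 2, p = 3, seed = 51)
  # monomorphic sites are rejected, so keep only polymorphic ones
  keep <- site_maf(g) > 0
  g <- g[, keep]
  model <- fit_pca(g, n_components = 2)
  # independent route: eigen of the score covariance z z^T
  d <- g$dosage
  n <- nrow(d)
  csum <- colSums(d)
  p_hat <- (1 + csum) / (2 + 2 * n)
  z <- sweep(sweep(d, 2, csum / n, "-"), 2, sqrt(p_hat * (1 - p_hat)), "/")
  ev <- eigen(z %*% t(z), symmetric = TRUE)
  for (comp in 1:2) {
    expect_equal(abs(model$ancestral_scores[, comp]),
                 abs(ev$vectors[, comp] * sqrt(ev$values[comp])),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_equal(model$eigenvalues,
               ev$values[1:2] / (n - 1), tolerance = 1e-9)
})

test_that("fit_pca rejects unusable panels", {
  g <- make_panel_geno()
  gm <- g
  gm$dosage[1, 1] <- NA_integer_
  expect_error(fit_pca(gm), "missing")
  mono <- toy_geno(cbind(rep(0L, 8), rep(c(0L, 2L), 4)),
                   labels = rep(c("wild", "vinifera"), each = 4))
  expect_error(fit_pca(mono), "monomorphic")
  uneq <- make_panel_geno(n_wild = 3, n_vin = 5)
  expect_error(fit_pca(uneq), "equal-sized")
})

test_that("projection reproduces fitting scores and centres the panel mean", {
  g <- make_panel_geno(n_wild = 5, n_vin = 5, p = 40, seed = 52)
  g <- g[, site_maf(g) > 0]
  model <- fit_pca(g)
  proj <- project_samples(model, g)
  expect_equal(proj, model$ancestral_scores, tolerance = 1e-9,
               ignore_attr = TRUE)
  # panel-mean genotype projects to the origin
  mean_geno <- matrix(colMeans(g$dosage), nrow = 1)
  expect_equal(as.numeric(project_samples(model, mean_geno)), c(0, 0),
               tolerance = 1e-9)
  expect_error(project_samples(model, g$dosage[, -1, drop = FALSE]), "sites")
})

test_that("projection with missing dosages rescales by observed fraction", {
  g <- make_panel_geno(n_wild = 5, n_vin = 5, p = 60, seed = 53)
  g <- g[, site_maf(g) > 0]
  model <- fit_pca(g)
  full <- project_samples(model, g$dosage[1, , drop = FALSE])
  holey <- g$dosage[1, , drop = FALSE]
  holey[1, seq(1, ncol(holey), by = 5)] <- NA_integer_
  part <- project_samples(model, holey)
  expect_true(attr(part, "rescaled")[1])
  # unbiased-ish under random holes: same sign, similar magnitude on PC1
  expect_equal(sign(part[1, 1]), sign(full[1, 1]))
  expect_lt(abs(part[1, 1] - full[1, 1]) / abs(full[1, 1]), 0.5)
})

test_that("the PC1 distance ratio maps scores to percent vinifera", {
  g <- make_panel_geno(seed = 54)
  g <- g[, site_maf(g) > 0]
  model <- fit_pca(g)
  mw <- model$mean_wild_pc1
  mv <- model$mean_vinifera_pc1
  at <- function(t) mw + t * (mv - mw)
  est <- ancestry_percent(model, c(at(0), at(0.25), at(0.5), at(1)))
  expect_equal(est$percent_vinifera, c(0, 25, 50, 100), tolerance = 1e-12)
  expect_false(any(est$out_of_interval))
  outside <- ancestry_percent(model, at(1.2))
  expect_true(outside$out_of_interval)
  # strictly monotone within the inter-mean interval
  grid <- ancestry_percent(model, at(seq(0, 1, by = 0.05)))
  expect_true(all(diff(grid$percent_vinifera) > 0))
})

test_that("the percent estimate is invariant to the PC1 sign convention", {
  g <- make_panel_geno(seed = 55)
  g <- g[, site_maf(g) > 0]
  model <- fit_pca(g)
  flipped <- model
  flipped$loadings[, 1] <- -flipped$loadings[, 1]
  flipped$ancestral_scores[, 1] <- -flipped$ancestral_scores[, 1]
  flipped$mean_wild_pc1 <- -model$mean_wild_pc1
  flipped$mean_vinifera_pc1 <- -model$mean_vinifera_pc1
  score <- project_samples(model, g$dosage[2, , drop = FALSE])[1, 1]
  expect_equal(
    ancestry_percent(model, score)$percent_vinifera,
    ancestry_percent(flipped, -score)$percent_vinifera,
    tolerance = 1e-12
  )
})

test_that("estimate_all recovers known ancestry for synthetic hybrids", {
  ds <- panels_fixture()
  g <- ds$geno
  fw <- empirical_frequencies(g, "wild")
  fv <- empirical_frequencies(g, "vinifera")
  withr::local_seed(56)
  half <- sample_admixed(fw, fv, 0.5, 25)$dosage
  pure_vin <- sample_admixed(fw, fv, 1, 10)$dosage
  hyb <- rbind(half, pure_vin)
  rownames(hyb) <- sprintf("hyb%02d", seq_len(nrow(hyb)))
  combined <- geno_matrix(
    rbind(g$dosage, hyb), g$sites,
    samples = c(g$samples, rownames(hyb)),
    labels = c(g$labels, rep("hybrid", nrow(hyb)))
  )
  res <- estimate_all(combined, seed = 57L)
  est <- res$estimates
  expect_lt(abs(mean(est$percent_vinifera[1:25]) - 50), 2)
  expect_true(all(est$percent_vinifera[26:35] > 90))
  # hybrid input order does not change per-sample estimates
  perm <- c(seq_len(14), 14 + sample(35))
  res_perm <- estimate_all(combined[perm, ], seed = 57L)
  est_perm <- res_perm$estimates[match(est$sample,
                                       res_perm$estimates$sample), ]
  expect_equal(est_perm$percent_vinifera, est$percent_vinifera,
               tolerance = 1e-9)
})

test_that("midparent expectations round half away from zero", {
  expect_identical(midparent_expectation(100, 46), 73)
  expect_identical(midparent_expectation(0, 31), 16)
  expect_identical(midparent_expectation(62, 100), 81)
  expect_identical(midparent_expectation(0, 31, digits = 1), 15.5)
})
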