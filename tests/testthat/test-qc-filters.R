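test_that("depth masking keeps calls at exactly the threshold", {
  d <- matrix(1L, nrow = 2, ncol = 3)
  depth <- rbind(c(7L, 8L, 30L), c(3L, 3L, 3L))
  g <- toy_geno(d, depth = depth)
  m <- mask_low_depth(g, 8L)
  expect_equal(m$dosage[1, ], c(NA_integer_, 1L, 1L), ignore_attr = TRUE)
  expect_true(all(is.na(m$dosage[2, ])))
  expect_identical(mask_low_depth(g, 0L)$dosage, g$dosage)
  expect_error(mask_low_depth(toy_geno(d), 8L), "no depth")
})

test_that("site missingness filter is strict at the boundary", {
  d <- matrix(0:2, nrow = 10, ncol = 3)
  d[1:2, 1] <- NA  # exactly 0.20 -> dropped
  d[1, 2] <- NA    # 0.10 -> kept
  g <- toy_geno(d)
  kept <- filter_sites_by_missingness(g, 0.20)
  expect_equal(kept$sites$pos, c(200L, 300L))
  expect_equal(n_sites(filter_sites_by_missingness(g, 1.0)), 3L)
})

test_that("sample missingness filter keeps samples at the boundary", {
  d <- matrix(0L, nrow = 3, ncol = 10)
  d[2, 1:2] <- NA  # exactly 0.20 -> kept
  d[3, 1:3] <- NA  # 0.30 -> removed
  g <- toy_geno(d)
  kept <- filter_samples_by_missingness(g, 0.20)
  expect_equal(kept$samples, c("s01", "s02"))
  expect_equal(n_sites(kept), 10L)
  full <- toy_geno(matrix(1L, 4, 5))
  expect_identical(filter_samples_by_missingness(full, 0.2)$dosage,
                   full$dosage)
  all_na <- toy_geno(matrix(NA_integer_, 2, 4))
  expect_error(filter_samples_by_missingness(all_na, 0.2), "all samples")
})

test_that("site_maf counts alleles over non-missing calls", {
  g <- toy_geno(cbind(c(0L, 1L, 2L, NA),
                      c(2L, 2L, 2L, 1L),
                      c(0L, NA, 0L, NA),
                      c(NA, NA, NA, NA)))
  maf <- site_maf(g)
  expect_equal(unname(maf), c(0.5, 0.125, 0, NA))
  # restricted to a subset
  expect_equal(unname(site_maf(g, samples = c("s01", "s02"))[1]), 0.25)
  expect_error(site_maf(g, samples = "nope"), "unknown sample")
})

test_that("site_maf always lies in [0, 0.5]", {
  withr::local_seed(1)
  for (rep in 1:20) {
    maf <- site_maf(random_geno(n = 8, p = 30, missing_rate = 0.3))
    expect_true(all(maf >= 0 & maf <= 0.5, na.rm = TRUE))
  }
})

test_that("MAF filter boundaries follow strict/non-strict semantics", {
  # site 1: MAF exactly 0.05 (1 alt copy in 10 samples)
  s1 <- c(1L, rep(0L, 9))
  # site 2: MAF exactly 0.10 (2 alt copies in 10 samples)
  s2 <- c(1L, 1L, rep(0L, 8))
  g <- toy_geno(cbind(s1, s2))
  expect_equal(filter_by_maf(g, 0.05, strict = FALSE)$sites$pos,
               c(100L, 200L))
  expect_equal(filter_by_maf(g, 0.10, strict = TRUE)$sites$pos, integer(0))
  expect_equal(n_sites(filter_by_maf(g, 0, strict = FALSE)), 2L)
})

test_that("heterozygote-excess exact p-values match hand-derivable cases", {
  # no heterozygotes: P(h >= 0) = 1 exactly
  expect_identical(hwe_het_excess_pvalue(hwe_counts(4, 0, 3)), 1)
  # n = 2, counts (0,2,0): allele counts 2/2, h in {0,2} with weights 2 and 4
  expect_equal(hwe_het_excess_pvalue(hwe_counts(0, 2, 0)), 2 / 3,
               tolerance = 1e-12)
  # n = 14 ancestral-panel-sized case against exhaustive enumeration
  expect_equal(hwe_het_excess_pvalue(hwe_counts(5, 9, 0)),
               hwe_oracle(5, 9, 0), tolerance = 1e-12)
  expect_error(hwe_counts(-1, 2, 0), ">= 0")
})

test_that("Levene-Haldane distribution is normalized and matches the oracle", {
  for (n in c(3L, 8L, 14L)) {
    for (n_alt in 0:(2 * n)) {
      dist <- grapeAncestry:::hwe_het_distribution(n, n_alt)
      expect_equal(sum(dist$prob), 1, tolerance = 1e-12)
      for (h in dist$h) {
        n2 <- (n_alt - h) / 2
        n0 <- n - h - n2
        expect_equal(
          hwe_het_excess_pvalue(hwe_counts(n0, h, n2)),
          hwe_oracle(n0, h, n2), tolerance = 1e-10
        )
        expect_equal(
          hwe_het_excess_pvalue(hwe_counts(n0, h, n2), "two_sided"),
          hwe_oracle(n0, h, n2, "two_sided"), tolerance = 1e-10
        )
      }
    }
  }
})

test_that("HWE filter removes heterozygote-excess sites and keeps the rest", {
  all_het <- matrix(1L, nrow = 20, ncol = 1)
  mono <- matrix(0L, nrow = 20, ncol = 1)
  balanced <- matrix(rep(c(0L, 1L, 2L), c(5, 10, 5)), ncol = 1)
  g <- toy_geno(cbind(all_het, mono, balanced))
  kept <- filter_hwe(g, alpha = 0.001)
  expect_equal(kept$sites$pos, c(200L, 300L))
  expect_equal(n_sites(filter_hwe(g, alpha = 1e-300)), 3L)
})

test_that("curation filters are idempotent", {
  withr::local_seed(7)
  g <- random_geno(n = 12, p = 40, missing_rate = 0.25)
  once <- filter_sites_by_missingness(g, 0.2)
  expect_identical(filter_sites_by_missingness(once, 0.2)$dosage, once$dosage)
  once <- filter_samples_by_missingness(g, 0.3)
  expect_identical(filter_samples_by_missingness(once, 0.3)$dosage,
                   once$dosage)
  once <- filter_by_maf(g, 0.1)
  expect_identical(filter_by_maf(once, 0.1)$dosage, once$dosage)
  once <- filter_hwe(g, 0.01)
  expect_identical(filter_hwe(once, 0.01)$dosage, once$dosage)
})
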