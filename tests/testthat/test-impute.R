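test_that("top_ld_sites ranks by squared dosage correlation", {
  withr::local_seed(30)
  target <- rbinom(30, 2, 0.5)
  noisy <- function(x, rate) {
    flip <- rbinom(length(x), 1, rate) == 1
    ifelse(flip, sample(0:2, length(x), replace = TRUE), x)
  }
  d <- cbind(target, target, noisy(target, 0.2), noisy(target, 0.5),
             rbinom(30, 2, 0.5), rbinom(30, 2, 0.5))
  g <- toy_geno(d)
  # exact duplicate ranks first
  expect_equal(top_ld_sites(g, 1, l = 1), 2L)
  # order matches an independent r2 ranking
  r2 <- vapply(2:6, function(j) dosage_r2(d[, 1], d[, j]), numeric(1))
  expect_equal(top_ld_sites(g, 1, l = 5), (2:6)[order(-r2)])
  # l larger than available sites returns all others
  expect_length(top_ld_sites(g, 1, l = 50), 5)
})

test_that("impute_cell votes by inverse squared distance", {
  # unanimous neighbours
  d <- rbind(c(NA, 1L, 1L), c(1L, 1L, 1L), c(1L, 1L, 1L), c(1L, 1L, 1L))
  g <- toy_geno(d)
  expect_equal(impute_cell(g, 1, 1, imputation_params(l = 2, k = 3)), 1L)
  # k = 1 copies the single nearest neighbour
  d2 <- rbind(c(NA, 0L, 0L, 0L),  # target, identical to sample 2 at LD sites
              c(2L, 0L, 0L, 0L),
              c(0L, 2L, 2L, 2L))
  g2 <- toy_geno(d2)
  expect_equal(impute_cell(g2, 1, 1, imputation_params(l = 3, k = 1)), 2L)
  # a single near-identical neighbour outweighs many distant ones:
  # weight 1/eps^2 dominates any finite number of 1/d^2 votes
  eps <- 1e-9
  d3 <- rbind(c(NA, 2L, 2L, 2L),                         # target
              c(2L, 2L, 2L, 2L),                         # distance eps
              matrix(0L, nrow = 10, ncol = 4))           # distance 2
  g3 <- toy_geno(d3)
  params <- imputation_params(l = 3, k = 11, epsilon = eps)
  w_near <- 1 / eps^2
  w_far <- 10 * (1 / 2^2)
  expect_true(w_near > w_far)
  expect_equal(impute_cell(g3, 1, 1, params), 2L)
  expect_error(impute_cell(g3, 2, 1, params), "not missing")
})

test_that("impute_all fills from original values only and never edits calls", {
  withr::local_seed(31)
  full <- random_geno(n = 10, p = 25, missing_rate = 0)
  expect_identical(impute_all(full)$dosage, full$dosage)
  # duplicated sample: the duplicate's genotype is recovered
  d <- matrix(rbinom(8 * 20, 2, 0.5), nrow = 8)
  d <- rbind(d, d[1, ])
  d_missing <- d
  d_missing[1, 5] <- NA
  g <- toy_geno(d_missing)
  out <- impute_all(g, imputation_params(l = 4, k = 1))
  expect_equal(out$dosage[1, 5], d[1, 5], ignore_attr = TRUE)
  # non-missing cells untouched; output restricted to valid dosages
  obs <- !is.na(g$dosage)
  expect_identical(out$dosage[obs], g$dosage[obs])
  expect_true(all(out$dosage %in% c(0L, 1L, 2L, NA)))
})

test_that("imputation accuracy is seeded, order-invariant and beats the mode
           baseline on haplotype-block data", {
  cfg <- synth_config(n_sites = 400L, n_hybrids = 30L, n_blocks = 20L,
                      haplotypes_per_block = 4L, seed = 32L)
  g <- make_dataset(cfg)$geno
  n_mask <- 400L
  a1 <- estimate_accuracy(g, n_mask = n_mask, seed = 9L)
  expect_identical(a1, estimate_accuracy(g, n_mask = n_mask, seed = 9L))
  mode_acc <- estimate_accuracy(g, n_mask = n_mask, seed = 9L,
                                method = "mode")
  expect_gte(a1, mode_acc + 0.02)
  # imputation commutes with sample reordering (for a fixed masked set)
  withr::local_seed(35)
  gm <- g
  gm$dosage[matrix(runif(length(gm$dosage)) < 0.03, nrow = nrow(gm$dosage))] <-
    NA_integer_
  perm <- sample(n_samples(gm))
  params_all <- imputation_params(k = n_samples(gm))  # every candidate votes
  out_perm <- impute_all(gm[perm, ], params_all)
  out_orig <- impute_all(gm, params_all)[perm, ]
  expect_identical(out_perm$dosage, out_orig$dosage)
  expect_error(estimate_accuracy(g, n_mask = 0), "positive")
})

test_that("replicated-sample matrices impute perfectly", {
  withr::local_seed(33)
  d <- matrix(rbinom(6 * 100, 2, 0.5), nrow = 6)
  g <- toy_geno(rbind(d, d, d))  # an intact replicate survives any mask
  expect_equal(estimate_accuracy(g, imputation_params(k = 1),
                                 n_mask = 50, seed = 2), 1)
})

test_that("parameter grid search returns the evaluated argmax", {
  cfg <- synth_config(n_sites = 200L, n_hybrids = 10L, n_blocks = 10L,
                      haplotypes_per_block = 4L, seed = 34L)
  g <- make_dataset(cfg)$geno
  single <- optimize_parameters(g, l_grid = 4L, k_grid = 5L,
                                n_mask = 100L, seed = 3L)
  expect_equal(c(single$l, single$k), c(4L, 5L))
  res <- optimize_parameters(g, l_grid = c(1L, 6L), k_grid = c(1L, 17L),
                             n_mask = 100L, seed = 3L)
  expect_equal(res$accuracy, max(res$grid$accuracy))
  best <- res$grid[which.max(res$grid$accuracy), ]
  expect_equal(res$accuracy,
               estimate_accuracy(g, imputation_params(best$l, best$k),
                                 n_mask = 100L, seed = 3L))
  res2 <- optimize_parameters(g, l_grid = c(1L, 6L), k_grid = c(1L, 17L),
                              n_mask = 100L, seed = 3L)
  expect_identical(res[c("l", "k", "accuracy")], res2[c("l", "k", "accuracy")])
})
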