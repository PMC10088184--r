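test_that("simulated genotypes follow Hardy-Weinberg proportions", {
  n <- 20000
  for (q in c(0.5, 0.2)) {
    X <- simulate_hwe_genotypes(n, 2, maf = q, seed = 60)
    expected <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    freq <- tabulate(X[, 1] + 1L, 3) / n
    se <- sqrt(expected * (1 - expected) / n)
    expect_true(all(abs(freq - expected) < 3 * se + 1e-9))
  }
  expect_identical(simulate_hwe_genotypes(100, 3, 0.3, seed = 1),
                   simulate_hwe_genotypes(100, 3, 0.3, seed = 1))
  expect_error(simulate_hwe_genotypes(100, 3, maf = 0.6, seed = 1))
})

test_that("additive phenotypes hit their calibrated variance explained", {
  X <- simulate_hwe_genotypes(2000, 6, 0.4, seed = 61)
  betas <- c(1, -0.5, 0.25, 0.8, 0, 0)
  y0 <- simulate_additive_phenotype(X, betas, 0, seed = 62)
  expect_equal(baseline_lr_r2(X, y0), 1.0)
  sd <- calibrate_noise_sd(X, betas, 0.10)
  r2 <- vapply(1:10, function(s) {
    baseline_lr_r2(X, simulate_additive_phenotype(X, betas, sd, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(r2) - 0.10), 0.02)
})

test_that("the XOR table is pure epistasis: 0.5 marginals, no single-locus effect", {
  expect_equal(xor_penetrance(1, 1), 0L)
  expect_equal(xor_penetrance(0, 1), 1L)
  expect_equal(xor_penetrance(2, 1), 1L)
  expect_equal(xor_penetrance(0, 2), 0L)
  expect_equal(unname(marginal_penetrance(xor_penetrance_table(), q = 0.5)),
               rep(0.5, 6))
  expect_error(xor_penetrance(3, 0), "0, 1 or 2")
})

test_that("XOR injection matches penetrance-1 combos to top phenotype ranks", {
  X <- simulate_hwe_genotypes(1000, 4, 0.5, seed = 63)
  y <- withr::with_seed(64, rnorm(1000))
  Xi <- inject_xor_pair(X, y, c(1, 2), seed = 65)
  # per-column genotype multisets preserved bit-exactly
  for (j in 1:4) expect_identical(sort(unname(Xi[, j])), sort(unname(X[, j])))
  pen <- xor_penetrance(Xi[, 1], Xi[, 2])
  k1 <- sum(pen)
  top <- order(-y, seq_along(y))[seq_len(k1)]
  expect_true(all(pen[top] == 1))
  expect_error(inject_xor_pair(X, y, c(1, 1), seed = 1))
})

test_that("an injected pair is invisible to marginal tests but visible to forests", {
  X <- simulate_hwe_genotypes(2000, 2, 0.5, seed = 66)
  y <- withr::with_seed(67, rnorm(2000))
  Xi <- inject_xor_pair(X, y, c(1, 2), seed = 68)
  expect_lt(max(abs(cor(Xi, y))), 0.06)        # no marginal effect
  expect_lt(baseline_lr_r2(Xi, y), 0.01)
  expect_gt(pair_rf_r2(Xi, y, split_data(2000, 69), seed = 69), 0.02)
})

test_that("partial shuffling degrades the signal monotonically to zero", {
  X <- simulate_hwe_genotypes(1500, 2, 0.5, seed = 70)
  y <- withr::with_seed(71, rnorm(1500))
  Xi <- inject_xor_pair(X, y, c(1, 2), seed = 72)
  expect_identical(shuffle_fraction(Xi, c(1, 2), 0, seed = 1), Xi)
  split <- split_data(1500, 7)
  mean_r2 <- vapply(c(0, 0.5, 1), function(f) {
    mean(vapply(1:3, function(s) {
      Xs <- shuffle_fraction(Xi, c(1, 2), f, seed = s)
      expect_identical(sort(unname(Xs[, 1])), sort(unname(Xi[, 1])))
      pair_rf_r2(Xs, y, split, seed = 1)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_r2) < 0))
  expect_lt(abs(mean_r2[3]), 0.05)             # fully shuffled: signal destroyed
})

test_that("column permutation preserves counts and kills association", {
  X <- simulate_hwe_genotypes(500, 10, 0.3, seed = 73)
  y <- as.vector(X %*% rep(0.5, 10)) + withr::with_seed(74, rnorm(500))
  Xp <- X
  for (j in 1:10) Xp <- permute_column(Xp, j, seed = 75 + j)
  for (j in 1:10) expect_identical(sort(unname(Xp[, j])), sort(unname(X[, j])))
  expect_identical(permute_column(X, 3, seed = 9), permute_column(X, 3, seed = 9))
  r2 <- baseline_lr_r2(Xp, y)
  m <- ncol(X); n <- nrow(X)
  expect_lt(r2, 3 * m / (n - 1))               # fitting noise only
})

test_that("calibration reaches the target detectable R2 or reports the ceiling", {
  sim <- simulate_xor_dataset(1000, 8, 0.5, target_r2 = 0.10, seed = 76)
  expect_lt(abs(sim$achieved_r2 - 0.10), 0.011)
  expect_identical(sort(unlist(sim$pairs)), 1:8)   # disjoint, all loci used
  X <- simulate_hwe_genotypes(1000, 4, 0.5, seed = 77)
  y <- withr::with_seed(78, rnorm(1000))
  Xi <- inject_xor_pair(X, y, c(1, 2), seed = 79)
  expect_error(calibrate_to_target_r2(Xi, y, list(c(1, 2)), target_r2 = 0.9,
                                      seed = 80),
               "ceiling")
})

test_that("interaction ladders use disjoint pairs and both replacement modes", {
  X <- simulate_hwe_genotypes(400, 18, 0.5, seed = 81)
  y <- as.vector(X %*% withr::with_seed(82, rnorm(18, 0, 0.3))) +
    withr::with_seed(83, rnorm(400))
  lad0 <- build_interaction_ladder(X, y, 0, mode = "replace_noise", seed = 84)
  expect_length(lad0$datasets, 1)
  lad <- build_interaction_ladder(X, y, 9, mode = "replace_main_effects", seed = 85)
  expect_length(lad$datasets, 10)
  expect_identical(sort(unlist(lad$pairs)), 1:18)  # every locus in exactly one pair
  for (d in lad$datasets) {
    for (j in 1:18) expect_identical(sort(unname(d[, j])), sort(unname(X[, j])))
  }
  expect_error(build_interaction_ladder(X, y, 10, seed = 86), "2k")
  # replace_noise starts from a fully permuted base
  ladn <- build_interaction_ladder(X, y, 1, mode = "replace_noise", seed = 87)
  expect_lt(baseline_lr_r2(ladn$datasets[[1]], y), 3 * 18 / 399)
})
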