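test_that("linear Shapley values are exact: local accuracy and relevance", {
  X <- random_genotypes(200, 2, seed = 40)
  y <- 2 * X[, 1] + withr::with_seed(41, rnorm(200, 0, 0.01))
  split <- split_data(200, 1)
  pipe <- qtl_pipeline(root = regressor_spec("LR"))
  det <- pipeline_shapley(pipe, X, y, split, detail = TRUE)
  expect_gt(det$scores[["locus1"]], 0.5)
  expect_lt(det$scores[["locus2"]], 0.05)
  # efficiency axiom, exact for the closed form
  expect_lt(max(abs(rowSums(det$phi) - (det$predictions - det$baseline))), 1e-6)
})

test_that("loci removed by a selector score exactly zero", {
  p <- exact_correlation_pair(100, 0.8, seed = 42)
  X <- cbind(strong = round(2 * stats::plogis(p$x)), weak = random_genotypes(100, 1, seed = 43)[, 1])
  storage.mode(X) <- "integer"
  X[X > 2] <- 2L
  split <- split_data(100, 2)
  pipe <- qtl_pipeline(list(list(class = "selector", kind = "SP", value = 50)),
                       regressor_spec("LR"))
  sc <- pipeline_shapley(pipe, X, p$y, split)
  expect_equal(sum(sc == 0), 1)              # exactly one locus masked out
  ex <- execute_pipeline(pipe, X[split$train, ], X[split$test, ], p$y[split$train])
  expect_identical(unname(sc[!ex$keep]), 0)
})

test_that("sampling Shapley telescopes to exact local accuracy and symmetry", {
  withr::with_seed(44, {
    Xbg <- matrix(rnorm(100), 50, 2)
    Xev <- matrix(rnorm(20), 10, 2)
  })
  f <- function(M) M[, 1] + M[, 2]           # symmetric in its two inputs
  sh <- shapley_sampling(f, Xbg, Xev, n_perm = 64, seed = 3)
  expect_lt(max(abs(rowSums(sh$phi) - (f(Xev) - sh$baseline))), 1e-10)
  expect_lt(max(abs(sh$phi[, 1] - (Xev[, 1] - mean(Xbg[, 1])))), 0.2)
  # duplicated evaluation columns with a symmetric model: equal scores
  Xd <- cbind(Xev[, 1], Xev[, 1])
  Bd <- cbind(Xbg[, 1], Xbg[, 1])
  shd <- shapley_sampling(function(M) M[, 1] + M[, 2], Bd, Xd,
                          n_perm = 200, seed = 4)
  expect_lt(mean(abs(shd$phi[, 1] - shd$phi[, 2])) / mean(abs(shd$phi)), 0.15)
})

test_that("a feature the tree never uses is a null player", {
  X <- random_genotypes(300, 2, seed = 45)
  y <- as.numeric(X[, 1] >= 1) + withr::with_seed(46, rnorm(300, 0, 0.05))
  split <- split_data(300, 3)
  pipe <- qtl_pipeline(root = regressor_spec("DT", max_depth = 1,
                                             min_samples_leaf = 5,
                                             min_samples_split = 10))
  sc <- pipeline_shapley(pipe, X, y, split, seed = 5)
  expect_gt(sc[["locus1"]], 0.1)
  expect_equal(sc[["locus2"]], 0)            # never split on: contributions all zero
})

test_that("single-feature models attribute the full deviation from baseline", {
  X <- random_genotypes(150, 1, seed = 47)
  y <- 1.5 * X[, 1] + withr::with_seed(48, rnorm(150, 0, 0.2))
  split <- split_data(150, 4)
  det <- pipeline_shapley(qtl_pipeline(), X, y, split, detail = TRUE)
  expect_equal(as.vector(det$phi), det$predictions - det$baseline)
})

test_that("interaction partners in an XOR pair earn similar importance", {
  X <- simulate_hwe_genotypes(600, 4, maf = 0.5, seed = 49)
  y <- withr::with_seed(50, rnorm(600))
  X <- inject_xor_pair(X, y, c(1, 2), seed = 51)
  split <- split_data(600, 5)
  pipe <- qtl_pipeline(list(list(class = "encoder", name = "heterosis")),
                       regressor_spec("RF", bootstrap = TRUE, max_features = 0.5,
                                      min_samples_leaf = 5, min_samples_split = 10))
  sc <- pipeline_shapley(pipe, X, y, split, seed = 6, n_perm = 24)
  pairm <- mean(sc[c("locus1", "locus2")])
  expect_gt(pairm, mean(sc[c("locus3", "locus4")]))   # the pair carries the signal
  expect_lt(abs(sc[["locus1"]] - sc[["locus2"]]) / pairm, 0.5)
})

test_that("importance aggregates with SEM across pipelines and deltas compare pairs", {
  sim <- simulate_qtl_dataset(150, 4, seed = 52)
  fit <- autoqtl(sim$genotypes, sim$phenotype, population_size = 8,
                 offspring_size = 8, generations = 1, seed = 6)
  imp <- qtl_importance(fit)
  expect_setequal(imp$locus, colnames(sim$genotypes))
  expect_true(all(imp$sem >= 0))
  expect_equal(imp$rank, seq_len(nrow(imp)))
  S <- attr(imp, "scores")
  expect_equal(dim(S), c(4L, length(fit$archive)))
  d <- importance_delta(imp, imp, list(c("locus1", "locus2")))
  expect_equal(d$delta_before, d$delta_after)
  bad <- imp; bad$locus[1] <- "other"
  expect_error(importance_delta(imp, bad, list(c("locus1", "locus2"))),
               "different locus sets")
})
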