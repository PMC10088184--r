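# Small in-code fixtures shared across test files.

tiny_dataset <- function() {
  X <- matrix(c(0L, 1L, 2L,
                2L, 1L, 0L), nrow = 3,
              dimnames = list(c("s1", "s2", "s3"), c("locusA", "locusB")))
  list(genotypes = X, phenotype = c(0.1, -0.2, 0.3))
}

# deterministic genotype matrix without HWE structure, for operator tests
random_genotypes <- function(n, m, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  })
  colnames(X) <- paste0("locus", seq_len(m))
  X
}

# forest probe for a bare locus pair: every tree must see both loci, so no
# per-tree feature subsampling (the packaged reference probe subsamples and is
# meant for full panels)
pair_rf_r2 <- function(X, y, split, seed = 1) {
  spec <- regressor_spec("RF", bootstrap = TRUE, max_features = 1,
                         min_samples_leaf = 5, min_samples_split = 10)
  fit <- fit_regressor(spec, X[split$train, , drop = FALSE],
                       y[split$train], seed = seed)
  r2_score(y[split$test],
           predict_regressor(fit, X[split$test, , drop = FALSE]))
}

# two standardized vectors with *exact* sample correlation rho
exact_correlation_pair <- function(n, rho, seed = 1) {
  withr::with_seed(seed, {
    z <- qr.Q(qr(cbind(rep(1, n), stats::rnorm(n), stats::rnorm(n))))[, 2:3]
  })
  # z columns are orthonormal and orthogonal to the constant: exact zero
  # means and exact zero correlation, so cor(x, y) = rho exactly
  x <- z[, 1] / stats::sd(z[, 1])
  e <- z[, 2] / stats::sd(z[, 2])
  y <- rho * x + sqrt(1 - rho^2) * e
  list(x = x, y = y)
}
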