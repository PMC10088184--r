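#' Simulate Hardy-Weinberg genotypes
#'
#' Each locus is drawn i.i.d. with genotype probabilities
#' `((1-q)^2, 2q(1-q), q^2)` for codes (0, 1, 2), `q` the minor allele
#' frequency.
#'
#' @param n_samples number of samples (>= 10).
#' @param n_loci number of loci.
#' @param maf minor allele frequency in (0, 0.5]; scalar or per-locus vector.
#' @param seed integer seed.
#' @return integer matrix with locus names `locus1..locusM`.
#' @export
simulate_hwe_genotypes <- function(n_samples, n_loci, maf = 0.5, seed = 1L) {
  stopifnot(n_samples >= 10, all(maf > 0), all(maf <= 0.5))
  maf <- rep_len(maf, n_loci)
  withr::with_seed(as.integer(seed), {
    X <- vapply(seq_len(n_loci), function(j) {
      q <- maf[j]
      sample(0:2, n_samples, replace = TRUE,
             prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
    }, integer(n_samples))
  })
  colnames(X) <- paste0("locus", seq_len(n_loci))
  rownames(X) <- as.character(seq_len(n_samples))
  X
}

#' Simulate an additive phenotype
#'
#' `y = X beta + N(0, noise_sd)` under the additive 0/1/2 coding.
#'
#' @param genotypes samples x loci matrix.
#' @param betas per-locus additive effect sizes.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed.
#' @export
simulate_additive_phenotype <- function(genotypes, betas, noise_sd, seed = 1L) {
  stopifnot(length(betas) == ncol(genotypes))
  withr::with_seed(as.integer(seed),
    as.vector(genotypes %*% betas) + stats::rnorm(nrow(genotypes), 0, noise_sd))
}

#' Noise level for a target full-data heritability
#'
#' Chooses the Gaussian noise standard deviation so that the expected
#' full-data R squared of the additive model is approximately `target_r2`:
#' `sd = sqrt(var(X beta) (1 - t) / t)`.
#'
#' @param genotypes samples x loci matrix.
#' @param betas per-locus effects.
#' @param target_r2 target proportion of variance explained.
#' @export
calibrate_noise_sd <- function(genotypes, betas, target_r2) {
  stopifnot(target_r2 > 0, target_r2 < 1)
  g <- as.vector(genotypes %*% betas)
  sqrt(stats::var(g) * (1 - target_r2) / target_r2)
}

#' Simulate a complete additive genotype/phenotype dataset
#'
#' Convenience wrapper emulating a main-effects-only QTL panel: HWE
#' genotypes, per-locus effect sizes, and noise calibrated so the full-data
#' multiple-regression R squared is approximately `target_r2`.
#'
#' @param n_samples,n_loci,maf,seed as in [simulate_hwe_genotypes()].
#' @param betas per-locus effects; default standard-normal draws (seeded).
#' @param target_r2 target full-data variance explained (default 0.10, a
#'   typical total for a small panel of genome-wide-significant QTL).
#' @return list with `genotypes`, `phenotype`, `betas`, `noise_sd`.
#' @export
simulate_qtl_dataset <- function(n_samples = 1000L, n_loci = 18L, maf = 0.5,
                                 target_r2 = 0.10, betas = NULL, seed = 1L) {
  X <- simulate_hwe_genotypes(n_samples, n_loci, maf, seed)
  if (is.null(betas))
    betas <- withr::with_seed(as.integer(seed) + 1L, stats::rnorm(n_loci))
  sd <- calibrate_noise_sd(X, betas, target_r2)
  y <- simulate_additive_phenotype(X, betas, sd, seed = as.integer(seed) + 2L)
  list(genotypes = X, phenotype = y, betas = betas, noise_sd = sd)
}

#' XOR two-locus penetrance
#'
#' Penetrance 1 iff exactly one of the two loci is heterozygous — the
#' non-linearly-separable pure-epistasis table whose HWE-weighted marginal
#' penetrance is 0.5 for every single-locus genotype at allele frequency
#' 0.5, so the interaction carries no marginal single-locus effect.
#'
#' @param g_a,g_b genotype codes in \{0,1,2\} (vectorized).
#' @return 0/1 penetrance values.
#' @export
xor_penetrance <- function(g_a, g_b) {
  if (any(!g_a %in% 0:2) || any(!g_b %in% 0:2))
    stop("genotype codes must be 0, 1 or 2")
  as.integer((g_a == 1L) + (g_b == 1L) == 1L)
}

#' The 3x3 XOR penetrance table
#' @return integer matrix indexed by (genotype A, genotype B) in 0..2.
#' @export
xor_penetrance_table <- function() {
  outer(0:2, 0:2, xor_penetrance)
}

#' HWE-weighted marginal penetrance of a two-locus table
#'
#' For each single-locus genotype of each locus, the penetrance marginalized
#' over the partner locus with Hardy-Weinberg genotype weights at the given
#' allele frequency.
#'
#' @param table 3x3 penetrance matrix.
#' @param q allele frequency (default 0.5).
#' @return named numeric vector of the six marginals (A0..A2, B0..B2).
#' @export
marginal_penetrance <- function(table = xor_penetrance_table(), q = 0.5) {
  w <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  out <- c(as.vector(table %*% w), as.vector(t(table) %*% w))
  names(out) <- c(paste0("A", 0:2), paste0("B", 0:2))
  out
}

pair_label <- function(genotypes, pair) {
  if (is.character(pair)) pair <- match(pair, colnames(genotypes))
  stopifnot(length(pair) == 2, !anyNA(pair), pair[1] != pair[2])
  as.integer(pair)
}

#' Inject a pure XOR interaction into a locus pair
#'
#' Jointly permutes the rows of the pair's two columns so that two-locus
#' genotype combinations with XOR penetrance 1 occupy the highest phenotype
#' ranks (the "top 50%" of phenotypic scores, as many combinations as exist)
#' and penetrance-0 combinations the remaining ranks. The multiset of
#' two-locus combinations — hence every genotype and allele frequency — is
#' preserved exactly, while the pair acquires the strongest possible XOR
#' association with the phenotype and no marginal single-locus effect.
#' Phenotype ties are broken by sample index.
#'
#' @param genotypes samples x loci matrix.
#' @param phenotype numeric phenotype vector.
#' @param pair two locus indices or names.
#' @param seed integer seed (orders combinations within the high/low blocks).
#' @return the modified genotype matrix.
#' @export
inject_xor_pair <- function(genotypes, phenotype, pair, seed = 1L) {
  pair <- pair_label(genotypes, pair)
  combos <- genotypes[, pair, drop = FALSE]
  pen <- xor_penetrance(combos[, 1], combos[, 2])
  rank_desc <- order(-phenotype, seq_along(phenotype))
  withr::with_seed(as.integer(seed), {
    hi <- sample(which(pen == 1L))
    lo <- sample(which(pen == 0L))
  })
  genotypes[rank_desc, pair] <- combos[c(hi, lo), , drop = FALSE]
  genotypes
}

#' Partially shuffle an injected interaction
#'
#' Re-permutes the pair's two-locus genotype combinations uniformly among a
#' random `fraction` of the rows, weakening the XOR association with the
#' phenotype while preserving the combination multiset (and therefore all
#' genotype and allele frequencies) exactly.
#'
#' @param genotypes samples x loci matrix.
#' @param pair two locus indices or names.
#' @param fraction fraction of rows to shuffle, in \[0, 1\].
#' @param seed integer seed.
#' @return the modified genotype matrix.
#' @export
shuffle_fraction <- function(genotypes, pair, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  pair <- pair_label(genotypes, pair)
  k <- floor(fraction * nrow(genotypes))
  if (k < 2) return(genotypes)
  withr::with_seed(as.integer(seed), {
    rows <- sample.int(nrow(genotypes), k)
    genotypes[rows, pair] <- genotypes[rows[sample.int(k)], pair, drop = FALSE]
  })
  genotypes
}

#' Permute one genotype column
#'
#' Destroys the locus's association with the phenotype in expectation while
#' preserving its genotype multiset exactly.
#'
#' @param genotypes samples x loci matrix.
#' @param locus column index or name.
#' @param seed integer seed.
#' @export
permute_column <- function(genotypes, locus, seed = 1L) {
  if (is.character(locus)) locus <- match(locus, colnames(genotypes))
  withr::with_seed(as.integer(seed),
    genotypes[, locus] <- genotypes[sample.int(nrow(genotypes)), locus])
  genotypes
}

#' Reference random-forest detectable R squared
#'
#' The probe used to quantify how much phenotypic variance a machine-learning
#' regressor can recover from a dataset: a fixed random forest (bootstrap,
#' max_features 0.25, min_samples_leaf 5, min_samples_split 10, 100 trees,
#' fixed seed) fit on the training partition and scored on the test
#' partition.
#'
#' @param genotypes,phenotype the dataset.
#' @param split a [split_data()] object (default: seeded by `seed`).
#' @param seed integer seed.
#' @export
rf_detectable_r2 <- function(genotypes, phenotype, split = NULL, seed = 1L) {
  if (is.null(split)) split <- split_data(nrow(genotypes), seed)
  spec <- regressor_spec("RF", bootstrap = TRUE, max_features = 0.25,
                         min_samples_leaf = 5, min_samples_split = 10)
  fit <- fit_regressor(spec, genotypes[split$train, , drop = FALSE],
                       phenotype[split$train], seed = seed)
  r2_score(phenotype[split$test],
           predict_regressor(fit, genotypes[split$test, , drop = FALSE]))
}

#' Calibrate injected interactions to a target detectable R squared
#'
#' Starting from a dataset with injected XOR pairs at full strength, bisects
#' on a common shuffle fraction (at most 20 iterations) until the probe
#' regressor's test R squared is within `tol` of `target_r2`.
#'
#' @param genotypes matrix with the pairs already injected (full strength).
#' @param phenotype phenotype vector.
#' @param pairs list of disjoint locus pairs (indices or names).
#' @param target_r2 target detectable R squared.
#' @param tol stopping tolerance (default 0.01).
#' @param seed integer seed (drives the shuffles, the probe and its split).
#' @param evaluator function(genotypes) -> R squared; defaults to
#'   [rf_detectable_r2()] with a split seeded by `seed`.
#' @return list with `genotypes` (calibrated), `achieved_r2`, `fraction`.
#' @export
calibrate_to_target_r2 <- function(genotypes, phenotype, pairs, target_r2,
                                   tol = 0.01, seed = 1L, evaluator = NULL) {
  if (is.null(evaluator)) {
    split <- split_data(nrow(genotypes), seed)
    evaluator <- function(X) rf_detectable_r2(X, phenotype, split, seed)
  }
  apply_fraction <- function(f) {
    X <- genotypes
    for (i in seq_along(pairs))
      X <- shuffle_fraction(X, pairs[[i]], f, seed = as.integer(seed) + i)
    X
  }
  ceiling_r2 <- evaluator(genotypes)
  if (target_r2 > ceiling_r2 + tol)
    stop(sprintf("target R2 %.3f above the unshuffled ceiling %.3f",
                 target_r2, ceiling_r2))
  lo <- 0; hi <- 1
  best <- list(genotypes = genotypes, achieved_r2 = ceiling_r2, fraction = 0)
  for (it in seq_len(20)) {
    mid <- (lo + hi) / 2
    X <- apply_fraction(mid)
    r2 <- evaluator(X)
    if (abs(r2 - target_r2) < abs(best$achieved_r2 - target_r2))
      best <- list(genotypes = X, achieved_r2 = r2, fraction = mid)
    if (abs(r2 - target_r2) <= tol) break
    if (r2 > target_r2) lo <- mid else hi <- mid
  }
  best
}

#' Build a ladder of datasets with increasing XOR interactions
#'
#' Returns `k + 1` datasets with 0..k injected XOR pairs. In `replace_noise`
#' mode the base dataset first has *every* column permuted (all main effects
#' destroyed; interactions then replace pure noise). In
#' `replace_main_effects` mode the base dataset is left intact and each step
#' first permutes the two chosen columns (breaking their main effects) and
#' then injects the XOR pair on them. Pairs are disjoint: with `k = 9` on 18
#' loci every locus takes part in exactly one interaction.
#'
#' @param genotypes,phenotype the base dataset.
#' @param k number of interactions (2k <= number of loci).
#' @param mode "replace_noise" or "replace_main_effects".
#' @param seed integer seed (drives pairing, permutations, injections).
#' @param shuffle fraction shuffled per injected pair (0 = full strength).
#' @return list with `datasets` (list of k+1 genotype matrices), `pairs`
#'   (list of locus-index pairs, step i uses pairs 1..i), `phenotype`.
#' @export
build_interaction_ladder <- function(genotypes, phenotype, k,
                                     mode = c("replace_noise",
                                              "replace_main_effects"),
                                     seed = 1L, shuffle = 0) {
  mode <- match.arg(mode)
  m <- ncol(genotypes)
  if (2 * k > m) stop("need 2k <= number of loci (", 2 * k, " > ", m, ")")
  seed <- as.integer(seed)
  loci <- withr::with_seed(seed, sample.int(m))
  pairs <- lapply(seq_len(k), function(i) loci[c(2 * i - 1, 2 * i)])
  base <- genotypes
  if (mode == "replace_noise") {
    for (j in seq_len(m)) base <- permute_column(base, j, seed = seed + 100L + j)
  }
  datasets <- vector("list", k + 1)
  datasets[[1]] <- base
  X <- base
  for (i in seq_len(k)) {
    if (mode == "replace_main_effects") {
      for (l in pairs[[i]]) X <- permute_column(X, l, seed = seed + 200L + l)
    }
    X <- inject_xor_pair(X, phenotype, pairs[[i]], seed = seed + 300L + i)
    if (shuffle > 0)
      X <- shuffle_fraction(X, pairs[[i]], shuffle, seed = seed + 400L + i)
    datasets[[i + 1]] <- X
  }
  list(datasets = datasets, pairs = pairs, phenotype = phenotype)
}
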