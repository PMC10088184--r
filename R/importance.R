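#' Exact Shapley values for a linear model
#'
#' With independent features and a linear model, the Shapley value of
#' feature j at point x is `coef_j * (x_j - mean(background_j))`; local
#' accuracy (values sum to prediction minus mean background prediction) is
#' exact.
#'
#' @param model a fitted LR handle from [fit_regressor()].
#' @param X_background,X_eval background and evaluation matrices.
#' @return list with `phi` (eval x features matrix) and scalar `baseline`.
#' @export
shapley_linear <- function(model, X_background, X_eval) {
  stopifnot(model$kind == "LR")
  beta <- model$coef[-1]
  mu <- colMeans(X_background)
  phi <- sweep(X_eval, 2, mu) * rep(beta, each = nrow(X_eval))
  list(phi = unname(phi), baseline = mean(predict_regressor(model, X_background)))
}

#' Permutation-sampling Shapley values
#'
#' Model-agnostic estimator: for each sampled permutation a background row is
#' drawn and features are switched one by one from the background value to
#' the evaluation value in permutation order; the marginal prediction change
#' is credited to the switched feature. By the telescoping construction,
#' local accuracy — values summing to `prediction - baseline` — holds
#' exactly for any number of permutations. The default settings perform well
#' above 2,000 model evaluations per explanation.
#'
#' @param predict_fn function(matrix) -> predictions.
#' @param X_background,X_eval background and evaluation matrices.
#' @param n_perm number of permutations sampled.
#' @param seed integer seed.
#' @return list with `phi` (eval x features) and scalar `baseline` (mean
#'   prediction over the sampled background rows).
#' @export
shapley_sampling <- function(predict_fn, X_background, X_eval,
                             n_perm = 16L, seed = 1L) {
  n_eval <- nrow(X_eval)
  m <- ncol(X_eval)
  withr::with_seed(as.integer(seed), {
    perms <- replicate(n_perm, sample.int(m), simplify = FALSE)
    zrows <- sample.int(nrow(X_background), n_perm, replace = TRUE)
  })
  blocks <- vector("list", n_perm * (m + 1L))
  b <- 0L
  for (p in seq_len(n_perm)) {
    cur <- X_background[rep(zrows[p], n_eval), , drop = FALSE]
    b <- b + 1L; blocks[[b]] <- cur
    for (j in perms[[p]]) {
      cur[, j] <- X_eval[, j]
      b <- b + 1L; blocks[[b]] <- cur
    }
  }
  preds <- predict_fn(do.call(rbind, blocks))
  block <- function(i) preds[((i - 1L) * n_eval + 1L):(i * n_eval)]
  phi <- matrix(0, n_eval, m)
  base <- 0
  for (p in seq_len(n_perm)) {
    i0 <- (p - 1L) * (m + 1L) + 1L
    prev <- block(i0)
    base <- base + prev[1] / n_perm
    for (s in seq_len(m)) {
      curp <- block(i0 + s)
      j <- perms[[p]][s]
      phi[, j] <- phi[, j] + (curp - prev) / n_perm
      prev <- curp
    }
  }
  list(phi = phi, baseline = base)
}

#' Per-locus Shapley importance of one pipeline
#'
#' Shapley values are computed in the pipeline's transformed feature space —
#' background distribution from the transformed training partition,
#' evaluation points from the transformed test partition, so importance
#' measures generalizable contribution — and reported against the original
#' locus identifiers (encoders re-map values locus-wise; selectors only
#' remove loci). Loci removed by the pipeline's selectors score exactly 0.
#' The per-locus score is the mean absolute Shapley value across evaluation
#' samples (phenotype units). Linear roots use the exact closed form; tree
#' roots use the seeded permutation-sampling estimator.
#'
#' @param pipeline a `qtl_pipeline`.
#' @param genotypes,phenotype the dataset.
#' @param split a [split_data()] object.
#' @param seed integer seed (model fitting and sampling).
#' @param n_perm permutations for the sampling estimator.
#' @param max_eval,max_background caps on evaluation/background rows
#'   (seeded subsamples beyond that).
#' @param detail return per-sample values as well.
#' @return named numeric vector of per-locus scores; with `detail = TRUE`, a
#'   list with `scores`, `phi`, `baseline`, `predictions`, `keep`.
#' @export
pipeline_shapley <- function(pipeline, genotypes, phenotype, split,
                             seed = 1L, n_perm = 16L, max_eval = 100L,
                             max_background = 200L, detail = FALSE) {
  loci <- colnames(genotypes)
  scores <- stats::setNames(numeric(ncol(genotypes)), loci)
  ex <- execute_pipeline(pipeline,
                         genotypes[split$train, , drop = FALSE],
                         genotypes[split$test, , drop = FALSE],
                         phenotype[split$train])
  if (ex$empty) {
    if (detail) return(list(scores = scores, phi = NULL, baseline = NA_real_,
                            predictions = NULL, keep = ex$keep))
    return(scores)
  }
  fit <- fit_regressor(pipeline$root, ex$train, phenotype[split$train],
                       seed = seed)
  bg <- ex$train
  ev <- ex$apply
  withr::with_seed(as.integer(seed) + 7L, {
    if (nrow(bg) > max_background)
      bg <- bg[sample.int(nrow(bg), max_background), , drop = FALSE]
    if (nrow(ev) > max_eval)
      ev <- ev[sample.int(nrow(ev), max_eval), , drop = FALSE]
  })
  sh <- if (pipeline$root$kind == "LR") {
    shapley_linear(fit, bg, ev)
  } else {
    shapley_sampling(function(X) predict_regressor(fit, X), bg, ev,
                     n_perm = n_perm, seed = seed)
  }
  scores[ex$keep] <- colMeans(abs(sh$phi))
  if (detail) {
    list(scores = scores, phi = sh$phi, baseline = sh$baseline,
         predictions = predict_regressor(fit, ev), keep = ex$keep)
  } else scores
}

#' Aggregate Shapley importance across a Pareto archive
#'
#' Computes per-locus scores for every archive pipeline (zeros for removed
#' loci included) and summarizes each locus by the mean and the standard
#' error of the mean across pipelines, ranked by mean.
#'
#' @param object an `autoqtl` fit.
#' @param seed integer seed (default: the run's seed).
#' @param ... forwarded to [pipeline_shapley()].
#' @return a data frame of class `qtl_importance` with columns `locus`,
#'   `mean`, `sem`, `rank`; the pipeline x locus score matrix is attached as
#'   attribute `"scores"`.
#' @export
qtl_importance <- function(object, seed = NULL, ...) {
  stopifnot(inherits(object, "autoqtl"), length(object$archive) > 0)
  if (is.null(seed)) seed <- object$config$seed
  S <- vapply(object$archive, function(rec) {
    pipeline_shapley(rec$pipeline, object$genotypes, object$phenotype,
                     object$split, seed = seed, ...)
  }, numeric(ncol(object$genotypes)))
  S <- matrix(S, nrow = ncol(object$genotypes),
              dimnames = list(colnames(object$genotypes), NULL))
  mu <- rowMeans(S)
  sem <- apply(S, 1, function(x) {
    if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  })
  out <- data.frame(locus = rownames(S), mean = unname(mu),
                    sem = unname(sem),
                    rank = rank(-mu, ties.method = "first"),
                    row.names = NULL)
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  attr(out, "scores") <- S
  class(out) <- c("qtl_importance", "data.frame")
  out
}

#' Change in importance contrast within locus pairs
#'
#' For each locus pair, the absolute difference of the two loci's mean
#' importance scores, in a "before" and an "after" table (e.g. before and
#' after replacing main effects with an interaction: interaction partners
#' are expected to move toward similar importance).
#'
#' @param before,after `qtl_importance` tables over the same loci.
#' @param pairs list of locus pairs (names or indices into the locus set).
#' @return data frame with one row per pair: `delta_before`, `delta_after`.
#' @export
importance_delta <- function(before, after, pairs) {
  if (!setequal(before$locus, after$locus))
    stop("importance tables cover different locus sets")
  get <- function(tab, l) {
    if (is.numeric(l)) l <- tab$locus[l]
    i <- match(l, tab$locus)
    if (anyNA(i)) stop("locus not present: ", paste(l[is.na(i)], collapse = ", "))
    tab$mean[i]
  }
  do.call(rbind, lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    data.frame(pair = i,
               delta_before = abs(diff(get(before, p))),
               delta_after = abs(diff(get(after, p))))
  }))
}
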