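#' Hyperparameter grids for the feature-selection operators
#'
#' VT (variance threshold) and GF (genotype frequency) thresholds run from 0
#' to 0.35 in steps of 0.05; SP (select percentile) runs from 5% to 95% in
#' steps of 5%.
#'
#' @name selector_grids
#' @export
vt_grid <- function() seq(0, 0.35, by = 0.05)

#' @rdname selector_grids
#' @export
gf_grid <- function() seq(0, 0.35, by = 0.05)

#' @rdname selector_grids
#' @export
sp_grid <- function() seq(5L, 95L, by = 5L)

pop_var <- function(x) mean((x - mean(x))^2)

#' Variance-threshold feature mask
#'
#' Keeps a locus iff its population variance (divide by n) is strictly
#' greater than the threshold, so threshold 0 removes constant loci.
#'
#' @param X encoded samples x loci matrix.
#' @param threshold variance threshold.
#' @return logical vector over loci, TRUE = keep.
#' @export
vt_mask <- function(X, threshold) {
  apply(X, 2, pop_var) > threshold
}

#' Univariate F-regression scores
#'
#' Per locus, the F statistic of the univariate regression of the phenotype
#' on that locus: `F = r^2/(1-r^2) * (n-2)` with `r` the Pearson correlation.
#' Constant loci score 0; a perfectly correlated locus scores `Inf` and
#' therefore outranks every finite score.
#'
#' @param X encoded samples x loci matrix.
#' @param y phenotype vector (non-constant, n >= 3).
#' @return numeric vector of F scores per locus.
#' @export
f_regression_scores <- function(X, y) {
  n <- nrow(X)
  r <- suppressWarnings(as.vector(stats::cor(X, y)))
  r[is.na(r)] <- 0
  r2 <- pmin(r^2, 1)
  ifelse(r2 >= 1, Inf, r2 / (1 - r2) * (n - 2))
}

#' Select-percentile feature mask
#'
#' Keeps the loci whose F-regression scores fall in the top `percentile`
#' percent; the number kept is `max(1, round(percentile/100 * m))` (half-up
#' rounding), with ties broken in favour of the lower column index.
#'
#' @param X encoded samples x loci matrix.
#' @param y phenotype vector.
#' @param percentile percentage of features to keep.
#' @return logical vector over loci, TRUE = keep.
#' @export
sp_mask <- function(X, y, percentile) {
  m <- ncol(X)
  k <- max(1L, as.integer(floor(percentile / 100 * m + 0.5)))
  scores <- f_regression_scores(X, y)
  keep <- logical(m)
  keep[order(-scores, seq_len(m))[seq_len(min(k, m))]] <- TRUE
  keep
}

#' Genotype-frequency feature mask
#'
#' Removes a locus iff the relative frequency of any genotype value present
#' in its column falls strictly below the threshold. Frequencies are computed
#' over the values actually present, so a 2-level-encoded locus with a 50/50
#' split of two values survives any threshold in the grid.
#'
#' @param X encoded samples x loci matrix.
#' @param threshold minimum genotype frequency.
#' @return logical vector over loci, TRUE = keep.
#' @export
gf_mask <- function(X, threshold) {
  n <- nrow(X)
  apply(X, 2, function(col) {
    min(tabulate(match(col, unique(col)))) / n >= threshold
  })
}
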