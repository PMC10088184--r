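#' Regression root specifications
#'
#' A pipeline's root is one of three regressors: `LR` (ordinary least
#' squares, no hyperparameters), `DT` (a CART regression tree with
#' `max_depth`, `min_samples_leaf`, `min_samples_split`) or `RF` (an ensemble
#' of such trees with a `bootstrap` flag and a per-tree feature-subsample
#' fraction `max_features`, plus the two leaf/split sizes; 100 trees).
#'
#' @param kind "LR", "DT" or "RF".
#' @param ... hyperparameters for DT/RF (see grids in [regressor_grids()]).
#' @return a list of class `regressor_spec`.
#' @export
regressor_spec <- function(kind = c("LR", "DT", "RF"), ...) {
  kind <- match.arg(kind)
  hp <- list(...)
  grids <- regressor_grids()[[kind]]
  defaults <- lapply(grids, `[[`, 1)
  miss <- setdiff(names(hp), names(grids))
  if (length(miss)) stop("unknown hyperparameter(s) for ", kind, ": ",
                         paste(miss, collapse = ", "))
  hp <- utils::modifyList(defaults, hp)
  structure(list(kind = kind, hp = hp), class = "regressor_spec")
}

#' Hyperparameter grids for the regression roots
#'
#' @return a named list: per regressor kind, a named list of admissible
#'   hyperparameter values.
#' @export
regressor_grids <- function() {
  list(
    LR = list(),
    DT = list(max_depth = 1:10,
              min_samples_leaf = 1:20,
              min_samples_split = 2:20),
    RF = list(bootstrap = c(TRUE, FALSE),
              max_features = seq(0.05, 1, by = 0.05),
              min_samples_leaf = 1:20,
              min_samples_split = 2:20)
  )
}

#' Number of trees grown for a random forest root
#' @export
rf_num_trees <- function() 100L

as_tree_frame <- function(X) {
  df <- as.data.frame(X)
  names(df) <- paste0("x", seq_len(ncol(X)))
  df
}

fit_tree <- function(df, y, hp) {
  df$.y <- y
  depth <- if (is.null(hp$max_depth)) 30L else hp$max_depth
  rpart::rpart(.y ~ ., data = df, method = "anova",
               control = rpart::rpart.control(
                 maxdepth = depth,
                 minbucket = hp$min_samples_leaf,
                 minsplit = hp$min_samples_split,
                 cp = 0, xval = 0, maxsurrogate = 0, maxcompete = 0))
}

#' Fit a regression root
#'
#' All randomness (bootstrap resampling and feature subsampling in RF) is a
#' pure function of `seed`; LR and DT are deterministic. A singular LR design
#' is resolved by the pivoting least-squares solution with aliased
#' coefficients set to zero.
#'
#' @param spec a [regressor_spec()].
#' @param X samples x features numeric matrix with at least one column.
#' @param y phenotype vector (non-constant).
#' @param seed integer seed for tree randomness.
#' @return a fitted-model handle for [predict_regressor()].
#' @export
fit_regressor <- function(spec, X, y, seed = 0L) {
  if (is.null(ncol(X)) || ncol(X) == 0)
    stop("empty pipeline: no features left to fit a regressor on")
  if (stats::var(y) == 0) stop("phenotype is constant")
  kind <- spec$kind
  hp <- spec$hp
  fit <- switch(kind,
    LR = {
      co <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)$coefficients
      co[is.na(co)] <- 0
      list(coef = co)
    },
    DT = list(tree = fit_tree(as_tree_frame(X), y, hp)),
    RF = {
      n <- nrow(X); m <- ncol(X)
      k <- max(1L, as.integer(floor(hp$max_features * m + 0.5)))
      df <- as_tree_frame(X)
      withr::with_seed(as.integer(seed), {
        trees <- lapply(seq_len(rf_num_trees()), function(t) {
          rows <- if (hp$bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
          feats <- sort(sample.int(m, k))
          list(tree = fit_tree(df[rows, feats, drop = FALSE], y[rows], hp),
               feats = feats)
        })
      })
      list(trees = trees)
    })
  structure(c(fit, list(kind = kind, hp = hp, p = ncol(X))),
            class = "qtl_regressor")
}

#' Predict from a fitted regression root
#'
#' @param object a fitted handle from [fit_regressor()].
#' @param X samples x features matrix with the same columns as at fit time.
#' @return numeric vector of predictions.
#' @export
predict_regressor <- function(object, X) {
  stopifnot(inherits(object, "qtl_regressor"), ncol(X) == object$p)
  switch(object$kind,
    LR = as.vector(cbind(1, X) %*% object$coef),
    DT = unname(stats::predict(object$tree, as_tree_frame(X))),
    RF = {
      df <- as_tree_frame(X)
      preds <- vapply(object$trees, function(tr)
        unname(stats::predict(tr$tree, df[tr$feats])), numeric(nrow(X)))
      if (nrow(X) == 1) mean(preds) else rowMeans(preds)
    })
}
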