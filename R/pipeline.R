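#' The overfitting-penalizing difference score
#'
#' `DS = (1 / |train R2 - test R2|)^(1/4)`, maximized alongside the test R
#' squared as the second Pareto objective. The fourth root compresses the
#' scale; the absolute difference is floored at 1e-8 so that a pipeline with
#' equal train and test R squared scores the ceiling DS = 100.
#'
#' @param train_r2,test_r2 R squared on the training and testing partitions.
#' @return a value in (0, 100].
#' @export
difference_score <- function(train_r2, test_r2) {
  (1 / pmax(abs(train_r2 - test_r2), 1e-8))^0.25
}

phase_encoder <- function(name) {
  list(class = "encoder", name = name)
}

phase_selector <- function(kind, value) {
  list(class = "selector", kind = kind, value = value)
}

#' Construct a pipeline expression tree
#'
#' A pipeline is an ordered chain of phases (inheritance-model encoders and
#' feature selectors, applied left to right) with exactly one regression root.
#'
#' @param phases list of phases built by the GP engine; each is an encoder
#'   (by name) or a selector (`VT`/`SP`/`GF` with its hyperparameter).
#' @param root a [regressor_spec()].
#' @return an object of class `qtl_pipeline`.
#' @export
qtl_pipeline <- function(phases = list(), root = regressor_spec("LR")) {
  stopifnot(inherits(root, "regressor_spec"))
  structure(list(phases = phases, root = root), class = "qtl_pipeline")
}

random_phase <- function() {
  if (stats::runif(1) < 0.5) {
    phase_encoder(sample(setdiff(names(encoding_tables), "additive"), 1))
  } else {
    kind <- c("VT", "SP", "GF")[sample.int(3, 1)]
    grid <- switch(kind, VT = vt_grid(), SP = sp_grid(), GF = gf_grid())
    phase_selector(kind, grid[sample.int(length(grid), 1)])
  }
}

random_regressor <- function() {
  kind <- c("LR", "DT", "RF")[sample.int(3, 1)]
  grid <- regressor_grids()[[kind]]
  hp <- lapply(grid, function(g) g[sample.int(length(g), 1)])
  do.call(regressor_spec, c(list(kind = kind), hp))
}

#' Draw a random pipeline
#'
#' Uniform over the operator catalog: the phase count is uniform on
#' `0..max_phases`, each phase is an encoder or a selector with equal
#' probability, and every hyperparameter is uniform over its grid. Draws
#' consume the current R random stream.
#'
#' @param max_phases maximum number of phases.
#' @export
random_pipeline <- function(max_phases = 6L) {
  n_phases <- sample.int(max_phases + 1L, 1L) - 1L
  qtl_pipeline(phases = replicate(n_phases, random_phase(), simplify = FALSE),
               root = random_regressor())
}

format_phase <- function(ph) {
  if (ph$class == "encoder") {
    paste0(toupper(substring(ph$name, 1, 1)), substring(ph$name, 2))
  } else {
    paste0(ph$kind, " (", format(ph$value, trim = TRUE), ")")
  }
}

format_root <- function(spec) {
  if (spec$kind == "LR") return("LR")
  hp <- spec$hp
  vals <- if (spec$kind == "DT") {
    c(hp$max_depth, hp$min_samples_leaf, hp$min_samples_split)
  } else {
    c(if (hp$bootstrap) "T" else "F", format(hp$max_features, trim = TRUE),
      hp$min_samples_leaf, hp$min_samples_split)
  }
  paste0(spec$kind, " (", paste(vals, collapse = ", "), ")")
}

#' Canonical single-line description of a pipeline
#'
#' Used for display, TSV output, and structural deduplication of the Pareto
#' archive.
#'
#' @param x a `qtl_pipeline`.
#' @param ... unused.
#' @export
format.qtl_pipeline <- function(x, ...) {
  phases <- if (length(x$phases)) {
    paste(vapply(x$phases, format_phase, ""), collapse = " | ")
  } else "-"
  paste0(phases, " | ", format_root(x$root))
}

#' @export
print.qtl_pipeline <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Execute a pipeline's phases
#'
#' Phases are applied left to right. Encoders transform the training and
#' application matrices identically; selectors compute their feature mask on
#' the *training* matrix only and apply it to both, so no information leaks
#' from test or holdout partitions into feature selection.
#'
#' @param pipeline a `qtl_pipeline`.
#' @param X_train training samples x loci matrix.
#' @param X_apply matrix to transform alongside (same loci).
#' @param y_train training phenotype (needed by SP selectors).
#' @return a list with `train`, `apply` (transformed matrices), `keep`
#'   (logical over the original loci) and `empty` (TRUE when every locus was
#'   removed, an invalid pipeline).
#' @export
execute_pipeline <- function(pipeline, X_train, X_apply, y_train) {
  stopifnot(identical(colnames(X_train), colnames(X_apply)))
  keep <- rep(TRUE, ncol(X_train))
  names(keep) <- colnames(X_train)
  tr <- X_train; ap <- X_apply
  for (ph in pipeline$phases) {
    if (ncol(tr) == 0) break
    if (ph$class == "encoder") {
      tr <- apply_encoding(tr, ph$name)
      ap <- apply_encoding(ap, ph$name)
    } else {
      mask <- switch(ph$kind,
                     VT = vt_mask(tr, ph$value),
                     SP = sp_mask(tr, y_train, ph$value),
                     GF = gf_mask(tr, ph$value))
      tr <- tr[, mask, drop = FALSE]
      ap <- ap[, mask, drop = FALSE]
      keep[keep][!mask] <- FALSE
    }
  }
  list(train = tr, apply = ap, keep = keep, empty = ncol(tr) == 0)
}

worst_fitness <- function() c(test_r2 = -Inf, ds = -Inf)

#' Evaluate a pipeline on a data split
#'
#' Executes the phases (selectors fit on the training partition), fits the
#' root on the transformed training data, and scores R squared on the
#' training and testing partitions. The fitness pair maximized by the GP is
#' `(test R2, DS)`. Pipelines whose selectors remove every locus are invalid
#' and receive the sentinel worst fitness `(-Inf, -Inf)`.
#'
#' @param pipeline a `qtl_pipeline`.
#' @param genotypes samples x loci matrix.
#' @param phenotype phenotype vector.
#' @param split a [split_data()] object.
#' @param seed seed forwarded to [fit_regressor()].
#' @return a list with `fitness` (named numeric: `test_r2`, `ds`),
#'   `train_r2`, `keep` and `valid`.
#' @export
evaluate_pipeline <- function(pipeline, genotypes, phenotype, split, seed = 0L) {
  if (stats::var(phenotype) == 0) stop("phenotype is constant")
  ex <- execute_pipeline(pipeline,
                         genotypes[split$train, , drop = FALSE],
                         genotypes[split$test, , drop = FALSE],
                         phenotype[split$train])
  if (ex$empty) {
    return(list(fitness = worst_fitness(), train_r2 = NA_real_,
                keep = ex$keep, valid = FALSE))
  }
  fit <- fit_regressor(pipeline$root, ex$train, phenotype[split$train], seed)
  train_r2 <- r2_score(phenotype[split$train], predict_regressor(fit, ex$train))
  test_r2 <- r2_score(phenotype[split$test], predict_regressor(fit, ex$apply))
  list(fitness = c(test_r2 = test_r2,
                   ds = difference_score(train_r2, test_r2)),
       train_r2 = train_r2, keep = ex$keep, valid = TRUE)
}
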