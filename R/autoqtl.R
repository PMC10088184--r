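#' Fit: evolve QTL-analysis pipelines for a genotype/phenotype dataset
#'
#' The main entry point. Splits the data into holdout (20%) and train/test
#' halves (40%/40%), evolves pipeline expression trees — inheritance-model
#' encoders and genetics-aware feature selectors below a regression root —
#' by genetic programming under two-objective NSGA-II selection (maximizing
#' test R squared and the overfitting-penalizing difference score), and
#' returns the cumulative Pareto archive with holdout scores.
#'
#' @param data a data frame (or path to a CSV/TSV readable by
#'   [read_qtl_data()]) with one row per sample, loci as 0/1/2-coded columns
#'   and one phenotype column; alternatively a genotype matrix, in which case
#'   `phenotype` must be the phenotype vector itself.
#' @param phenotype the phenotype column name (or the numeric vector when
#'   `data` is a matrix).
#' @param population_size,offspring_size,mutation_rate,crossover_rate,generations,max_phases
#'   GP run parameters, see [gp_config()].
#' @param seed integer seed; drives the data split and the whole evolution.
#' @return an object of class `autoqtl`; see [pareto_front()],
#'   [summary.autoqtl()], [plot.autoqtl()], [predict.autoqtl()],
#'   [qtl_importance()].
#' @examples
#' sim <- simulate_qtl_dataset(n_samples = 200, n_loci = 8, seed = 1)
#' fit <- autoqtl(sim$genotypes, sim$phenotype, population_size = 10,
#'                offspring_size = 10, generations = 2, seed = 1)
#' pareto_front(fit)
#' @export
autoqtl <- function(data, phenotype,
                    population_size = 100L, offspring_size = 100L,
                    mutation_rate = 0.9, crossover_rate = 0.1,
                    generations = 25L, seed = 1L, max_phases = 6L) {
  cl <- match.call()
  if (is.character(data) && length(data) == 1) {
    ds <- read_qtl_data(data, phenotype)
    genotypes <- ds$genotypes
    y <- ds$phenotype
  } else if (is.data.frame(data)) {
    if (!phenotype %in% names(data))
      stop("phenotype column '", phenotype, "' not present in data")
    y <- data[[phenotype]]
    genotypes <- as.matrix(data[setdiff(names(data), phenotype)])
    storage.mode(genotypes) <- "integer"
  } else {
    genotypes <- data
    y <- phenotype
    stopifnot(is.numeric(y), length(y) == nrow(genotypes))
  }
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- paste0("locus", seq_len(ncol(genotypes)))
  validate_genotypes(genotypes)
  config <- gp_config(population_size, offspring_size, mutation_rate,
                      crossover_rate, generations, seed, max_phases)
  run <- evolve(genotypes, y, config)
  hold <- holdout_scores(run$archive, genotypes, y, run$split,
                         seed = config$seed)
  structure(list(archive = run$archive, holdout_r2 = hold, log = run$log,
                 split = run$split, config = config,
                 genotypes = genotypes, phenotype = y, call = cl),
            class = "autoqtl")
}

#' Pareto front table of a fitted run
#'
#' One row per archive pipeline: the ordered phase chain with
#' hyperparameters, the root with hyperparameters, train/test R squared, DS,
#' holdout R squared, the final inheritance-model class, and the
#' Pareto-efficiency flag.
#'
#' @param object an `autoqtl` fit.
#' @return a data frame ordered by decreasing test R squared.
#' @export
pareto_front <- function(object) {
  stopifnot(inherits(object, "autoqtl"))
  s <- summarize_front(object$archive)
  data.frame(
    pipeline = vapply(object$archive, function(r) format(r$pipeline), ""),
    root = vapply(object$archive, function(r) r$pipeline$root$kind, ""),
    train_r2 = vapply(object$archive, `[[`, 0, "train_r2"),
    test_r2 = vapply(object$archive, function(r) r$fitness[["test_r2"]], 0),
    ds = vapply(object$archive, function(r) r$fitness[["ds"]], 0),
    holdout_r2 = object$holdout_r2,
    encoding = vapply(object$archive,
                      function(r) final_encoding_class(r$pipeline), ""),
    pareto_efficient = s$pareto_efficient,
    row.names = NULL)
}

#' @export
print.autoqtl <- function(x, ...) {
  cat("autoqtl fit:", length(x$archive), "Pareto-optimal pipelines over",
      x$config$generations, "generations\n")
  cat(sprintf("  %d samples x %d loci (train %d / test %d / holdout %d), seed %d\n",
              nrow(x$genotypes), ncol(x$genotypes), length(x$split$train),
              length(x$split$test), length(x$split$holdout), x$config$seed))
  fr <- pareto_front(x)
  best <- fr[1, ]
  cat(sprintf("  best test R2 = %.4f (DS %.2f): %s\n",
              best$test_r2, best$ds, best$pipeline))
  invisible(x)
}

#' Summarize a fitted run
#'
#' Reports the root-regressor census, the final inheritance-model census and
#' the full front table.
#'
#' @param object an `autoqtl` fit.
#' @param ... unused.
#' @export
summary.autoqtl <- function(object, ...) {
  s <- summarize_front(object$archive)
  s$front <- pareto_front(object)
  s$config <- object$config
  class(s) <- "summary.autoqtl"
  s
}

#' @export
print.summary.autoqtl <- function(x, ...) {
  cat("Pareto archive:", x$n, "pipelines\n\nRoot regressors:\n")
  print(x$root_census, row.names = FALSE)
  cat("\nFinal inheritance models:\n")
  print(x$encoding_census, row.names = FALSE)
  cat("\nFront (by test R2):\n")
  fr <- x$front
  fr$train_r2 <- round(fr$train_r2, 4)
  fr$test_r2 <- round(fr$test_r2, 4)
  fr$ds <- round(fr$ds, 2)
  fr$holdout_r2 <- round(fr$holdout_r2, 4)
  print(fr[c("pipeline", "train_r2", "test_r2", "ds", "holdout_r2",
             "encoding", "pareto_efficient")], row.names = FALSE)
  invisible(x)
}

#' Pareto-front scatter plot
#'
#' Test R squared against difference score for every archive pipeline;
#' Pareto-efficient pipelines (optimized in both metrics) are filled.
#'
#' @param x an `autoqtl` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.autoqtl <- function(x, ...) {
  fr <- pareto_front(x)
  graphics::plot(fr$test_r2, fr$ds, xlab = "Test R²",
                 ylab = "Difference score",
                 pch = ifelse(fr$pareto_efficient, 19, 1),
                 col = ifelse(fr$root == "LR", "#1f77b4",
                              ifelse(fr$root == "RF", "#2ca02c", "#d62728")),
                 main = "Pareto archive", ...)
  graphics::legend("topright", legend = c("LR", "RF", "DT"),
                   col = c("#1f77b4", "#2ca02c", "#d62728"), pch = 19,
                   bty = "n")
  invisible(fr)
}

#' Predict the phenotype with one archive pipeline
#'
#' Re-fits the chosen pipeline on the training partition (deterministically,
#' with the run's seed) and predicts for new samples.
#'
#' @param object an `autoqtl` fit.
#' @param newdata samples x loci matrix over the same loci (defaults to the
#'   fitted data).
#' @param pipeline index of the archive pipeline (front order), default the
#'   highest test R squared.
#' @param ... unused.
#' @export
predict.autoqtl <- function(object, newdata = NULL, pipeline = 1L, ...) {
  if (is.null(newdata)) newdata <- object$genotypes
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  rec <- object$archive[[pipeline]]
  tr <- object$genotypes[object$split$train, , drop = FALSE]
  ex <- execute_pipeline(rec$pipeline, tr, newdata,
                         object$phenotype[object$split$train])
  fit <- fit_regressor(rec$pipeline$root, ex$train,
                       object$phenotype[object$split$train],
                       seed = object$config$seed)
  predict_regressor(fit, ex$apply)
}

#' Residuals of one archive pipeline on the fitted data
#'
#' @param object an `autoqtl` fit.
#' @param pipeline archive pipeline index.
#' @param ... unused.
#' @export
residuals.autoqtl <- function(object, pipeline = 1L, ...) {
  object$phenotype - predict(object, pipeline = pipeline)
}
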