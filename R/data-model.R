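#' Read a genotype/phenotype table
#'
#' Reads a CSV or TSV file (auto-detected from the extension, `.tsv`/`.txt`
#' are tab-separated, anything else comma-separated) with one row per sample,
#' one column per biallelic locus coded 0/1/2 (copies of one allele:
#' AA = 0, Aa = 1, aa = 2), and one continuous phenotype column.
#'
#' @param path path to the file; a header row is mandatory.
#' @param phenotype_column name of the phenotype column.
#' @return a list with components `genotypes` (integer matrix, samples x loci,
#'   locus identifiers as column names, sample identifiers as row names),
#'   `phenotype` (numeric vector) and `sample_ids`, `locus_ids`.
#' @export
read_qtl_data <- function(path, phenotype_column) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!phenotype_column %in% names(df))
    stop("phenotype column '", phenotype_column, "' not present in ", path)
  sample_ids <- if ("sample_id" %in% names(df)) {
    ids <- as.character(df[["sample_id"]])
    df[["sample_id"]] <- NULL
    ids
  } else as.character(seq_len(nrow(df)))
  y <- df[[phenotype_column]]
  if (!is.numeric(y)) stop("phenotype column '", phenotype_column, "' is not numeric")
  if (any(!is.finite(y))) stop("phenotype contains non-finite values")
  G <- df[setdiff(names(df), phenotype_column)]
  codes <- as.matrix(G)
  validate_genotypes(codes, rownames = sample_ids)
  storage.mode(codes) <- "integer"
  rownames(codes) <- sample_ids
  list(genotypes = codes, phenotype = as.numeric(y),
       sample_ids = sample_ids, locus_ids = colnames(codes))
}

#' Write a genotype/phenotype table
#'
#' Inverse of [read_qtl_data()]: writes samples as rows, loci as columns plus
#' a phenotype column, with a `sample_id` column when sample identifiers are
#' informative.
#'
#' @param genotypes integer matrix of 0/1/2 codes, loci as named columns.
#' @param phenotype numeric vector, one value per sample.
#' @param path output path; extension selects the delimiter as in
#'   [read_qtl_data()].
#' @param phenotype_column name for the phenotype column.
#' @export
write_qtl_data <- function(genotypes, phenotype, path,
                           phenotype_column = "phenotype") {
  stopifnot(nrow(genotypes) == length(phenotype))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- as.data.frame(genotypes, check.names = FALSE)
  df[[phenotype_column]] <- phenotype
  if (!is.null(rownames(genotypes)))
    df <- cbind(sample_id = rownames(genotypes), df)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_genotypes <- function(codes, rownames = NULL) {
  if (is.null(colnames(codes)) || anyDuplicated(colnames(codes)))
    stop("locus identifiers must be present and unique")
  if (!is.null(rownames) && anyDuplicated(rownames))
    stop("sample identifiers must be unique")
  bad <- which(!is.finite(codes) | !(codes %in% c(0L, 1L, 2L)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("invalid genotype code at row ", bad[1, 1], ", locus '",
         colnames(codes)[bad[1, 2]], "': value ",
         codes[bad[1, 1], bad[1, 2]], " (codes must be 0, 1 or 2)")
  }
  invisible(TRUE)
}

#' Holdout/train/test split of sample indices
#'
#' Randomly partitions `n_samples` indices into a ~20% holdout set (used only
#' to score final Pareto-front pipelines) and two ~40% halves used as the
#' training and testing sets during pipeline evolution. Sizes are
#' `floor(0.2 n)` for the holdout; the remainder is halved with the odd
#' sample, if any, going to the test set.
#'
#' @param n_samples number of samples (>= 10).
#' @param seed integer seed; the permutation is a pure function of it.
#' @return an object of class `qtl_split` with integer index vectors
#'   `holdout`, `train`, `test` and the `seed`.
#' @export
split_data <- function(n_samples, seed) {
  if (n_samples < 10) stop("need at least 10 samples to split, got ", n_samples)
  perm <- withr::with_seed(as.integer(seed), sample.int(n_samples))
  n_hold <- floor(0.2 * n_samples)
  n_rem <- n_samples - n_hold
  n_train <- floor(n_rem / 2)
  structure(list(holdout = sort(perm[seq_len(n_hold)]),
                 train = sort(perm[n_hold + seq_len(n_train)]),
                 test = sort(perm[(n_hold + n_train + 1):n_samples]),
                 seed = as.integer(seed)),
            class = "qtl_split")
}

#' @export
print.qtl_split <- function(x, ...) {
  cat(sprintf("qtl_split: holdout %d / train %d / test %d (seed %d)\n",
              length(x$holdout), length(x$train), length(x$test), x$seed))
  invisible(x)
}

#' Coefficient of determination
#'
#' `1 - SSres/SStot` with `SStot` taken around the mean of the scored
#' partition's observations; may be negative on held-out data.
#'
#' @param observed,predicted numeric vectors.
#' @export
r2_score <- function(observed, predicted) {
  1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
}

#' Multiple linear regression baseline R squared
#'
#' Ordinary least squares of the phenotype on all loci under the additive
#' coding. With `split = NULL` the model is fit and scored on the full data
#' (the total phenotypic variance explained by main effects); with a split it
#' is fit on the training partition and scored on the requested partition.
#' Singular designs are resolved by the pivoting least-squares solution
#' (aliased coefficients set to zero).
#'
#' @param genotypes samples x loci matrix.
#' @param phenotype numeric phenotype vector.
#' @param split a [split_data()] object or `NULL`.
#' @param partition one of "test", "train", "holdout" (ignored when
#'   `split` is `NULL`).
#' @return R squared on the requested partition.
#' @export
baseline_lr_r2 <- function(genotypes, phenotype, split = NULL,
                           partition = c("test", "train", "holdout")) {
  if (stats::var(phenotype) == 0) stop("phenotype is constant")
  if (is.null(split)) {
    fit <- fit_regressor(regressor_spec("LR"), genotypes, phenotype, seed = 0L)
    return(r2_score(phenotype, predict_regressor(fit, genotypes)))
  }
  partition <- match.arg(partition)
  idx <- split[[partition]]
  fit <- fit_regressor(regressor_spec("LR"),
                       genotypes[split$train, , drop = FALSE],
                       phenotype[split$train], seed = 0L)
  r2_score(phenotype[idx],
           predict_regressor(fit, genotypes[idx, , drop = FALSE]))
}
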