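#' GP run configuration
#'
#' Defaults follow the standard run parameters: population 100, offspring
#' 100, mutation rate 0.9, crossover rate 0.1, 25 generations, at most 6
#' phases per pipeline. Mutation and crossover are mutually exclusive per
#' offspring; their rates must not sum above 1 (any remainder produces
#' clones).
#'
#' @param population_size,offspring_size population and offspring counts.
#' @param mutation_rate,crossover_rate per-offspring variation probabilities.
#' @param generations number of GP generations.
#' @param seed integer seed driving the whole run.
#' @param max_phases maximum phase-chain length.
#' @return a list of class `gp_config`.
#' @export
gp_config <- function(population_size = 100L, offspring_size = 100L,
                      mutation_rate = 0.9, crossover_rate = 0.1,
                      generations = 25L, seed = 1L, max_phases = 6L) {
  if (mutation_rate + crossover_rate > 1)
    stop("mutation_rate + crossover_rate must be <= 1")
  structure(list(population_size = as.integer(population_size),
                 offspring_size = as.integer(offspring_size),
                 mutation_rate = mutation_rate,
                 crossover_rate = crossover_rate,
                 generations = as.integer(generations),
                 seed = as.integer(seed),
                 max_phases = as.integer(max_phases)),
            class = "gp_config")
}

mutate_root <- function(root) {
  repeat {
    grid <- regressor_grids()[[root$kind]]
    replace_op <- length(grid) == 0 || stats::runif(1) < 0.5
    new <- if (replace_op) random_regressor() else {
      hp <- root$hp
      nm <- names(grid)[sample.int(length(grid), 1)]
      hp[[nm]] <- grid[[nm]][sample.int(length(grid[[nm]]), 1)]
      do.call(regressor_spec, c(list(kind = root$kind), hp))
    }
    if (!identical(new, root)) return(new)
  }
}

mutate_phase <- function(ph) {
  repeat {
    replace_op <- ph$class == "encoder" || stats::runif(1) < 0.5
    new <- if (replace_op) random_phase() else {
      grid <- switch(ph$kind, VT = vt_grid(), SP = sp_grid(), GF = gf_grid())
      phase_selector(ph$kind, grid[sample.int(length(grid), 1)])
    }
    if (!identical(new, ph)) return(new)
  }
}

#' Mutate a pipeline
#'
#' One of three mutation kinds, each with probability 1/3:
#' * uniform — a random node (phase or root) either has its operator replaced
#'   by a new random operator or its hyperparameters re-drawn; the root may
#'   be swapped or re-parameterized but never deleted; re-draws repeat until
#'   something actually changes;
#' * insert — a new random phase at a random position (falls back to uniform
#'   mutation when the pipeline is already at `max_phases`);
#' * shrink — a random phase is removed (a no-op on a phase-less pipeline).
#'
#' Draws consume the current R random stream.
#'
#' @param pipeline a `qtl_pipeline`.
#' @param max_phases maximum phase-chain length.
#' @export
mutate_pipeline <- function(pipeline, max_phases = 6L) {
  kind <- sample.int(3, 1)
  np <- length(pipeline$phases)
  if (kind == 2L && np >= max_phases) kind <- 1L
  if (kind == 1L) {
    i <- sample.int(np + 1L, 1L)
    if (i > np) {
      pipeline$root <- mutate_root(pipeline$root)
    } else {
      pipeline$phases[[i]] <- mutate_phase(pipeline$phases[[i]])
    }
  } else if (kind == 2L) {
    pos <- sample.int(np + 1L, 1L)
    pipeline$phases <- append(pipeline$phases, list(random_phase()), after = pos - 1L)
  } else if (np > 0) {
    pipeline$phases[[sample.int(np, 1L)]] <- NULL
  }
  pipeline
}

phase_classes <- function(pipeline) {
  unique(vapply(pipeline$phases, `[[`, "", "class"))
}

#' One-point crossover of two pipelines
#'
#' Two pipelines are eligible when they share a phase operator class (both
#' contain an encoding phase, or both a selection phase). A random position
#' of the shared class is chosen in each parent and the phase chains are
#' spliced there: the offspring keeps `a`'s root and phases before the point,
#' followed by `b`'s phases from its point onward (truncated at
#' `max_phases`). Only the first offspring is kept.
#'
#' @param a,b `qtl_pipeline` parents.
#' @param max_phases maximum phase-chain length.
#' @return a `qtl_pipeline`, or `NULL` when the parents are ineligible.
#' @export
crossover_pipelines <- function(a, b, max_phases = 6L) {
  shared <- intersect(phase_classes(a), phase_classes(b))
  if (length(shared) == 0) return(NULL)
  cls <- shared[sample.int(length(shared), 1L)]
  pos_of <- function(p) which(vapply(p$phases, `[[`, "", "class") == cls)
  i <- pos_of(a); i <- i[sample.int(length(i), 1L)]
  j <- pos_of(b); j <- j[sample.int(length(j), 1L)]
  phases <- c(a$phases[seq_len(i - 1L)], b$phases[j:length(b$phases)])
  if (length(phases) > max_phases) phases <- phases[seq_len(max_phases)]
  qtl_pipeline(phases = phases, root = a$root)
}

#' Update the cumulative Pareto archive
#'
#' The archive is the non-dominated, structurally deduplicated subset of
#' every valid pipeline evaluated so far (hall-of-fame semantics across
#' generations).
#'
#' @param archive list of records `list(pipeline, fitness, train_r2, keep)`.
#' @param evaluated list of new records of the same shape.
#' @return the updated archive, ordered by decreasing test R squared.
#' @export
update_archive <- function(archive, evaluated) {
  pool <- c(archive, evaluated)
  if (length(pool) == 0) return(pool)
  pool <- Filter(function(r) all(is.finite(r$fitness)), pool)
  if (length(pool) == 0) return(list())
  ids <- vapply(pool, function(r) format(r$pipeline), "")
  pool <- pool[!duplicated(ids)]
  fit <- do.call(rbind, lapply(pool, `[[`, "fitness"))
  keep <- nondominated_sort(fit) == 1L
  pool <- pool[keep]
  pool[order(-vapply(pool, function(r) r$fitness[["test_r2"]], 0))]
}

#' Evolve QTL-analysis pipelines by genetic programming
#'
#' The core loop: initialize `population_size` random pipelines; each
#' generation, produce `offspring_size` offspring (per offspring: mutation
#' with probability `mutation_rate`, else crossover with probability
#' `crossover_rate` — falling back to a clone when the chosen parents are
#' ineligible — else a clone), evaluate everything, update the cumulative
#' Pareto archive, and select the next population from parents plus
#' offspring by NSGA-II survival. Parents are picked by crowded binary
#' tournament (non-domination rank, ties by crowding distance), so fitter
#' pipelines contribute more material to offspring. Pipeline fitness is cached by
#' structure, so re-evaluations of identical pipelines are free and the whole
#' run is a pure function of the data, the split and the configuration.
#'
#' @param genotypes samples x loci matrix of 0/1/2 codes.
#' @param phenotype numeric phenotype vector.
#' @param config a [gp_config()].
#' @param split a [split_data()] object; defaults to a split seeded by
#'   `config$seed`.
#' @return a list with `archive` (Pareto archive records), `log`
#'   (per-generation data frame), `split` and `config`.
#' @export
evolve <- function(genotypes, phenotype, config = gp_config(), split = NULL) {
  validate_genotypes(genotypes)
  if (is.null(split)) split <- split_data(nrow(genotypes), config$seed)
  cache <- new.env(parent = emptyenv())
  evaluate <- function(pipeline) {
    id <- format(pipeline)
    if (!is.null(cache[[id]])) return(cache[[id]])
    rec <- evaluate_pipeline(pipeline, genotypes, phenotype, split,
                             seed = config$seed)
    rec$pipeline <- pipeline
    cache[[id]] <- rec
    rec
  }
  log_rows <- list()
  archive <- list()
  best_so_far <- -Inf
  last_improved <- 0L
  log_generation <- function(gen, recs) {
    fin <- Filter(function(r) all(is.finite(r$fitness)), recs)
    test <- vapply(fin, function(r) r$fitness[["test_r2"]], 0)
    ds <- vapply(fin, function(r) r$fitness[["ds"]], 0)
    mx <- if (length(test)) max(test) else NA_real_
    if (is.finite(mx) && mx > best_so_far + 1e-12) {
      best_so_far <<- mx
      last_improved <<- gen
    }
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      generation = gen,
      mean_test_r2 = if (length(test)) mean(test) else NA_real_,
      max_test_r2 = mx,
      mean_ds = if (length(ds)) mean(ds) else NA_real_,
      archive_size = length(archive),
      last_improvement = last_improved)
  }

  withr::with_seed(config$seed, {
    population <- replicate(config$population_size,
                            random_pipeline(config$max_phases),
                            simplify = FALSE)
    pop_recs <- lapply(population, evaluate)
    archive <- update_archive(archive, pop_recs)
    log_generation(0L, pop_recs)
    gen <- 1L
    while (gen <= config$generations) {
      # crowded binary tournament over the current population
      pop_fit <- do.call(rbind, lapply(pop_recs, `[[`, "fitness"))
      rank <- nondominated_sort(pop_fit)
      cd <- numeric(length(rank))
      for (lev in unique(rank)) {
        idx <- which(rank == lev)
        cd[idx] <- crowding_distance(pop_fit[idx, , drop = FALSE])
      }
      pick_parent <- function() {
        ij <- sample.int(length(population), 2L, replace = TRUE)
        i <- ij[1]; j <- ij[2]
        if (rank[j] < rank[i] ||
            (rank[j] == rank[i] && cd[j] > cd[i])) j else i
      }
      offspring <- vector("list", config$offspring_size)
      for (o in seq_len(config$offspring_size)) {
        u <- stats::runif(1)
        child <- if (u < config$mutation_rate) {
          mutate_pipeline(population[[pick_parent()]], config$max_phases)
        } else if (u < config$mutation_rate + config$crossover_rate) {
          pa <- population[[pick_parent()]]
          pb <- population[[pick_parent()]]
          ch <- crossover_pipelines(pa, pb, config$max_phases)
          if (is.null(ch)) pa else ch
        } else {
          population[[pick_parent()]]
        }
        offspring[[o]] <- child
      }
      off_recs <- lapply(offspring, evaluate)
      archive <- update_archive(archive, off_recs)
      combined <- c(population, offspring)
      fit <- do.call(rbind, lapply(c(pop_recs, off_recs), `[[`, "fitness"))
      sel <- nsga2_select(fit, config$population_size)
      population <- combined[sel]
      pop_recs <- c(pop_recs, off_recs)[sel]
      log_generation(gen, off_recs)
      gen <- gen + 1L
    }
  })
  list(archive = archive, log = do.call(rbind, log_rows),
       split = split, config = config)
}

#' Score archive pipelines on the holdout partition
#'
#' Each archive pipeline is re-fit on the training partition (same seed rule
#' as during evolution) and scored on the 20% holdout set reserved before
#' evolution, the standard check for overfitting of the final front.
#'
#' @param archive a Pareto archive (list of records).
#' @param genotypes,phenotype the data the archive was evolved on.
#' @param split the [split_data()] object of the run.
#' @param seed seed forwarded to [fit_regressor()].
#' @return numeric vector of holdout R squared, one per archive member.
#' @export
holdout_scores <- function(archive, genotypes, phenotype, split, seed = 0L) {
  vapply(archive, function(rec) {
    ex <- execute_pipeline(rec$pipeline,
                           genotypes[split$train, , drop = FALSE],
                           genotypes[split$holdout, , drop = FALSE],
                           phenotype[split$train])
    fit <- fit_regressor(rec$pipeline$root, ex$train, phenotype[split$train],
                         seed)
    r2_score(phenotype[split$holdout], predict_regressor(fit, ex$apply))
  }, numeric(1))
}

#' Classify a pipeline's final inheritance model
#'
#' Composes all encoder phases left to right and classifies the composed map
#' by the number of distinct genotype values it produces: `additive` (no
#' encoder phase), `2-level`, `3-level`, or the degenerate `1-level`
#' (a composition collapsing all genotypes to one value).
#'
#' @param pipeline a `qtl_pipeline`.
#' @export
final_encoding_class <- function(pipeline) {
  encs <- Filter(function(p) p$class == "encoder", pipeline$phases)
  if (length(encs) == 0) return("additive")
  tab <- compose_encodings(vapply(encs, `[[`, "", "name"))
  paste0(length(unique(tab)), "-level")
}

#' Summarize a Pareto archive
#'
#' Root-regressor census (counts and percentages of LR/DT/RF), final
#' inheritance-model census, and per-pipeline Pareto-efficiency flags (a
#' member is Pareto efficient when no other member is strictly better in
#' both test R squared and DS).
#'
#' @param archive a non-empty Pareto archive.
#' @return a list with `n`, `root_census`, `encoding_census` (data frames
#'   with counts and percentages) and `pareto_efficient` (logical vector).
#' @export
summarize_front <- function(archive) {
  if (length(archive) == 0) stop("empty archive")
  roots <- vapply(archive, function(r) r$pipeline$root$kind, "")
  enc <- vapply(archive, function(r) final_encoding_class(r$pipeline), "")
  census <- function(x) {
    tb <- table(x)
    data.frame(class = names(tb), count = as.integer(tb),
               percent = 100 * as.integer(tb) / length(x))
  }
  fit <- do.call(rbind, lapply(archive, `[[`, "fitness"))
  eff <- vapply(seq_along(archive), function(i) {
    !any(fit[, 1] > fit[i, 1] & fit[, 2] > fit[i, 2])
  }, logical(1))
  list(n = length(archive), root_census = census(roots),
       encoding_census = census(enc), pareto_efficient = eff)
}
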