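test_that("difference score follows its closed form with a floored singularity", {
  expect_equal(difference_score(0.50, 0.25), sqrt(2), tolerance = 1e-12)
  expect_equal(difference_score(1, 0), 1)
  expect_equal(difference_score(0.3, 0.3), 100)
  expect_equal(difference_score(0.25, 0.50), sqrt(2), tolerance = 1e-12)  # symmetric
})

test_that("random pipelines respect the structural contract", {
  withr::with_seed(30, {
    pipes <- replicate(2000, random_pipeline(max_phases = 6), simplify = FALSE)
  })
  counts <- vapply(pipes, function(p) length(p$phases), integer(1))
  expect_true(all(counts <= 6))
  expect_true(all(counts >= 0))
  expect_setequal(unique(counts), 0:6)
  roots <- vapply(pipes, function(p) p$root$kind, "")
  expect_setequal(unique(roots), c("LR", "DT", "RF"))
  # the draw sequence is a pure function of the RNG state
  a <- withr::with_seed(31, replicate(20, random_pipeline(), simplify = FALSE))
  b <- withr::with_seed(31, replicate(20, random_pipeline(), simplify = FALSE))
  expect_identical(a, b)
})

test_that("mutation keeps pipelines valid and always changes something removable", {
  withr::with_seed(32, {
    grew <- shrank <- same_len <- FALSE
    for (i in 1:500) {
      parent <- random_pipeline(max_phases = 6)
      child <- mutate_pipeline(parent, max_phases = 6)
      expect_s3_class(child, "qtl_pipeline")
      expect_true(child$root$kind %in% c("LR", "DT", "RF"))  # root never deleted
      expect_lte(length(child$phases), 6)
      d <- length(child$phases) - length(parent$phases)
      grew <- grew || d == 1; shrank <- shrank || d == -1
      same_len <- same_len || d == 0
      # the only admissible no-op is shrink on a phase-less pipeline
      if (identical(child, parent)) expect_equal(length(parent$phases), 0)
    }
    expect_true(grew && shrank && same_len)
  })
})

test_that("crossover requires a shared phase class and keeps one offspring", {
  a <- qtl_pipeline(list(list(class = "encoder", name = "recessive")),
                    regressor_spec("LR"))
  b <- qtl_pipeline(list(list(class = "encoder", name = "heterosis"),
                         list(class = "selector", kind = "GF", value = 0.1)),
                    regressor_spec("RF"))
  withr::with_seed(33, {
    child <- crossover_pipelines(a, b)
    expect_s3_class(child, "qtl_pipeline")
    expect_identical(child$root, a$root)       # first offspring keeps a's root
    expect_lte(length(child$phases), 6)
    # every child phase comes from a parent
    for (ph in child$phases) {
      expect_true(any(vapply(c(a$phases, b$phases), identical, logical(1), ph)))
    }
    # bare pipelines share no phase class
    expect_null(crossover_pipelines(qtl_pipeline(root = regressor_spec("LR")),
                                    qtl_pipeline(root = regressor_spec("RF"))))
    # encoder-only vs selector-only are ineligible too
    sel_only <- qtl_pipeline(list(list(class = "selector", kind = "VT",
                                       value = 0.05)), regressor_spec("DT"))
    expect_null(crossover_pipelines(a, sel_only))
  })
})

test_that("NSGA-II survival equals the brute-force domination oracle", {
  expect_equal(nsga2_select(rbind(c(1, 1), c(0, 0)), 1), 1L)
  expect_setequal(nsga2_select(rbind(c(1, 0), c(0, 1), c(0.5, 0.5)), 3), 1:3)
  withr::with_seed(34, {
    for (i in 1:60) {
      n <- sample(3:30, 1)
      fitness <- cbind(round(runif(n), 2), round(runif(n), 2))
      k <- sample.int(n, 1)
      expect_identical(sort(nsga2_select(fitness, k)),
                       sort(oracle_select(fitness, k)))
    }
  })
})

test_that("the archive rejects dominated, duplicate and invalid entries", {
  rec <- function(test_r2, ds, name) {
    list(pipeline = qtl_pipeline(list(list(class = "encoder", name = name)),
                                 regressor_spec("LR")),
         fitness = c(test_r2 = test_r2, ds = ds), train_r2 = 0)
  }
  arch <- update_archive(list(), list(rec(0.5, 2, "recessive"),
                                      rec(0.3, 5, "dominant")))
  expect_length(arch, 2)
  # dominated newcomer: unchanged
  expect_length(update_archive(arch, list(rec(0.2, 1, "heterosis"))), 2)
  # dominating newcomer: takes over
  expect_length(update_archive(arch, list(rec(0.9, 9, "overdominance"))), 1)
  # structural duplicate: unchanged
  expect_length(update_archive(arch, list(rec(0.5, 2, "recessive"))), 2)
  # sentinel-fitness pipelines never enter
  bad <- rec(-Inf, -Inf, "underdominance")
  expect_length(update_archive(arch, list(bad)), 2)
})

test_that("phases execute left-to-right with masks fit on the training matrix", {
  X <- cbind(l1 = c(0L, 1L, 0L, 1L, 0L, 1L),   # constant after recessive
             l2 = c(0L, 1L, 2L, 2L, 1L, 0L))
  y <- c(0.1, 0.5, 0.9, 1.0, 0.4, 0.2)
  id <- execute_pipeline(qtl_pipeline(), X, X, y)
  expect_identical(id$train, X)
  expect_true(all(id$keep) && !id$empty)

  rec_vt <- qtl_pipeline(list(list(class = "encoder", name = "recessive"),
                              list(class = "selector", kind = "VT", value = 0.05)),
                         regressor_spec("LR"))
  out <- execute_pipeline(rec_vt, X, X, y)
  expect_equal(unname(out$keep), c(FALSE, TRUE))
  # opposite order keeps both loci: VT sees the raw variances first
  vt_rec <- qtl_pipeline(list(list(class = "selector", kind = "VT", value = 0.05),
                              list(class = "encoder", name = "recessive")),
                         regressor_spec("LR"))
  expect_equal(unname(execute_pipeline(vt_rec, X, X, y)$keep), c(TRUE, TRUE))
})

test_that("evaluation scores both objectives and flags emptied pipelines", {
  X <- random_genotypes(80, 3, seed = 36)
  y <- as.vector(X %*% c(1, 2, -1))
  split <- split_data(80, 1)
  ev <- evaluate_pipeline(qtl_pipeline(), X, y, split)
  expect_equal(unname(ev$fitness["test_r2"]), 1.0)
  expect_equal(unname(ev$fitness["ds"]), 100)
  expect_true(ev$valid)
  # a pipeline whose encoding collapses everything to variance zero
  kill <- qtl_pipeline(list(list(class = "encoder", name = "heterosis"),
                            list(class = "encoder", name = "heterosis"),
                            list(class = "selector", kind = "VT", value = 0)),
                       regressor_spec("LR"))
  evk <- evaluate_pipeline(kill, X, y, split)
  expect_false(evk$valid)
  expect_equal(unname(evk$fitness), c(-Inf, -Inf))
  ev2 <- evaluate_pipeline(qtl_pipeline(), X, y, split)
  expect_identical(ev$fitness, ev2$fitness)
  expect_error(evaluate_pipeline(qtl_pipeline(), X, rep(1, 80), split),
               "constant")
})

test_that("evolution is reproducible and generation zero is the random start", {
  X <- random_genotypes(120, 5, seed = 37)
  y <- as.vector(X %*% c(1, -1, 0.5, 0, 0)) + withr::with_seed(38, rnorm(120, 0, 2))
  cfg <- gp_config(population_size = 12, offspring_size = 12,
                   generations = 3, seed = 5)
  r1 <- evolve(X, y, cfg)
  r2 <- evolve(X, y, cfg)
  expect_identical(r1$archive, r2$archive)
  expect_identical(r1$log, r2$log)
  expect_equal(nrow(r1$log), 4)          # generation 0 plus 3
  r0 <- evolve(X, y, gp_config(population_size = 12, offspring_size = 12,
                               generations = 0, seed = 5))
  expect_equal(nrow(r0$log), 1)
  fit0 <- do.call(rbind, lapply(r0$archive, `[[`, "fitness"))
  expect_true(all(nondominated_sort(fit0) == 1))
  expect_error(gp_config(mutation_rate = 0.9, crossover_rate = 0.2), "<= 1")
})

test_that("front summaries count roots and final inheritance models", {
  recs <- c(replicate(4, list(pipeline = qtl_pipeline(root = regressor_spec("LR")),
                              fitness = c(test_r2 = 0.1, ds = 2), train_r2 = 0.1),
                      simplify = FALSE),
            list(list(pipeline = qtl_pipeline(
                        list(list(class = "encoder", name = "heterosis")),
                        regressor_spec("RF")),
                      fitness = c(test_r2 = 0.2, ds = 1), train_r2 = 0.2)))
  s <- summarize_front(recs)
  expect_equal(s$root_census$percent[s$root_census$class == "LR"], 80)
  expect_equal(s$root_census$percent[s$root_census$class == "RF"], 20)
  expect_equal(s$encoding_census$class, c("2-level", "additive"))
  expect_error(summarize_front(list()), "empty")
  expect_equal(final_encoding_class(recs[[5]]$pipeline), "2-level")
  expect_equal(final_encoding_class(qtl_pipeline()), "additive")
  und <- qtl_pipeline(list(list(class = "encoder", name = "underdominance")))
  expect_equal(final_encoding_class(und), "3-level")
})
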