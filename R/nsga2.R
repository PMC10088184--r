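#' Pareto domination (maximize both objectives)
#'
#' `a` dominates `b` when it is at least as good in both objectives and
#' strictly better in at least one.
#'
#' @param a,b numeric fitness vectors of equal length.
#' @export
dominates <- function(a, b) {
  all(a >= b) && any(a > b)
}

#' Fast non-dominated sorting
#'
#' Sorts fitness rows into Pareto fronts (front 1 = non-dominated set of the
#' whole input), maximizing every objective.
#'
#' @param fitness numeric matrix, one row per candidate.
#' @return integer vector of front ranks (1 = best).
#' @export
nondominated_sort <- function(fitness) {
  n <- nrow(fitness)
  rank <- integer(n)
  dominated_by <- vector("list", n)
  n_dominating <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(fitness[i, ], fitness[j, ])) {
        dominated_by[[i]] <- c(dominated_by[[i]], j)
      } else if (dominates(fitness[j, ], fitness[i, ])) {
        n_dominating[i] <- n_dominating[i] + 1L
      }
    }
  }
  front <- which(n_dominating == 0L)
  level <- 1L
  while (length(front)) {
    rank[front] <- level
    nxt <- integer(0)
    for (i in front) {
      for (j in dominated_by[[i]]) {
        n_dominating[j] <- n_dominating[j] - 1L
        if (n_dominating[j] == 0L) nxt <- c(nxt, j)
      }
    }
    front <- sort(unique(nxt))
    level <- level + 1L
  }
  rank
}

#' Crowding distance within a front
#'
#' Per objective, boundary candidates get infinite distance; interior
#' candidates accumulate the normalized gap between their neighbours in the
#' objective's sorted order.
#'
#' @param fitness numeric matrix, one row per candidate (a single front).
#' @return numeric vector of crowding distances.
#' @export
crowding_distance <- function(fitness) {
  n <- nrow(fitness)
  d <- numeric(n)
  if (n <= 2) return(rep(Inf, n))
  for (k in seq_len(ncol(fitness))) {
    o <- order(fitness[, k], seq_len(n))
    d[o[c(1, n)]] <- Inf
    rng <- fitness[o[n], k] - fitness[o[1], k]
    if (is.finite(rng) && rng > 0) {
      gaps <- (fitness[o[3:n], k] - fitness[o[1:(n - 2)], k]) / rng
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] + gaps
    }
  }
  d
}

#' NSGA-II survival selection
#'
#' Fills the next population front by front (fast non-dominated sorting,
#' maximizing both objectives); the last, partially admitted front is ordered
#' by decreasing crowding distance, ties broken by input index, making the
#' selection deterministic given the input order.
#'
#' @param fitness numeric matrix, one row per candidate.
#' @param k number of survivors (k <= rows).
#' @return integer indices of the selected candidates.
#' @export
nsga2_select <- function(fitness, k) {
  stopifnot(k <= nrow(fitness))
  rank <- nondominated_sort(fitness)
  selected <- integer(0)
  for (lev in sort(unique(rank))) {
    front <- which(rank == lev)
    if (length(selected) + length(front) <= k) {
      selected <- c(selected, front)
    } else {
      need <- k - length(selected)
      cd <- crowding_distance(fitness[front, , drop = FALSE])
      selected <- c(selected, front[order(-cd, seq_along(front))[seq_len(need)]])
    }
    if (length(selected) >= k) break
  }
  selected
}
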