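# Brute-force NSGA-II survival oracle: domination ranks by direct pairwise
# scan, crowding distance re-derived from the definition. Kept independent of
# the package implementation.
oracle_select <- function(fitness, k) {
  n <- nrow(fitness)
  dominated <- function(i, pool) {
    any(vapply(pool, function(j) {
      i != j && all(fitness[j, ] >= fitness[i, ]) && any(fitness[j, ] > fitness[i, ])
    }, logical(1)))
  }
  remaining <- seq_len(n)
  rank <- integer(n)
  lev <- 1L
  while (length(remaining)) {
    front <- remaining[!vapply(remaining, dominated, logical(1), pool = remaining)]
    rank[front] <- lev
    remaining <- setdiff(remaining, front)
    lev <- lev + 1L
  }
  crowd <- function(front) {
    d <- numeric(length(front))
    for (kk in seq_len(ncol(fitness))) {
      v <- fitness[front, kk]
      o <- order(v, seq_along(v))
      d[o[c(1, length(front))]] <- Inf
      if (length(front) > 2) {
        rng <- v[o[length(front)]] - v[o[1]]
        for (s in 2:(length(front) - 1)) {
          d[o[s]] <- if (is.finite(rng) && rng > 0)
            d[o[s]] + (v[o[s + 1]] - v[o[s - 1]]) / rng else d[o[s]]
        }
      }
    }
    d
  }
  chosen <- integer(0)
  for (lev in sort(unique(rank))) {
    front <- which(rank == lev)
    if (length(chosen) + length(front) <= k) {
      chosen <- c(chosen, front)
    } else {
      cd <- crowd(front)
      chosen <- c(chosen, front[order(-cd, seq_along(front))[seq_len(k - length(chosen))]])
      break
    }
  }
  chosen
}
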