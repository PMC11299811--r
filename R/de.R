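# Differential evolution (rand/1/bin) for the deterministic SSE surfaces
# produced by the common-random-numbers objective. Uses R's RNG; callers seed
# before invoking. Stops at `max_gen` generations or after `stagnation`
# generations without improvement of the best objective value.
de_optimize <- function(fn, lower, upper, np = NULL, max_gen = 50,
                        stagnation = 100, f = 0.8, cr = 0.9,
                        strategy = c("local-to-best", "rand"),
                        tol = 1e-12, init = NULL) {
  strategy <- match.arg(strategy)
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  if (is.null(np)) np <- 10L * d
  np <- max(np, 5L)
  pop <- matrix(stats::runif(np * d), np, d)
  pop <- sweep(sweep(pop, 2, upper - lower, "*"), 2, lower, "+")
  if (!is.null(init)) pop[1, ] <- pmin(pmax(init, lower), upper)
  vals <- apply(pop, 1, fn)
  best_i <- which.min(vals)
  best_val <- vals[best_i]
  best_par <- pop[best_i, ]
  stag <- 0L
  trace <- data.frame(generation = 0L, best_sse = best_val)
  gen <- 0L
  nfeval <- np
  while (gen < max_gen && stag < stagnation) {
    gen <- gen + 1L
    improved <- FALSE
    for (i in seq_len(np)) {
      r <- sample.int(np - 1L, 3L)
      r <- r + (r >= i)  # three distinct indices != i
      mutant <- if (strategy == "local-to-best") {
        pop[i, ] + f * (best_par - pop[i, ]) + f * (pop[r[1], ] - pop[r[2], ])
      } else {
        pop[r[1], ] + f * (pop[r[2], ] - pop[r[3], ])
      }
      jrand <- sample.int(d, 1L)
      cross <- stats::runif(d) < cr
      cross[jrand] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      v <- fn(trial)
      nfeval <- nfeval + 1L
      if (v <= vals[i]) {
        pop[i, ] <- trial
        vals[i] <- v
        if (v < best_val - tol) {
          best_val <- v
          best_par <- trial
          improved <- TRUE
        } else if (v < best_val) {
          best_val <- v
          best_par <- trial
        }
      }
    }
    stag <- if (improved) 0L else stag + 1L
    trace <- rbind(trace, data.frame(generation = gen, best_sse = best_val))
  }
  list(par = best_par, value = best_val, generations = gen, nfeval = nfeval,
       trace = trace, converged = stag >= stagnation)
}
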