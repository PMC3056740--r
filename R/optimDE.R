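## Compact differential-evolution optimizer (rand/1/bin) used by the
## transfer-function fit: population-based, bound-constrained, seeded,
## restartable. Stops early when the best value stagnates or the
## population has collapsed.

.deOptim <- function(fn, lower, upper, popSize = 30L, maxGen = 60L,
                     seed = 1L, F = 0.8, CR = 0.9, stagnationLimit = 15L) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  withr::with_seed(seed, {
    pop <- matrix(runif(popSize * d), popSize, d)
    pop <- sweep(sweep(pop, 2L, upper - lower, "*"), 2L, lower, "+")
    vals <- apply(pop, 1L, fn)
    nev <- popSize
    initBest <- min(vals)
    best <- initBest
    stag <- 0L
    gen <- 0L
    while (gen < maxGen) {
      gen <- gen + 1L
      for (i in seq_len(popSize)) {
        idx <- sample.int(popSize, 4L)
        idx <- setdiff(idx, i)[1:3]
        v <- pop[idx[1L], ] + F * (pop[idx[2L], ] - pop[idx[3L], ])
        cross <- runif(d) < CR
        cross[sample.int(d, 1L)] <- TRUE
        trial <- ifelse(cross, v, pop[i, ])
        trial <- pmin(pmax(trial, lower), upper)
        fv <- fn(trial)
        nev <- nev + 1L
        if (fv <= vals[i]) {
          pop[i, ] <- trial
          vals[i] <- fv
        }
      }
      newBest <- min(vals)
      if (newBest < best - 1e-12 * (1 + abs(best))) {
        best <- newBest
        stag <- 0L
      } else {
        stag <- stag + 1L
      }
      if (stag >= stagnationLimit) break
      if (max(vals) - min(vals) <= 1e-13 * (1 + abs(min(vals)))) break
    }
    iBest <- which.min(vals)
    list(par = pop[iBest, ], value = vals[iBest], nEvaluations = nev,
         generationsRun = gen, improved = vals[iBest] < initBest)
  })
}
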