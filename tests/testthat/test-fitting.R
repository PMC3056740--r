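# Inverse problem: objective, optimizer, and goodness-of-fit indices.

test_that("objective is zero for a perfect fit and positive otherwise", {
  hp <- quickPair(nCells = 3000, seed = 1, nBins = 128)
  p <- opPoint()
  model <- applyTransfer(hp$t0, p)
  expect_equal(objectiveValue(hp$t0, model, p, "sse"), 0, tolerance = 1e-15)
  expect_equal(objectiveValue(hp$t0, model, p, "neg_correlation"), 0,
               tolerance = 1e-12)
  # ft = 0 against the unchanged histogram is also exact
  p0 <- opPoint(ft = 0)
  expect_equal(objectiveValue(hp$t0, hp$t0, p0, "sse"), 0, tolerance = 1e-15)
  expect_equal(objectiveValue(hp$t0, hp$t0, p0, "neg_correlation"), 0,
               tolerance = 1e-12)
  expect_gt(objectiveValue(hp$t0, hp$t, p0, "sse"), 0)
  expect_error(objectiveValue(hp$t0, quickPair(seed = 1, nBins = 32)$t, p0),
               "identical bin edges")
})

test_that("objective at the generating parameters beats a displaced alpha", {
  wins <- 0L
  for (i in 1:20) {
    hp <- quickPair(nCells = 4000, seed = 100 + i, nBins = 128)
    pTrue <- opPoint()
    pOff <- TransferParams(0.91, 0.11, dividingFraction = 0.98)
    wins <- wins + (objectiveValue(hp$t0, hp$t, pTrue) <=
                      objectiveValue(hp$t0, hp$t, pOff))
  }
  expect_gte(wins, 19L)
})

test_that("fitTransfer recovers generating parameters on synthetic data", {
  hp <- quickPair(nCells = 1e4, seed = 42, nBins = 256)
  fit <- fitTransfer(hp$t0, hp$t, FitOptions(seed = 1, nRestarts = 3))
  expect_lt(abs(alpha(fit) - 0.71), 0.03)
  expect_lt(abs(deltaAlpha(fit) - 0.11), 0.03)
  expect_lt(abs(dividingFraction(fit) - 0.98), 0.03)
  expect_true(fit@converged)
  # the reported objective re-evaluates exactly from the reported params
  expect_equal(fitObjective(fit),
               objectiveValue(hp$t0, hp$t, fittedParams(fit)),
               tolerance = 1e-9)
  expect_true(ftMoment(fit) >= 0 && ftMoment(fit) <= 1)
  expect_lt(fit@restartSpread, 0.05)
})

test_that("an undivided pair fits to a near-zero dividing fraction", {
  hp <- quickPair(nCells = 5000, seed = 3, nBins = 128)
  fit <- fitTransfer(hp$t0, hp$t0, quickFit(seed = 2))
  expect_lt(dividingFraction(fit), 0.05)
})

test_that("fitted and moment dividing fractions agree on synthetic pairs", {
  for (seed in c(7, 8, 9, 10, 11)) {
    hp <- quickPair(nCells = 5000, seed = seed, nBins = 128)
    fit <- fitTransfer(hp$t0, hp$t, quickFit(seed = seed))
    expect_lt(abs(dividingFraction(fit) - ftMoment(fit)), 0.03)
  }
})

test_that("fixing ft at the moment estimate barely moves alpha", {
  hp <- quickPair(nCells = 1e4, seed = 5, nBins = 256)
  free <- fitTransfer(hp$t0, hp$t, quickFit(seed = 4))
  fixed <- fitTransfer(hp$t0, hp$t,
                       FitOptions(seed = 4, nRestarts = 2, populationSize = 15,
                                  maxGenerations = 30,
                                  fixDividingFraction = ftMoment(free)))
  expect_identical(dividingFraction(fixed), ftMoment(free))
  expect_lt(abs(alpha(fixed) - alpha(free)), 0.02)
})

test_that("the fit is bit-reproducible given the seed", {
  hp <- quickPair(nCells = 2000, seed = 6, nBins = 64)
  o <- FitOptions(seed = 9, nRestarts = 2, populationSize = 12,
                  maxGenerations = 25)
  f1 <- fitTransfer(hp$t0, hp$t, o)
  f2 <- fitTransfer(hp$t0, hp$t, o)
  expect_identical(alpha(f1), alpha(f2))
  expect_identical(deltaAlpha(f1), deltaAlpha(f2))
  expect_identical(dividingFraction(f1), dividingFraction(f2))
  expect_identical(fitObjective(f1), fitObjective(f2))
  # a different seed explores differently but lands near the same optimum
  f3 <- fitTransfer(hp$t0, hp$t, FitOptions(seed = 10, nRestarts = 2,
                                            populationSize = 12,
                                            maxGenerations = 25))
  expect_lt(abs(alpha(f3) - alpha(f1)), 0.05)
})

test_that("parameter recovery improves with sample size", {
  errFor <- function(n, seeds) {
    e <- numeric(length(seeds))
    for (i in seq_along(seeds)) {
      hp <- quickPair(nCells = n, seed = seeds[i], nBins = 128)
      fit <- fitTransfer(hp$t0, hp$t, quickFit(seed = seeds[i]))
      e[i] <- abs(alpha(fit) - 0.71) + abs(deltaAlpha(fit) - 0.11) +
        abs(dividingFraction(fit) - 0.98)
    }
    median(e)
  }
  seeds <- 201:206
  expect_lt(errFor(1e4, seeds), errFor(1e3, seeds))
})

test_that("Poisson weighting and the correlation objective also recover", {
  hp <- quickPair(nCells = 1e4, seed = 77, nBins = 256)
  fw <- fitTransfer(hp$t0, hp$t, FitOptions(seed = 3, nRestarts = 2,
                                            populationSize = 15,
                                            maxGenerations = 30,
                                            weighting = "poisson"))
  expect_lt(abs(alpha(fw) - 0.71), 0.05)
  fc <- fitTransfer(hp$t0, hp$t, FitOptions(seed = 3, nRestarts = 2,
                                            populationSize = 15,
                                            maxGenerations = 30,
                                            objective = "neg_correlation"))
  expect_lt(abs(alpha(fc) - 0.71), 0.05)
})

test_that("goodness-of-fit indices behave as documented", {
  hp <- quickPair(nCells = 1e4, seed = 55, nBins = 256)
  # identical histograms: correlation 1, p exactly 1
  g0 <- goodnessOfFit(hp$t, hp$t)
  expect_equal(g0$correlation, 1)
  expect_equal(g0$pValue, 1)
  # well-specified model: high correlation, high p
  g1 <- goodnessOfFit(applyTransfer(hp$t0, opPoint()), hp$t)
  expect_gt(g1$correlation, 0.99)
  expect_gt(g1$pValue, 0.1)
  # a gross shape misfit is flagged by the correlation index
  g2 <- goodnessOfFit(applyTransfer(hp$t0, opPoint(ft = 0)), hp$t)
  expect_lt(g2$correlation, 0.9)
  expect_lt(g2$correlation, g1$correlation)
  # too few informative bins is an error
  tiny <- IntensityHistogram(c(0, 1, 2, 3), c(0, 1, 0))
  expect_error(goodnessOfFit(tiny, tiny), "at least 3 bins")
})

test_that("well-specified models score high p across seeds", {
  ps <- vapply(301:330, function(seed) {
    hp <- quickPair(nCells = 1e4, seed = seed, nBins = 256)
    goodnessOfFit(applyTransfer(hp$t0, opPoint()), hp$t)$pValue
  }, numeric(1))
  expect_gte(mean(ps > 0.5), 0.8)
})

test_that("fit results serialize to JSON with everything needed to re-run", {
  hp <- quickPair(nCells = 2000, seed = 60, nBins = 64)
  fit <- fitTransfer(hp$t0, hp$t, FitOptions(seed = 5, nRestarts = 1,
                                             populationSize = 12,
                                             maxGenerations = 25))
  f <- withr::local_tempfile(fileext = ".json")
  writeFitResult(fit, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$params$alpha, alpha(fit))
  expect_equal(back$seed, 5)
  expect_equal(back$objective, "sse")
  expect_length(back$bounds$lower, 3)
  expect_true(nzchar(back$package_version))
})
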