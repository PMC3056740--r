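# The partitioning density, the discretized transfer operator, the moment
# estimator, and the multi-generation extension.

test_that("partitionPdf is a symmetric, normalized, canonicalized density", {
  for (pp in list(PartitionParams(0.5, 0.1), PartitionParams(0.71, 0.11),
                  PartitionParams(0.9, 0.03))) {
    x <- seq(0, 1, length.out = 2001)
    d <- partitionPdf(x, pp)
    expect_equal(d, rev(d), tolerance = 1e-12)          # x <-> 1 - x symmetry
    q <- integrate(partitionPdf, 0, 1, params = pp, rel.tol = 1e-12)
    expect_lt(abs(q$value - 1), 1e-8)
    expect_true(all(d >= 0))
    expect_equal(partitionPdf(c(-0.1, 1.1), pp), c(0, 0))
  }
  # coincident components: global maximum at 1/2
  x <- seq(0, 1, length.out = 4001)
  expect_equal(x[which.max(partitionPdf(x, PartitionParams(0.5, 0.1)))], 0.5)
  # alpha below one half maps onto the canonical half
  expect_identical(alpha(PartitionParams(0.29, 0.11)), 0.71)
})

test_that("the fitted-operating-point density has modes near 0.29 and 0.71", {
  x <- seq(0, 1, length.out = 20001)
  d <- partitionPdf(x, PartitionParams(0.71, 0.11))
  peaks <- x[which(diff(sign(diff(d))) == -2) + 1]
  expect_length(peaks, 2)
  expect_lt(abs(min(peaks) - 0.29), 0.01)
  expect_lt(abs(max(peaks) - 0.71), 0.01)
})

test_that("rPartitionRatio draws follow the truncated mixture", {
  pp <- PartitionParams(0.71, 0.11)
  x <- withr::with_seed(7, rPartitionRatio(2e5, pp))
  expect_true(all(x >= 0 & x <= 1))
  expect_equal(mean(x), 0.5, tolerance = 0.005)   # symmetric: mean exactly 1/2
  ks <- max(abs(flowInherit:::.partitionCdf(sort(x), 0.71, 0.11) -
                (seq_along(x) - 0.5) / length(x)))
  expect_lt(ks, 0.005)
})

test_that("kernel columns are probability distributions for random params", {
  edges <- seq(0, 100, length.out = 65)
  withr::with_seed(11, {
    for (i in 1:100) {
      p <- TransferParams(runif(1, 0.5, 1), runif(1, 0.01, 0.5),
                          dividingFraction = runif(1))
      K <- kernelMatrix(buildKernel(edges, edges, p))
      expect_true(all(K >= 0))
      expect_lt(max(abs(colSums(K) - 1)), 1e-6)
    }
  })
})

test_that("kernel limits: identity at ft = 0, halving at ft = 1", {
  edges <- seq(0, 200, length.out = 101)
  p0 <- TransferParams(0.71, 0.11, dividingFraction = 0)
  expect_equal(kernelMatrix(buildKernel(edges, edges, p0)), diag(100),
               ignore_attr = TRUE)
  # near-deterministic symmetric halving: parent mass at 100 -> mass at 50
  p1 <- TransferParams(0.5, 0.01, dividingFraction = 1)
  h <- IntensityHistogram(edges, replace(numeric(100), 50, 1000))  # bin [98,100)
  out <- applyTransfer(h, p1)
  mids <- (edges[-1] + edges[-101]) / 2
  expect_lt(abs(sum(counts(out) * mids) / sum(counts(out)) - 49.5), 2)
  expect_gt(sum(counts(out)[mids > 45 & mids < 55]) / sum(counts(out)), 0.99)
})

test_that("alpha and 1 - alpha parameterize the same operator", {
  edges <- seq(0, 100, length.out = 65)
  Ka <- buildKernel(edges, edges, TransferParams(0.75, 0.1, dividingFraction = 0.8))
  Kb <- buildKernel(edges, edges, TransferParams(0.25, 0.1, dividingFraction = 0.8))
  expect_identical(kernelMatrix(Ka), kernelMatrix(Kb))
})

test_that("a too-narrow destination range is refused, not silently truncated", {
  p <- TransferParams(0.71, 0.11, dividingFraction = 1)
  # daughters of parents at 100-200 land mostly below the destination floor
  expect_error(buildKernel(seq(100, 200, 10), seq(90, 200, 10), p),
               "widen the destination range")
})

test_that("applyTransfer conserves mass and obeys the mean-dilution identity", {
  h <- smoothParentHist()
  withr::with_seed(13, {
    for (i in 1:40) {
      p <- TransferParams(runif(1, 0.5, 1), runif(1, 0.01, 0.4),
                          dividingFraction = runif(1))
      out <- applyTransfer(h, p)
      expect_equal(sum(counts(out)), sum(counts(h)), tolerance = 1e-6)
      ratio <- meanIntensity(out) / meanIntensity(h)
      expect_equal(ratio, 1 - dividingFraction(p) / 2, tolerance = 0.01)
    }
  })
  # identity at ft = 0 and scale-mismatch guard
  p0 <- TransferParams(0.71, 0.11, dividingFraction = 0)
  expect_equal(counts(applyTransfer(h, p0)), counts(h), tolerance = 1e-12)
  hl <- IntensityHistogram(logEdges(1, 100, 8), rep(1, 8), scale = "log")
  expect_error(applyTransfer(hl, p0), "linear")
})

test_that("mean intensity is non-increasing in the dividing fraction", {
  h <- smoothParentHist()
  m <- vapply(seq(0, 1, 0.1), function(ft)
    meanIntensity(applyTransfer(h, TransferParams(0.71, 0.11,
                                                  dividingFraction = ft))),
    numeric(1))
  expect_true(all(diff(m) < 0))
})

test_that("matrix kernel and streaming forward application agree", {
  h <- quickPair(nCells = 3000, seed = 8, nBins = 128)$t0
  p <- TransferParams(0.8, 0.07, dividingFraction = 0.6)
  viaKernel <- as.numeric(kernelMatrix(buildKernel(binEdges(h), binEdges(h), p))
                          %*% counts(h))
  viaStream <- counts(applyTransfer(h, p))
  expect_equal(viaStream, viaKernel, tolerance = 1e-12)
})

test_that("forward model matches the event-level simulator in distribution", {
  cfg <- SimConfig(nCells = 1e5, seed = 17)
  hp <- sampleToHistograms(simulatePair(cfg), nBins = 256)
  out <- applyTransfer(hp$t0, cfg@params)
  expect_lt(ksDistance(out, hp$t), 0.02)
})

test_that("moment estimator of the dividing fraction", {
  h <- IntensityHistogram(c(0, 1, 2), c(5, 5))
  expect_equal(as.numeric(estimateDividingFraction(h, h)), 0)   # no dilution
  # mean ratio exactly one half -> full division
  h2 <- IntensityHistogram(c(0, 1, 2), c(5, 5))                 # mean 1.0
  hHalf <- IntensityHistogram(c(0, 1, 2), c(10, 0))             # mean 0.5
  expect_equal(as.numeric(estimateDividingFraction(h2, hHalf)), 1,
               tolerance = 1e-9)
  # a later mean below half the initial mean clamps, and says so
  hHi <- IntensityHistogram(c(0, 1, 2), c(0, 10))               # mean 1.5
  hLow <- IntensityHistogram(c(0, 1, 2), c(100, 1))             # mean ~0.51
  expect_message(est <- estimateDividingFraction(hHi, hLow), "clamped")
  expect_true(attr(est, "clamped"))
  expect_equal(as.numeric(est), 1)
  # simulator truth recovered within 0.03 at n = 1e4
  hp <- quickPair(nCells = 1e4, seed = 19, nBins = 256, ft = 0.7)
  expect_equal(as.numeric(estimateDividingFraction(hp$t0, hp$t)), 0.7,
               tolerance = 0.03)
})

test_that("multi-generation ratio density: reduction, modes, normalization", {
  pp <- PartitionParams(0.71, 0.05)
  xg <- seq(0, 1, length.out = 64)
  expect_equal(multigenerationRatioPdf(xg, pp, 1), partitionPdf(xg, pp),
               tolerance = 1e-6)
  expect_error(multigenerationRatioPdf(xg, pp, 0), "positive integer")

  # k = 2: modes near the pairwise products of the component means
  # (0.71^2 = 0.5041, 0.71*0.29 = 0.2059 twice, 0.29^2 = 0.0841);
  # frozen locations 0.4995, 0.2030, 0.0805 confirmed against a 1e6-draw
  # Monte-Carlo product of two independent ratios.
  x <- seq(0.001, 1, 0.0005)
  f2 <- multigenerationRatioPdf(x, pp, 2)
  peaks <- sort(x[which(diff(sign(diff(f2))) == -2) + 1])
  expect_length(peaks, 3)
  expect_lt(max(abs(peaks - c(0.0841, 0.2059, 0.5041))), 0.01)

  for (k in 1:3) {
    q <- logTrapIntegral(function(z)
      multigenerationRatioPdf(z, PartitionParams(0.71, 0.11), k))
    expect_lt(abs(q - 1), 1e-6)
  }
})

test_that("k = 2 product density matches the Monte-Carlo product of ratios", {
  pp <- PartitionParams(0.71, 0.05)
  r2 <- withr::with_seed(23, rPartitionRatio(2e5, pp) * rPartitionRatio(2e5, pp))
  cdf2 <- flowInherit:::.multigenRatioCdf(pp, 2L)
  ks <- max(abs(cdf2(sort(r2)) - (seq_along(r2) - 0.5) / length(r2)))
  expect_lt(ks, 0.02)
})

test_that("transfer params serialize to and from flat configs", {
  p <- TransferParams(0.71, 0.11, dividingFraction = 0.98, intervalH = 19,
                      generations = 2L, generationFractions = c(0.98, 0.4))
  cfgList <- transferParamsToConfig(p)
  expect_named(cfgList, c("alpha", "delta_alpha", "dividing_fraction",
                          "interval_h", "generations", "generation_fractions"))
  back <- transferParamsFromConfig(cfgList)
  expect_equal(alpha(back), 0.71)
  expect_equal(generationFractions(back), c(0.98, 0.4))
  expect_error(transferParamsFromConfig(list(alpha = 0.7)), "missing required")
})
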