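# Shared fixture builders: everything is generated in code at test time.

# The experimental operating point used as generating truth throughout.
opPoint <- function(ft = 0.98) {
  TransferParams(0.71, 0.11, dividingFraction = ft, intervalH = 19)
}

# Small synthetic histogram pair at the operating point.
quickPair <- function(nCells = 2000, seed = 1, nBins = 64, ft = 0.98) {
  cfg <- SimConfig(nCells = nCells, seed = seed, params = opPoint(ft))
  sampleToHistograms(simulatePair(cfg), nBins = nBins)
}

# A broad deterministic (noise-free) log-normal-shaped histogram, used
# where sampling noise would obscure an analytic identity.
smoothParentHist <- function(nBins = 256, meanlog = log(1000), sdlog = 0.5) {
  hi <- exp(meanlog + 4 * sdlog)
  edges <- seq(0, hi, length.out = nBins + 1)
  mids <- (edges[-1] + edges[-(nBins + 1)]) / 2
  IntensityHistogram(edges, stats::dlnorm(mids, meanlog, sdlog), "linear")
}

# Reduced-budget optimizer options for module-level fits.
quickFit <- function(seed = 1, nRestarts = 2) {
  FitOptions(seed = seed, nRestarts = nRestarts, populationSize = 15,
             maxGenerations = 30)
}

# Trapezoid quadrature on a log-spaced grid, resolving the 1/x factor of
# ratio densities near zero.
logTrapIntegral <- function(f, n = 200001, xMin = 1e-9) {
  s <- seq(log(xMin), 0, length.out = n)
  y <- f(exp(s)) * exp(s)
  sum((y[-1] + y[-n]) / 2) * (s[2] - s[1])
}
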