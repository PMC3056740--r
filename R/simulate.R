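## Monte-Carlo single-cell population generator: the synthetic-data source
## and event-level brute-force oracle for the transfer model.

## One division round applied in place. state is a list with fields
## i0, cur (intensities), curK (organelle counts or NULL), nDiv, ratio.
.divideOnce <- function(state, fraction, config) {
  n <- length(state$cur)
  div <- runif(n) < fraction
  m <- sum(div)
  if (m == 0L) {
    state$last <- logical(n)
    return(state)
  }
  part <- config@params@partition
  x <- if (config@biasMode == "fixed") rep(part@alpha, m)
       else rPartitionRatio(m, part)
  keepA <- runif(m) < 0.5
  if (config@partitionMode == "ratio") {
    r <- ifelse(keepA, x, 1 - x)
    state$cur[div] <- state$cur[div] * r
    state$ratio[div] <- state$ratio[div] * r
  } else {
    k <- state$curK[div]
    toA <- rbinom(m, k, x)
    kept <- ifelse(keepA, toA, k - toA)
    pos <- k > 0L                        # unlabeled cells split trivially
    r <- rep(1, m)
    r[pos] <- kept[pos] / k[pos]
    state$curK[div] <- kept
    state$cur[div] <- kept * config@unitIntensity
    state$ratio[div] <- state$ratio[div] * r
  }
  state$nDiv[div] <- state$nDiv[div] + 1L
  state$last <- div
  state
}

.simulateCore <- function(config, fractions) {
  withr::with_seed(config@seed, {
    n <- config@nCells
    if (config@partitionMode == "ratio") {
      i0 <- rlnorm(n, config@initLogMean, config@initLogSd)
      curK <- NULL
    } else {
      k0 <- rpois(n, config@organellesMean)
      while (any(k0 == 0L))              # zero-truncated: unlabeled cells
        k0[k0 == 0L] <- rpois(sum(k0 == 0L), config@organellesMean)
      i0 <- k0 * config@unitIntensity
      curK <- k0
    }
    state <- list(i0 = i0, cur = i0, curK = curK,
                  nDiv = integer(n), ratio = rep(1, n))
    for (f in fractions) {
      if (config@retainBoth) {
        ## keep both daughters: simulate the kept daughter as usual, then
        ## append the sibling rows (ratio complemented)
        pre <- state
        state <- .divideOnce(state, f, config)
        div <- state$last
        if (any(div)) {
          sibR <- pre$cur[div] * (1 - state$cur[div] / pre$cur[div])
          state$i0 <- c(state$i0, pre$i0[div])
          state$cur <- c(state$cur, sibR)
          if (!is.null(state$curK))
            state$curK <- c(state$curK, pre$curK[div] - state$curK[div])
          state$nDiv <- c(state$nDiv, state$nDiv[div])
          state$ratio <- c(state$ratio,
                           pre$ratio[div] * (sibR / pre$cur[div]))
        }
      } else {
        state <- .divideOnce(state, f, config)
      }
    }
    new("PopulationSample", intensitiesT0 = state$i0,
        intensitiesT = state$cur, nDivisions = state$nDiv,
        realizedRatios = state$ratio)
  })
}

#' Simulate a paired two-time-point measurement
#'
#' Draws \code{nCells} parent intensities from a log-normal distribution
#' (a broad unimodal parent population), lets each cell divide once with
#' probability \code{dividingFraction} within the interval, and for each
#' divider draws a splitting ratio x from the truncated mixture and retains
#' ONE daughter uniformly at random (intensity x I0 or (1 - x) I0 with
#' probability 1/2 each), keeping the sampled population size constant —
#' the condition under which the moment estimator of f_t is valid. In
#' organelle mode the cell's discrete labelled organelles are instead
#' assigned binomially with bias x and intensity is organelle count times
#' \code{unitIntensity}, building in exact fluorescence/organelle
#' linearity. Deterministic given \code{config@seed}.
#'
#' @param config a \linkS4class{SimConfig}
#' @return a \linkS4class{PopulationSample}
#' @seealso \code{\link{sampleToHistograms}},
#'   \code{\link{simulateMultigeneration}}
#' @examples
#' s <- simulatePair(SimConfig(nCells = 500, seed = 3))
#' mean(intensities(s)$t) / mean(intensities(s)$t0)  # ~ 1 - ft/2
#' @export
simulatePair <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (config@params@generations != 1L)
    stop("simulatePair models a single generation; ",
         "use simulateMultigeneration for generations > 1")
  .simulateCore(config, config@params@dividingFraction)
}

#' Simulate several division rounds
#'
#' Applies the single-generation division step k times, each round with its
#' own dividing fraction, retaining one random descendant per lineage (or
#' both, in \code{retainBoth} mode). The realized per-cell cumulative ratio
#' is the product of the per-generation retained fractions. With
#' \code{k = 1} this is exactly \code{\link{simulatePair}} (same seed, same
#' output).
#'
#' @param config a \linkS4class{SimConfig}
#' @param k number of generations (>= 1)
#' @param fractions per-generation dividing fractions of length k; defaults
#'   to \code{generationFractions(config@params)} when those have length k,
#'   else to the single dividing fraction repeated
#' @return a \linkS4class{PopulationSample}
#' @export
simulateMultigeneration <- function(config, k, fractions = NULL) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  if (is.null(fractions)) {
    gf <- config@params@generationFractions
    fractions <- if (length(gf) == k) gf
                 else rep(config@params@dividingFraction, k)
  }
  if (length(fractions) != k)
    stop("fractions must have length k = ", k)
  if (any(fractions < 0 | fractions > 1))
    stop("fractions must lie in [0, 1]")
  .simulateCore(config, fractions)
}

#' Bin a simulated sample into a histogram pair
#'
#' Bins the time-0 and time-t intensities onto one shared edge set, as the
#' fitting functions require. The default edges span [0, max intensity]
#' linearly, so no divided mass can fall outside the range.
#'
#' @param sample a \linkS4class{PopulationSample}
#' @param edges shared bin edges, or NULL to build \code{nBins} linear bins
#'   from 0 to the sample maximum
#' @param nBins number of bins when \code{edges} is NULL (default 256, a
#'   typical cytometer histogram resolution)
#' @return list with elements \code{t0} and \code{t}
#'   (\linkS4class{IntensityHistogram}s on identical edges)
#' @export
sampleToHistograms <- function(sample, edges = NULL, nBins = 256L) {
  stopifnot(is(sample, "PopulationSample"))
  allI <- c(sample@intensitiesT0, sample@intensitiesT)
  if (is.null(edges))
    edges <- seq(0, max(allI) * (1 + 1e-9), length.out = nBins + 1L)
  pos0 <- sample@intensitiesT0 > 0
  post <- sample@intensitiesT > 0
  if (!all(post))
    message("sampleToHistograms: ", sum(!post),
            " zero-intensity (unlabeled) cells at time t excluded")
  h0 <- binEvents(EventList(sample@intensitiesT0[pos0], label = "t0",
                            timeH = 0), edges)
  ht <- binEvents(EventList(sample@intensitiesT[post], label = "t",
                            timeH = 0), edges)
  list(t0 = h0, t = ht)
}
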