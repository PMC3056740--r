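## S4 containers for the transfer-function analysis. All fluorescence
## intensities are in arbitrary units (AU); splitting ratios are
## dimensionless fractions in [0, 1].

## ---------------------------------------------------------------- EventList

#' Per-cell fluorescence events
#'
#' One total-fluorescence value per cell, as produced by a flow or imaging
#' cytometer (after instrument-side gating). Intensities must be finite and
#' strictly positive.
#'
#' @slot intensities numeric, per-cell total fluorescence (AU)
#' @slot label single sample identifier
#' @slot timeH measurement time in hours relative to the first measurement
#'
#' @param intensities numeric vector of positive, finite intensities
#' @param label sample identifier
#' @param timeH measurement time (hours)
#' @return an \code{EventList}
#' @seealso \code{\link{readEvents}}, \code{\link{binEvents}}
#' @examples
#' ev <- EventList(c(10, 20, 30), label = "t0")
#' meanIntensity(ev)
#' @aliases intensities,EventList-method timeH,EventList-method
#'   meanIntensity,EventList-method
#' @export EventList
#' @exportClass EventList
EventList <- function(intensities, label = "sample", timeH = 0) {
  new("EventList", intensities = as.numeric(intensities),
      label = as.character(label)[1], timeH = as.numeric(timeH)[1])
}

setClass("EventList",
  slots = c(intensities = "numeric", label = "character", timeH = "numeric"))

setValidity("EventList", function(object) {
  msg <- character()
  if (length(object@intensities) < 1L)
    msg <- c(msg, "intensities must be non-empty")
  else if (!all(is.finite(object@intensities)) || any(object@intensities <= 0))
    msg <- c(msg, "all intensities must be finite and > 0")
  if (length(object@label) != 1L || is.na(object@label))
    msg <- c(msg, "label must be a single string")
  if (length(object@timeH) != 1L || !is.finite(object@timeH))
    msg <- c(msg, "timeH must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("intensities", "EventList", function(x) x@intensities)
#' @export
setMethod("timeH", "EventList", function(x) x@timeH)
#' @export
setMethod("meanIntensity", "EventList", function(x) mean(x@intensities))

setMethod("show", "EventList", function(object) {
  cat("EventList '", object@label, "': ", length(object@intensities),
      " cells at t = ", object@timeH, " h; mean intensity ",
      format(mean(object@intensities), digits = 5), " AU\n", sep = "")
})

## ------------------------------------------------------- IntensityHistogram

.detectScale <- function(edges) {
  if (length(edges) < 3L) return("linear")
  d <- diff(edges)
  if ((max(d) - min(d)) <= 1e-9 * max(abs(d))) return("linear")
  if (all(edges > 0)) {
    r <- edges[-1L] / edges[-length(edges)]
    if (max(r) / min(r) - 1 <= 1e-9) return("log")
  }
  "linear"
}

#' Binned fluorescence-intensity histogram
#'
#' Cell counts over intensity bins; the state function N(I) of the transfer
#' model. Bins follow the half-open convention [lo, hi) with the final bin
#' closed. \code{scale} records the binning dialect: \code{"linear"}
#' (constant width) or \code{"log"} (constant edge ratio, the log-amplifier
#' output of most flow cytometers). Counts may be fractional after rebinning
#' or forward-model application; only raw event binning is integer.
#'
#' @slot binEdges strictly increasing bin edges (AU), length B + 1
#' @slot counts non-negative per-bin cell counts, length B
#' @slot scale \code{"linear"} or \code{"log"}
#' @slot timeH measurement time (hours)
#'
#' @param binEdges strictly increasing numeric vector of edges
#' @param counts per-bin counts (at least one positive)
#' @param scale \code{"linear"}, \code{"log"}, or NULL to detect from the
#'   edge spacing
#' @param timeH measurement time (hours)
#' @return an \code{IntensityHistogram}
#' @seealso \code{\link{binEvents}}, \code{\link{logToLinearRebin}},
#'   \code{\link{meanIntensity}}, \code{\link{readHistogram}}
#' @examples
#' h <- IntensityHistogram(c(0, 2, 4), c(1, 1))
#' meanIntensity(h)
#' @aliases binEdges,IntensityHistogram-method counts,IntensityHistogram-method
#'   histScale,IntensityHistogram-method timeH,IntensityHistogram-method
#'   meanIntensity,IntensityHistogram-method
#' @export IntensityHistogram
#' @exportClass IntensityHistogram
IntensityHistogram <- function(binEdges, counts, scale = NULL, timeH = 0) {
  binEdges <- as.numeric(binEdges)
  if (is.null(scale)) scale <- .detectScale(binEdges)
  new("IntensityHistogram", binEdges = binEdges, counts = as.numeric(counts),
      scale = scale, timeH = as.numeric(timeH)[1])
}

setClass("IntensityHistogram",
  slots = c(binEdges = "numeric", counts = "numeric", scale = "character",
            timeH = "numeric"))

setValidity("IntensityHistogram", function(object) {
  msg <- character()
  e <- object@binEdges; ct <- object@counts
  if (length(e) < 2L || !all(is.finite(e)) || any(diff(e) <= 0))
    msg <- c(msg, "binEdges must be finite and strictly increasing (>= 2 edges)")
  if (length(ct) != length(e) - 1L)
    msg <- c(msg, "counts must have length length(binEdges) - 1")
  if (!all(is.finite(ct)) || any(ct < 0))
    msg <- c(msg, "counts must be finite and >= 0")
  else if (!any(ct > 0))
    msg <- c(msg, "at least one count must be > 0")
  if (length(object@scale) != 1L || !object@scale %in% c("linear", "log"))
    msg <- c(msg, "scale must be 'linear' or 'log'")
  else if (object@scale == "log" && length(e) >= 3L) {
    if (any(e <= 0)) {
      msg <- c(msg, "log-scale edges must be positive")
    } else {
      r <- e[-1L] / e[-length(e)]
      if (max(r) / min(r) - 1 > 1e-9)
        msg <- c(msg, "log-scale edges must have a constant ratio (rel. tol. 1e-9)")
    }
  }
  if (length(object@timeH) != 1L || !is.finite(object@timeH))
    msg <- c(msg, "timeH must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("binEdges", "IntensityHistogram", function(x) x@binEdges)
#' @export
setMethod("counts", "IntensityHistogram", function(object, ...) object@counts)
#' @export
setMethod("histScale", "IntensityHistogram", function(x) x@scale)
#' @export
setMethod("timeH", "IntensityHistogram", function(x) x@timeH)

setMethod("show", "IntensityHistogram", function(object) {
  cat("IntensityHistogram: ", length(object@counts), " ", object@scale,
      " bins over [", format(object@binEdges[1], digits = 4), ", ",
      format(object@binEdges[length(object@binEdges)], digits = 4),
      "] AU at t = ", object@timeH, " h\n  total count ",
      format(sum(object@counts), digits = 8), ", mean intensity ",
      format(meanIntensity(object), digits = 5), " AU\n", sep = "")
})

## --------------------------------------------------------- PartitionParams

#' Splitting-ratio distribution parameters
#'
#' Mean \code{alpha} and spread \code{deltaAlpha} of the mitotic splitting
#' ratio: a daughter inherits a fraction x of the parent's labelled
#' material, the sibling 1 - x, with x drawn from an equal-weight mixture
#' of Normal(alpha, deltaAlpha^2) and Normal(1 - alpha, deltaAlpha^2)
#' truncated to [0, 1]. Because alpha and 1 - alpha parameterize the same
#' distribution, the constructor canonicalizes alpha into [0.5, 1].
#'
#' @slot alpha mean splitting ratio, in [0.5, 1] after canonicalization
#' @slot deltaAlpha spread of the splitting ratio, in (0, 0.5]
#'
#' @param alpha mean splitting ratio in [0, 1]; values below 0.5 are mapped
#'   to 1 - alpha
#' @param deltaAlpha positive spread, at most 0.5
#' @return a \code{PartitionParams}
#' @seealso \code{\link{partitionPdf}}, \code{\link{TransferParams}}
#' @examples
#' PartitionParams(0.71, 0.11)
#' identical(alpha(PartitionParams(0.29, 0.1)), alpha(PartitionParams(0.71, 0.1)))
#' @aliases alpha,PartitionParams-method deltaAlpha,PartitionParams-method
#' @export PartitionParams
#' @exportClass PartitionParams
PartitionParams <- function(alpha, deltaAlpha) {
  alpha <- as.numeric(alpha)[1]
  if (is.finite(alpha) && alpha < 0.5) alpha <- 1 - alpha
  new("PartitionParams", alpha = alpha, deltaAlpha = as.numeric(deltaAlpha)[1])
}

setClass("PartitionParams", slots = c(alpha = "numeric", deltaAlpha = "numeric"))

setValidity("PartitionParams", function(object) {
  msg <- character()
  a <- object@alpha; s <- object@deltaAlpha
  if (length(a) != 1L || !is.finite(a) || a < 0.5 || a > 1)
    msg <- c(msg, "alpha must be a single number in [0.5, 1] (canonical half)")
  if (length(s) != 1L || !is.finite(s) || s <= 0 || s > 0.5)
    msg <- c(msg, "deltaAlpha must be a single number in (0, 0.5]")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("alpha", "PartitionParams", function(x) x@alpha)
#' @export
setMethod("deltaAlpha", "PartitionParams", function(x) x@deltaAlpha)

setMethod("show", "PartitionParams", function(object) {
  cat("PartitionParams: alpha = ", object@alpha,
      ", deltaAlpha = ", object@deltaAlpha, "\n", sep = "")
})

## ---------------------------------------------------------- TransferParams

#' Transfer-function parameters
#'
#' The full parameter set of the transfer operator: the splitting-ratio
#' distribution, the dividing fraction \code{ft} (fraction of cells that
#' underwent mitosis during the measurement interval), the interval length,
#' and optionally a multi-generation schedule of per-generation dividing
#' fractions.
#'
#' @slot partition a \linkS4class{PartitionParams}
#' @slot dividingFraction f_t in [0, 1] (first-generation fraction)
#' @slot intervalH time between the two measurements (hours)
#' @slot generations number of division rounds modelled (default 1)
#' @slot generationFractions per-generation dividing fractions, length
#'   \code{generations}
#'
#' @param alpha,deltaAlpha splitting-ratio parameters (ignored when
#'   \code{partition} is supplied)
#' @param dividingFraction fraction of cells dividing in generation 1
#' @param intervalH measurement interval in hours
#' @param generations number of division rounds
#' @param generationFractions per-generation fractions (defaults to
#'   \code{dividingFraction} when \code{generations == 1})
#' @param partition optional \linkS4class{PartitionParams}
#' @return a \code{TransferParams}
#' @seealso \code{\link{buildKernel}}, \code{\link{applyTransfer}},
#'   \code{\link{fitTransfer}}
#' @examples
#' TransferParams(0.71, 0.11, dividingFraction = 0.98, intervalH = 19)
#' @aliases alpha,TransferParams-method deltaAlpha,TransferParams-method
#'   dividingFraction,TransferParams-method intervalH,TransferParams-method
#'   generations,TransferParams-method generationFractions,TransferParams-method
#'   partitionParams,TransferParams-method
#' @export TransferParams
#' @exportClass TransferParams
TransferParams <- function(alpha, deltaAlpha, dividingFraction,
                           intervalH = 19, generations = 1L,
                           generationFractions = NULL, partition = NULL) {
  if (is.null(partition)) partition <- PartitionParams(alpha, deltaAlpha)
  generations <- as.integer(generations)
  if (is.null(generationFractions)) {
    if (generations == 1L) generationFractions <- as.numeric(dividingFraction)[1]
    else stop("generationFractions must be supplied when generations > 1")
  }
  new("TransferParams", partition = partition,
      dividingFraction = as.numeric(dividingFraction)[1],
      intervalH = as.numeric(intervalH)[1], generations = generations,
      generationFractions = as.numeric(generationFractions))
}

setClass("TransferParams",
  slots = c(partition = "PartitionParams", dividingFraction = "numeric",
            intervalH = "numeric", generations = "integer",
            generationFractions = "numeric"))

setValidity("TransferParams", function(object) {
  msg <- character()
  ft <- object@dividingFraction
  if (length(ft) != 1L || !is.finite(ft) || ft < 0 || ft > 1)
    msg <- c(msg, "dividingFraction must be a single number in [0, 1]")
  if (length(object@intervalH) != 1L || !is.finite(object@intervalH) ||
      object@intervalH < 0)
    msg <- c(msg, "intervalH must be a single non-negative number")
  k <- object@generations
  if (length(k) != 1L || is.na(k) || k < 1L)
    msg <- c(msg, "generations must be a positive integer")
  gf <- object@generationFractions
  if (length(k) == 1L && !is.na(k) && length(gf) != k)
    msg <- c(msg, "generationFractions must have length equal to generations")
  if (!all(is.finite(gf)) || any(gf < 0) || any(gf > 1))
    msg <- c(msg, "generationFractions must lie in [0, 1]")
  if (length(gf) >= 1L && length(ft) == 1L && is.finite(ft) &&
      abs(gf[1] - ft) > 1e-12)
    msg <- c(msg, "generationFractions[1] must equal dividingFraction")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("partitionParams", "TransferParams", function(x) x@partition)
#' @export
setMethod("alpha", "TransferParams", function(x) x@partition@alpha)
#' @export
setMethod("deltaAlpha", "TransferParams", function(x) x@partition@deltaAlpha)
#' @export
setMethod("dividingFraction", "TransferParams", function(x) x@dividingFraction)
#' @export
setMethod("intervalH", "TransferParams", function(x) x@intervalH)
#' @export
setMethod("generations", "TransferParams", function(x) x@generations)
#' @export
setMethod("generationFractions", "TransferParams", function(x) x@generationFractions)

setMethod("show", "TransferParams", function(object) {
  cat("TransferParams: alpha = ", object@partition@alpha,
      ", deltaAlpha = ", object@partition@deltaAlpha,
      ", ft = ", object@dividingFraction,
      ", interval = ", object@intervalH, " h", sep = "")
  if (object@generations > 1L)
    cat("; ", object@generations, " generations (fractions ",
        paste(object@generationFractions, collapse = ", "), ")", sep = "")
  cat("\n")
})

## ----------------------------------------------------------- TransferKernel

#' Discretized transfer operator
#'
#' The B x B matrix form of the transfer function T(I, I', t): column j
#' holds the destination-bin distribution of a parent cell in source bin j,
#' mixing the divided component (splitting-ratio convolution, weight
#' \code{ft}) and the undivided Dirac component (weight \code{1 - ft}).
#' Every column sums to 1: each parent is accounted for exactly once.
#'
#' @slot matrix non-negative B_dest x B_src weight matrix, columns sum to 1
#' @slot sourceEdges,destEdges linear bin edges of the two axes
#' @slot params the \linkS4class{TransferParams} used
#' @seealso \code{\link{buildKernel}}, \code{\link{applyTransfer}}
#' @aliases kernelMatrix,TransferKernel-method
#' @exportClass TransferKernel
setClass("TransferKernel",
  slots = c(matrix = "matrix", sourceEdges = "numeric", destEdges = "numeric",
            params = "TransferParams"))

setValidity("TransferKernel", function(object) {
  msg <- character()
  M <- object@matrix
  if (nrow(M) != length(object@destEdges) - 1L ||
      ncol(M) != length(object@sourceEdges) - 1L)
    msg <- c(msg, "matrix dimensions must match the bin edges")
  if (any(M < 0)) msg <- c(msg, "kernel entries must be >= 0")
  cs <- colSums(M)
  if (any(abs(cs - 1) > 1e-6))
    msg <- c(msg, "kernel columns must sum to 1 within 1e-6")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("kernelMatrix", "TransferKernel", function(x) x@matrix)
#' @export
setMethod("partitionParams", "TransferKernel", function(x) x@params@partition)

setMethod("show", "TransferKernel", function(object) {
  cat("TransferKernel: ", nrow(object@matrix), " x ", ncol(object@matrix),
      " (dest x source), ft = ", object@params@dividingFraction,
      ", alpha = ", object@params@partition@alpha,
      ", deltaAlpha = ", object@params@partition@deltaAlpha, "\n", sep = "")
})

## --------------------------------------------------------- PopulationSample

#' Monte-Carlo population sample
#'
#' Event-level output of the population simulator: per-cell (or, with both
#' daughters retained, per-lineage-branch) intensities before and after the
#' measurement interval, the number of divisions each lineage underwent,
#' and the realized cumulative splitting ratio (product of the per-division
#' retained fractions; 1 for undivided cells).
#'
#' @slot intensitiesT0 intensities at time 0 (AU)
#' @slot intensitiesT intensities at time t (AU)
#' @slot nDivisions integer division count per cell
#' @slot realizedRatios cumulative retained fraction per cell
#' @seealso \code{\link{simulatePair}}, \code{\link{sampleToHistograms}}
#' @aliases intensities,PopulationSample-method divided,PopulationSample-method
#'   nDivisions,PopulationSample-method realizedRatios,PopulationSample-method
#' @exportClass PopulationSample
setClass("PopulationSample",
  slots = c(intensitiesT0 = "numeric", intensitiesT = "numeric",
            nDivisions = "integer", realizedRatios = "numeric"))

setValidity("PopulationSample", function(object) {
  n <- length(object@intensitiesT0)
  if (length(object@intensitiesT) != n || length(object@nDivisions) != n ||
      length(object@realizedRatios) != n)
    return("all per-cell slots must have equal length")
  if (any(object@nDivisions < 0L)) return("nDivisions must be >= 0")
  TRUE
})

#' @export
setMethod("intensities", "PopulationSample",
          function(x) list(t0 = x@intensitiesT0, t = x@intensitiesT))
#' @export
setMethod("divided", "PopulationSample", function(x) x@nDivisions > 0L)
#' @export
setMethod("nDivisions", "PopulationSample", function(x) x@nDivisions)
#' @export
setMethod("realizedRatios", "PopulationSample", function(x) x@realizedRatios)

setMethod("show", "PopulationSample", function(object) {
  n <- length(object@intensitiesT0)
  cat("PopulationSample: ", n, " cells, ",
      sum(object@nDivisions > 0L), " divided; mean intensity ",
      format(mean(object@intensitiesT0), digits = 5), " -> ",
      format(mean(object@intensitiesT), digits = 5), " AU\n", sep = "")
})

## ---------------------------------------------------------------- SimConfig

#' Simulator configuration
#'
#' Study conditions for the Monte-Carlo population generator. Defaults
#' reproduce the experimental operating point used throughout the package:
#' a broad log-normal parent intensity distribution, a 19 h interval in
#' which 98 percent of cells divide once, and splitting ratios with mean
#' 0.71 and spread 0.11. \code{partitionMode = "organelle"} replaces the
#' continuous ratio draw by binomial assignment of discrete labelled
#' organelles (intensity = organelle count x \code{unitIntensity}), the
#' microscopic picture behind the fluorescence-count linearity assumption.
#'
#' @slot nCells number of cells sampled at each time point
#' @slot initLogMean,initLogSd log-normal meanlog/sdlog of parent intensity
#' @slot params \linkS4class{TransferParams} governing division
#' @slot partitionMode \code{"ratio"} or \code{"organelle"}
#' @slot organellesMean mean labelled-organelle count per cell (organelle mode)
#' @slot unitIntensity fluorescence per organelle (AU, organelle mode)
#' @slot seed RNG seed
#' @slot retainBoth keep both daughters (grows the sample) instead of one
#'   random daughter per division
#' @slot biasMode \code{"mixture"} (per-division bias drawn from the
#'   splitting-ratio mixture) or \code{"fixed"} (bias always alpha)
#'
#' @param nCells,initLogMean,initLogSd,params,partitionMode,organellesMean,unitIntensity,seed,retainBoth,biasMode
#'   see slot descriptions
#' @return a \code{SimConfig}
#' @examples
#' cfg <- SimConfig(nCells = 1000, seed = 7)
#' simulatePair(cfg)
#' @export SimConfig
#' @exportClass SimConfig
SimConfig <- function(nCells = 10000, initLogMean = log(1000),
                      initLogSd = 0.5,
                      params = TransferParams(0.71, 0.11,
                                              dividingFraction = 0.98,
                                              intervalH = 19),
                      partitionMode = c("ratio", "organelle"),
                      organellesMean = 100, unitIntensity = 10,
                      seed = 1L, retainBoth = FALSE,
                      biasMode = c("mixture", "fixed")) {
  new("SimConfig", nCells = as.integer(nCells),
      initLogMean = as.numeric(initLogMean)[1],
      initLogSd = as.numeric(initLogSd)[1], params = params,
      partitionMode = match.arg(partitionMode),
      organellesMean = as.numeric(organellesMean)[1],
      unitIntensity = as.numeric(unitIntensity)[1],
      seed = as.integer(seed)[1], retainBoth = isTRUE(retainBoth),
      biasMode = match.arg(biasMode))
}

setClass("SimConfig",
  slots = c(nCells = "integer", initLogMean = "numeric", initLogSd = "numeric",
            params = "TransferParams", partitionMode = "character",
            organellesMean = "numeric", unitIntensity = "numeric",
            seed = "integer", retainBoth = "logical", biasMode = "character"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (length(object@nCells) != 1L || is.na(object@nCells) || object@nCells < 1L)
    msg <- c(msg, "nCells must be a positive integer")
  if (!is.finite(object@initLogSd) || object@initLogSd <= 0)
    msg <- c(msg, "initLogSd must be > 0")
  if (!object@partitionMode %in% c("ratio", "organelle"))
    msg <- c(msg, "partitionMode must be 'ratio' or 'organelle'")
  if (object@partitionMode == "organelle") {
    if (!is.finite(object@organellesMean) || object@organellesMean <= 0)
      msg <- c(msg, "organellesMean must be > 0 in organelle mode")
    if (!is.finite(object@unitIntensity) || object@unitIntensity <= 0)
      msg <- c(msg, "unitIntensity must be > 0 in organelle mode")
  }
  if (!object@biasMode %in% c("mixture", "fixed"))
    msg <- c(msg, "biasMode must be 'mixture' or 'fixed'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: ", object@nCells, " cells, parent ~ logNormal(",
      format(object@initLogMean, digits = 4), ", ",
      format(object@initLogSd, digits = 4), "), mode = ",
      object@partitionMode, ", seed = ", object@seed, "\n  ", sep = "")
  show(object@params)
})

## --------------------------------------------------------------- FitOptions

.defaultFitBounds <- function() {
  b <- rbind(lower = c(0.5, 0.005, 0), upper = c(1, 0.5, 1))
  colnames(b) <- c("alpha", "deltaAlpha", "dividingFraction")
  b
}

#' Options for the transfer-function fit
#'
#' Controls for \code{\link{fitTransfer}}: the objective, optional fixing
#' of the dividing fraction (e.g. at its moment estimate), box bounds, the
#' differential-evolution budget, the seed, and the number of restarts.
#'
#' @slot objective \code{"sse"} (sum of squared differences of normalized
#'   histograms, the default) or \code{"neg_correlation"}
#'   (1 - Pearson correlation)
#' @slot fixDividingFraction length-0 numeric (fit f_t) or the fixed value
#' @slot bounds 2 x 3 matrix (rows lower/upper; columns alpha, deltaAlpha,
#'   dividingFraction)
#' @slot populationSize,maxGenerations differential-evolution budget
#' @slot seed integer RNG seed; the fit is bit-reproducible given the seed
#' @slot nRestarts independent optimizer restarts (distinct sub-seeds)
#' @slot weighting \code{"none"} or \code{"poisson"} (per-bin weight
#'   1/max(observed count, 1))
#'
#' @param objective,fixDividingFraction,bounds,populationSize,maxGenerations,seed,nRestarts,weighting
#'   see slot descriptions
#' @return a \code{FitOptions}
#' @examples
#' FitOptions(seed = 42, nRestarts = 2)
#' @export FitOptions
#' @exportClass FitOptions
FitOptions <- function(objective = c("sse", "neg_correlation"),
                       fixDividingFraction = numeric(0),
                       bounds = .defaultFitBounds(),
                       populationSize = 30L, maxGenerations = 60L,
                       seed = 1L, nRestarts = 5L,
                       weighting = c("none", "poisson")) {
  new("FitOptions", objective = match.arg(objective),
      fixDividingFraction = as.numeric(fixDividingFraction),
      bounds = bounds, populationSize = as.integer(populationSize),
      maxGenerations = as.integer(maxGenerations), seed = as.integer(seed),
      nRestarts = as.integer(nRestarts), weighting = match.arg(weighting))
}

setClass("FitOptions",
  slots = c(objective = "character", fixDividingFraction = "numeric",
            bounds = "matrix", populationSize = "integer",
            maxGenerations = "integer", seed = "integer",
            nRestarts = "integer", weighting = "character"))

setValidity("FitOptions", function(object) {
  msg <- character()
  if (!object@objective %in% c("sse", "neg_correlation"))
    msg <- c(msg, "objective must be 'sse' or 'neg_correlation'")
  b <- object@bounds
  if (!is.numeric(b) || nrow(b) != 2L || ncol(b) != 3L)
    msg <- c(msg, "bounds must be a 2 x 3 numeric matrix")
  else {
    if (any(b[1, ] >= b[2, ])) msg <- c(msg, "bounds: lower must be < upper")
    if (b[1, 1] < 0.5 || b[2, 1] > 1)
      msg <- c(msg, "alpha bounds must lie in [0.5, 1]")
    if (b[1, 2] <= 0 || b[2, 2] > 0.5)
      msg <- c(msg, "deltaAlpha bounds must lie in (0, 0.5]")
    if (b[1, 3] < 0 || b[2, 3] > 1)
      msg <- c(msg, "dividingFraction bounds must lie in [0, 1]")
  }
  f <- object@fixDividingFraction
  if (length(f) > 1L || (length(f) == 1L && (!is.finite(f) || f < 0 || f > 1)))
    msg <- c(msg, "fixDividingFraction must be empty or a single value in [0, 1]")
  if (is.na(object@populationSize) || object@populationSize < 10L)
    msg <- c(msg, "populationSize must be >= 10")
  if (is.na(object@maxGenerations) || object@maxGenerations < 20L)
    msg <- c(msg, "maxGenerations must be >= 20")
  if (is.na(object@nRestarts) || object@nRestarts < 1L)
    msg <- c(msg, "nRestarts must be >= 1")
  if (!object@weighting %in% c("none", "poisson"))
    msg <- c(msg, "weighting must be 'none' or 'poisson'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FitOptions", function(object) {
  cat("FitOptions: objective = ", object@objective,
      if (length(object@fixDividingFraction))
        paste0(", ft fixed at ", object@fixDividingFraction) else "",
      ", pop = ", object@populationSize, ", maxGen = ", object@maxGenerations,
      ", restarts = ", object@nRestarts, ", seed = ", object@seed, "\n",
      sep = "")
})

## ----------------------------------------------------------------- FitResult

#' Result of a transfer-function fit
#'
#' Best-of-restarts parameter estimates with diagnostics: the objective at
#' the optimum (re-evaluated from the returned parameters), the descriptive
#' goodness-of-fit indices (Pearson correlation and the paired per-bin
#' t-test p-value), the moment estimate of the dividing fraction computed
#' alongside, the evaluation count, a convergence flag, and the maximum
#' pairwise parameter distance across restarts.
#'
#' @slot params fitted \linkS4class{TransferParams}
#' @slot objective objective name used
#' @slot objectiveValue objective at \code{params}
#' @slot pValue paired per-bin t-test p-value (descriptive index)
#' @slot correlation Pearson correlation of model and observed bin counts
#' @slot ftMoment moment estimate of f_t from the two mean intensities
#' @slot nEvaluations total objective evaluations
#' @slot converged TRUE if the search improved on its initial population
#' @slot restartSpread max over restarts and parameters of the absolute
#'   difference between restart optima
#' @slot seed,bounds as used (sufficient to re-run the fit)
#' @seealso \code{\link{fitTransfer}}, \code{\link{writeFitResult}}
#' @aliases fittedParams,FitResult-method fitObjective,FitResult-method
#'   pValue,FitResult-method ftMoment,FitResult-method
#' @exportClass FitResult
setClass("FitResult",
  slots = c(params = "TransferParams", objective = "character",
            objectiveValue = "numeric", pValue = "numeric",
            correlation = "numeric", ftMoment = "numeric",
            nEvaluations = "integer", converged = "logical",
            restartSpread = "numeric", seed = "integer", bounds = "matrix"))

#' @export
setMethod("fittedParams", "FitResult", function(x) x@params)
#' @export
setMethod("fitObjective", "FitResult", function(x) x@objectiveValue)
#' @export
setMethod("pValue", "FitResult", function(x) x@pValue)
#' @export
setMethod("ftMoment", "FitResult", function(x) x@ftMoment)
#' @export
setMethod("alpha", "FitResult", function(x) alpha(x@params))
#' @export
setMethod("deltaAlpha", "FitResult", function(x) deltaAlpha(x@params))
#' @export
setMethod("dividingFraction", "FitResult", function(x) dividingFraction(x@params))

setMethod("show", "FitResult", function(object) {
  cat("FitResult (", object@objective, "): alpha = ",
      format(alpha(object@params), digits = 4), ", deltaAlpha = ",
      format(deltaAlpha(object@params), digits = 4), ", ft = ",
      format(dividingFraction(object@params), digits = 4),
      "\n  objective = ", format(object@objectiveValue, digits = 6),
      ", correlation = ", format(object@correlation, digits = 4),
      ", p = ", format(object@pValue, digits = 4),
      ", ft (moment) = ", format(object@ftMoment, digits = 4),
      "\n  ", object@nEvaluations, " evaluations, converged = ",
      object@converged, ", restart spread = ",
      format(object@restartSpread, digits = 3), "\n", sep = "")
})
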