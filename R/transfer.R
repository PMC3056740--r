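## The partitioning density, the discretized transfer operator, forward
## convolution, the moment estimator, and the multi-generation extension.

## Truncated-mixture helpers shared by the R and compiled paths.
.truncMixConst <- function(a, s) {
  lo <- 0.5 * (pnorm((0 - a) / s) + pnorm((a - 1) / s))
  hi <- 0.5 * (pnorm((1 - a) / s) + pnorm(a / s))
  list(lo = lo, Z = hi - lo)
}

.partitionCdf <- function(x, a, s) {
  k <- .truncMixConst(a, s)
  raw <- 0.5 * (pnorm((x - a) / s) + pnorm((x - 1 + a) / s))
  p <- (raw - k$lo) / k$Z
  p[x <= 0] <- 0
  p[x >= 1] <- 1
  p
}

#' Splitting-ratio probability density
#'
#' Density of the mitotic splitting ratio x (the fraction of labelled
#' material one daughter inherits): an equal-weight mixture of
#' Normal(alpha, deltaAlpha^2) and Normal(1 - alpha, deltaAlpha^2),
#' truncated to [0, 1] and renormalized to integrate to 1. The density is
#' symmetric about 1/2 — the two mixture components are the two daughters —
#' so its mean is exactly 1/2, which is what makes mean fluorescence decay
#' by the factor 1 - ft/2 per interval.
#'
#' @param x ratio values; the density is zero outside [0, 1]
#' @param params a \linkS4class{PartitionParams} (or
#'   \linkS4class{TransferParams}, whose partition slot is used)
#' @return density values, same length as \code{x}
#' @examples
#' p <- PartitionParams(0.71, 0.11)
#' integrate(partitionPdf, 0, 1, params = p)
#' @export
partitionPdf <- function(x, params) {
  if (is(params, "TransferParams")) params <- params@partition
  stopifnot(is(params, "PartitionParams"))
  validObject(params)
  a <- params@alpha; s <- params@deltaAlpha
  k <- .truncMixConst(a, s)
  d <- 0.5 * (dnorm(x, a, s) + dnorm(x, 1 - a, s)) / k$Z
  d[x < 0 | x > 1] <- 0
  d
}

#' Draw splitting ratios
#'
#' Random draws from the truncated splitting-ratio mixture, by equal-weight
#' component choice followed by inverse-CDF sampling of the component
#' truncated to [0, 1]. (The two components truncate symmetrically, so the
#' component weights remain exactly 1/2.)
#'
#' @param n number of draws
#' @param params a \linkS4class{PartitionParams}
#' @return n ratios in [0, 1]
#' @export
rPartitionRatio <- function(n, params) {
  if (is(params, "TransferParams")) params <- params@partition
  a <- params@alpha; s <- params@deltaAlpha
  comp <- ifelse(runif(n) < 0.5, a, 1 - a)
  plo <- pnorm((0 - comp) / s)
  phi <- pnorm((1 - comp) / s)
  x <- comp + s * qnorm(plo + runif(n) * (phi - plo))
  pmin(pmax(x, 0), 1)
}

.checkLinearEdges <- function(edges, what = "edges") {
  edges <- as.numeric(edges)
  if (length(edges) < 2L || !all(is.finite(edges)) || any(diff(edges) <= 0))
    stop(what, " must be finite and strictly increasing (>= 2 values)")
  edges
}

## Destination bin of each source representative intensity (the Dirac term).
.diagBins <- function(mids, destEdges) {
  d <- findInterval(mids, destEdges, rightmost.closed = TRUE)
  if (any(d < 1L | d > length(destEdges) - 1L))
    stop("every source bin midpoint must lie inside the destination range")
  as.integer(d)
}

#' Build the discretized transfer operator
#'
#' Constructs the B x B matrix form of the transfer function for a single
#' division round. For a parent cell at the representative intensity I' of
#' source bin j, the divided component (weight ft) distributes the daughter
#' intensity I = x I' over destination bins by exact integration of the
#' daughter-intensity density (1/I') P(I/I') — the 1/I' change-of-variables
#' factor makes each parent's daughter distribution integrate to 1 — and
#' the undivided component (weight 1 - ft) goes to the destination bin
#' containing I'. Columns are renormalized to sum to exactly 1 to absorb
#' floating-point edge truncation; if the destination range cuts off more
#' than 5 percent of any column's divided mass, an error asks for a wider
#' range rather than silently leaking mass.
#'
#' @param sourceEdges,destEdges strictly increasing linear bin edges
#' @param params a \linkS4class{TransferParams} with \code{generations = 1}
#' @return a \linkS4class{TransferKernel}
#' @examples
#' p <- TransferParams(0.71, 0.11, dividingFraction = 0.98)
#' K <- buildKernel(seq(0, 100, 10), seq(0, 100, 10), p)
#' colSums(kernelMatrix(K))
#' @export
buildKernel <- function(sourceEdges, destEdges, params) {
  stopifnot(is(params, "TransferParams"))
  validObject(params)
  if (params@generations != 1L)
    stop("buildKernel constructs a single-generation operator; ",
         "apply one kernel per generation fraction for generations > 1")
  sourceEdges <- .checkLinearEdges(sourceEdges, "sourceEdges")
  destEdges <- .checkLinearEdges(destEdges, "destEdges")
  mids <- (sourceEdges[-length(sourceEdges)] + sourceEdges[-1L]) / 2
  diag <- .diagBins(mids, destEdges)
  ft <- params@dividingFraction
  a <- params@partition@alpha; s <- params@partition@deltaAlpha
  W <- partition_weights(destEdges, mids, a, s)
  if (ft > 0) {
    lost <- 1 - colSums(W)
    if (any(lost > 0.05))
      stop("destination range [", destEdges[1], ", ",
           destEdges[length(destEdges)], "] truncates more than 5% of the ",
           "divided mass for ", sum(lost > 0.05), " source bin(s); ",
           "widen the destination range")
  }
  K <- ft * W
  idx <- cbind(diag, seq_along(diag))
  K[idx] <- K[idx] + (1 - ft)
  cs <- colSums(K)
  K <- sweep(K, 2L, cs, "/")
  new("TransferKernel", matrix = K, sourceEdges = sourceEdges,
      destEdges = destEdges, params = params)
}

## Fast forward application shared by applyTransfer and the fit objective;
## identical arithmetic to the compiled forward_counts path.
.forwardCounts <- function(edges, mids, diag, cts, a, s, ft) {
  forward_counts(edges, mids, cts, diag, a, s, ft)
}

#' Apply the transfer operator to a histogram
#'
#' Pushes an initial intensity histogram through the forward model to
#' predict the histogram one measurement interval later, on the same bin
#' edges. Total count is conserved (each parent cell maps to exactly one
#' sampled post-division cell). For \code{generations > 1} the
#' single-generation operator is applied once per generation with that
#' generation's dividing fraction.
#'
#' Requires a linear intensity axis; rebin log-amplifier histograms with
#' \code{\link{logToLinearRebin}} first.
#'
#' @param hist a linear-scale \linkS4class{IntensityHistogram}
#' @param params a \linkS4class{TransferParams}
#' @return an \linkS4class{IntensityHistogram} on the same edges, with
#'   \code{timeH} advanced by the measurement interval
#' @seealso \code{\link{buildKernel}}, \code{\link{fitTransfer}}
#' @export
applyTransfer <- function(hist, params) {
  stopifnot(is(hist, "IntensityHistogram"), is(params, "TransferParams"))
  validObject(params)
  if (hist@scale != "linear")
    stop("applyTransfer requires a linear-scale histogram; ",
         "use logToLinearRebin() first")
  edges <- hist@binEdges
  mids <- (edges[-length(edges)] + edges[-1L]) / 2
  diag <- .diagBins(mids, edges)
  a <- params@partition@alpha; s <- params@partition@deltaAlpha
  cts <- hist@counts
  for (f in params@generationFractions) {
    if (f > 0) {
      lost <- 1 - colSums(partition_weights(edges, mids, a, s))
      if (any(lost > 0.05))
        stop("destination range truncates more than 5% of the divided mass; ",
             "widen the binning range (it should start at or near zero)")
    }
    cts <- .forwardCounts(edges, mids, diag, cts, a, s, f)
  }
  IntensityHistogram(edges, cts, scale = "linear",
                     timeH = hist@timeH + params@intervalH)
}

#' Moment estimate of the dividing fraction
#'
#' Irrespective of how asymmetric the partitioning is, the two daughters'
#' mean intensity is half the parent's, so the population mean decays as
#' \code{mean_t = (1 - ft) mean_0 + ft mean_0 / 2}. Solving gives
#' \code{ft = 2 (1 - mean_t / mean_0)}, valid when both measurements sample
#' equal numbers of cells. The estimate is clamped to [0, 1]; clamping is
#' reported via a message and the \code{"clamped"} attribute.
#'
#' @param h0,ht the initial and later \linkS4class{IntensityHistogram}s
#' @return the estimate in [0, 1], with attribute \code{"clamped"}
#' @examples
#' h <- IntensityHistogram(c(0, 1, 2), c(5, 5))
#' estimateDividingFraction(h, h)  # identical histograms -> 0
#' @export
estimateDividingFraction <- function(h0, ht) {
  m0 <- meanIntensity(h0)
  mt <- meanIntensity(ht)
  if (m0 <= 0) stop("initial mean intensity must be > 0")
  raw <- 2 * (1 - mt / m0)
  clamped <- raw < 0 || raw > 1
  if (clamped)
    message("estimateDividingFraction: estimate ", format(raw, digits = 4),
            " clamped to [0, 1]")
  structure(min(max(raw, 0), 1), clamped = clamped)
}

## ------------------------------------------------- multi-generation density

## Open (full) discrete convolution; stats::convolve with a reversed second
## argument yields the standard orientation.
.convOpen <- function(x, y) convolve(x, rev(y), type = "open")

## Density of the cumulative ratio after k divisions on a log-ratio grid:
## list(s, g) with s = log(x) and trapezoid-normalized g.
.multigenLogGrid <- function(params, k, nGrid = 4096L) {
  sMin <- log(1e-7)
  s1 <- seq(sMin, 0, length.out = nGrid)
  dS <- s1[2] - s1[1]
  g1 <- partitionPdf(exp(s1), params) * exp(s1)
  g <- g1
  if (k > 1L) for (i in 2:k) g <- pmax(.convOpen(g, g1) * dS, 0)
  s <- seq(k * sMin, 0, length.out = length(g))
  trap <- sum((g[-1L] + g[-length(g)]) / 2) * dS
  list(s = s, g = g / trap, dS = dS)
}

#' Cumulative-ratio density after k generations
#'
#' Density of the product of k independent splitting-ratio draws — the
#' fraction of the progenitor's labelled material held by a randomly
#' sampled descendant after k division rounds — computed by numerical
#' convolution in log-ratio space. For \code{k = 1} this is exactly
#' \code{\link{partitionPdf}}. For k = 2 the four daughter-of-daughter
#' branches appear as modes near alpha^2, alpha (1 - alpha) (twice), and
#' (1 - alpha)^2.
#'
#' @param x ratio values in [0, 1]
#' @param params a \linkS4class{PartitionParams}
#' @param k number of generations (>= 1)
#' @param nGrid log-space grid size per generation
#' @return density values, same length as \code{x}
#' @export
multigenerationRatioPdf <- function(x, params, k, nGrid = 4096L) {
  if (is(params, "TransferParams")) params <- params@partition
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  if (k == 1L) return(partitionPdf(x, params))
  grid <- .multigenLogGrid(params, k, nGrid)
  out <- numeric(length(x))
  ok <- x > 0 & x <= 1
  out[ok] <- approx(grid$s, grid$g, xout = log(x[ok]), yleft = 0,
                    yright = grid$g[length(grid$g)])$y / x[ok]
  out
}

## CDF of the cumulative ratio after k generations, as a vectorized closure
## over the same log-space grid (used for the iterated-kernel cross-check).
.multigenRatioCdf <- function(params, k, nGrid = 4096L) {
  if (k == 1L) {
    a <- params@alpha; s <- params@deltaAlpha
    return(function(r) .partitionCdf(r, a, s))
  }
  grid <- .multigenLogGrid(params, k, nGrid)
  L <- length(grid$g)
  cdf <- c(0, cumsum((grid$g[-1L] + grid$g[-L]) / 2) * grid$dS)
  cdf <- cdf / cdf[L]
  sGrid <- grid$s
  function(r) {
    p <- numeric(length(r))
    pos <- r > 0
    p[pos] <- approx(sGrid, cdf, xout = log(r[pos]), yleft = 0,
                     yright = 1)$y
    p[r >= 1] <- 1
    p
  }
}

## Forward model with an arbitrary cumulative-ratio CDF (e.g. the k-
## generation product density) in place of the single-division mixture.
## Used to cross-check the iterated kernel against the explicit
## multi-generation density.
.forwardWithRatioCdf <- function(hist, cdfFun, ftAll = 1) {
  stopifnot(is(hist, "IntensityHistogram"), hist@scale == "linear")
  edges <- hist@binEdges
  B <- length(edges) - 1L
  mids <- (edges[-length(edges)] + edges[-1L]) / 2
  diag <- .diagBins(mids, edges)
  R <- outer(edges, 1 / mids)          # (B+1) x B edge/parent ratios
  Cv <- matrix(cdfFun(pmin(R, 1)), nrow = B + 1L)
  W <- Cv[-1L, , drop = FALSE] - Cv[-(B + 1L), , drop = FALSE]
  K <- ftAll * W
  idx <- cbind(diag, seq_along(diag))
  K[idx] <- K[idx] + (1 - ftAll)
  K <- sweep(K, 2L, colSums(K), "/")
  IntensityHistogram(edges, as.numeric(K %*% hist@counts), scale = "linear",
                     timeH = hist@timeH)
}
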