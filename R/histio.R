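## Event and histogram I/O, binning and rebinning, including the
## log-amplifier binning dialect of flow cytometers.

#' Read per-cell fluorescence events from a CSV file
#'
#' Reads one intensity per row from a delimited text file with a header.
#' Rows whose intensity is missing, non-finite, or not strictly positive
#' are dropped with a message saying how many were removed and why. The
#' optional columns \code{sample} and \code{time_h}, when present, populate
#' the event-list label and measurement time.
#'
#' @param path path to a CSV file with a header row
#' @param column name of the intensity column (default \code{"intensity"})
#' @return an \linkS4class{EventList}; the number of dropped rows is
#'   attached as attribute \code{"dropped"}
#' @seealso \code{\link{writeEvents}}, \code{\link{binEvents}}
#' @export
readEvents <- function(path, column = "intensity") {
  if (!file.exists(path)) stop("event file not found: ", path)
  tab <- read.csv(path, check.names = FALSE)
  if (!column %in% names(tab))
    stop("column '", column, "' not found in ", path,
         " (columns: ", paste(names(tab), collapse = ", "), ")")
  x <- suppressWarnings(as.numeric(tab[[column]]))
  bad <- !is.finite(x) | x <= 0
  nBad <- sum(bad)
  if (nBad == nrow(tab))
    stop("no valid events in ", path,
         ": all ", nrow(tab), " rows are missing, non-finite or <= 0")
  if (nBad > 0)
    message("readEvents: dropped ", nBad, " of ", nrow(tab),
            " rows (missing, non-finite or non-positive intensity)")
  label <- if ("sample" %in% names(tab)) as.character(tab$sample[!bad][1]) else "sample"
  tH <- if ("time_h" %in% names(tab))
    suppressWarnings(as.numeric(tab$time_h[!bad][1])) else 0
  if (is.na(tH)) tH <- 0
  ev <- EventList(x[!bad], label = label, timeH = tH)
  attr(ev, "dropped") <- nBad
  ev
}

#' Write per-cell events to a CSV file
#'
#' Inverse of \code{\link{readEvents}}: columns \code{intensity},
#' \code{sample}, \code{time_h}. Intensities are printed with 17
#' significant digits so a write/read round trip reproduces the doubles
#' exactly.
#'
#' @param events an \linkS4class{EventList}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeEvents <- function(events, path) {
  stopifnot(is(events, "EventList"))
  lines <- c("intensity,sample,time_h",
             sprintf("%.17g,%s,%.17g", events@intensities, events@label,
                     events@timeH))
  writeLines(lines, path)
  invisible(path)
}

#' Convenience bin-edge builders
#'
#' \code{linearEdges} returns \code{n + 1} equally spaced edges;
#' \code{logEdges} returns \code{n + 1} edges with constant ratio
#' (logarithmic spacing, as produced by a log-amplifier).
#'
#' @param from,to range covered (for \code{logEdges}, \code{from > 0})
#' @param n number of bins
#' @return numeric vector of length \code{n + 1}
#' @export
linearEdges <- function(from, to, n) {
  stopifnot(n >= 1, to > from)
  seq(from, to, length.out = n + 1L)
}

#' @rdname linearEdges
#' @export
logEdges <- function(from, to, n) {
  stopifnot(n >= 1, from > 0, to > from)
  exp(seq(log(from), log(to), length.out = n + 1L))
}

#' Bin events into an intensity histogram
#'
#' Counts events into half-open bins [lo, hi), the final bin closed, so
#' that in-range events are partitioned exactly. Events outside
#' [first edge, last edge] are excluded from the counts.
#'
#' @param events an \linkS4class{EventList}
#' @param edges strictly increasing bin edges (length >= 2)
#' @param scale \code{"linear"}, \code{"log"}, or NULL to detect from the
#'   edge spacing
#' @return an \linkS4class{IntensityHistogram} whose counts sum to the
#'   number of in-range events
#' @examples
#' binEvents(EventList(c(1, 2, 3)), c(0, 2, 4))  # counts 1, 2
#' @export
binEvents <- function(events, edges, scale = NULL) {
  stopifnot(is(events, "EventList"))
  edges <- as.numeric(edges)
  if (length(edges) < 2L || any(diff(edges) <= 0))
    stop("edges must be strictly increasing, with at least 2 values")
  x <- events@intensities
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  inside <- idx >= 1L & idx <= length(edges) - 1L
  if (!any(inside))
    stop("no events inside the binning range [", edges[1], ", ",
         edges[length(edges)], "]")
  ct <- tabulate(idx[inside], nbins = length(edges) - 1L)
  IntensityHistogram(edges, as.numeric(ct), scale = scale,
                     timeH = events@timeH)
}

#' Rebin a log-spaced histogram onto a linear intensity axis
#'
#' Spreads each log bin's count uniformly in intensity across the linear
#' bins it overlaps, covering the same total range. Total count is
#' preserved; rebinned counts are generally fractional.
#'
#' @param hist a log-scale \linkS4class{IntensityHistogram}
#' @param nBins number of linear output bins (>= 2)
#' @return a linear-scale \linkS4class{IntensityHistogram}
#' @seealso \code{\link{binEvents}}, \code{\link{applyTransfer}} (which
#'   requires a linear axis)
#' @export
logToLinearRebin <- function(hist, nBins) {
  stopifnot(is(hist, "IntensityHistogram"))
  if (hist@scale != "log")
    stop("logToLinearRebin expects a log-scale histogram")
  nBins <- as.integer(nBins)
  if (is.na(nBins) || nBins < 2L) stop("nBins must be >= 2")
  src <- hist@binEdges
  tgt <- seq(src[1], src[length(src)], length.out = nBins + 1L)
  out <- numeric(nBins)
  for (j in seq_along(hist@counts)) {
    cj <- hist@counts[j]
    if (cj == 0) next
    a <- src[j]; b <- src[j + 1L]
    ov <- pmax(0, pmin(b, tgt[-1L]) - pmax(a, tgt[-(nBins + 1L)]))
    out <- out + cj * ov / (b - a)
  }
  IntensityHistogram(tgt, out, scale = "linear", timeH = hist@timeH)
}

## Regrid a histogram onto arbitrary linear edges covering its range, by
## uniform-in-intensity spreading (mass-conserving). Used by the command
## layer to put log-amplifier histograms onto a linear axis anchored at 0,
## where the transfer operator loses no daughter mass.
.regridLinear <- function(hist, edges) {
  src <- hist@binEdges
  if (edges[1] > src[1] || edges[length(edges)] < src[length(src)])
    stop("target edges must cover the source histogram range")
  nB <- length(edges) - 1L
  out <- numeric(nB)
  for (j in seq_along(hist@counts)) {
    cj <- hist@counts[j]
    if (cj == 0) next
    a <- src[j]; b <- src[j + 1L]
    ov <- pmax(0, pmin(b, edges[-1L]) - pmax(a, edges[-(nB + 1L)]))
    out <- out + cj * ov / (b - a)
  }
  IntensityHistogram(edges, out, scale = "linear", timeH = hist@timeH)
}

.binMids <- function(hist) {
  e <- hist@binEdges
  if (hist@scale == "log") sqrt(e[-length(e)] * e[-1L])
  else (e[-length(e)] + e[-1L]) / 2
}

#' @export
setMethod("meanIntensity", "IntensityHistogram", function(x) {
  tot <- sum(x@counts)
  if (tot <= 0) stop("empty histogram: total count is zero")
  sum(.binMids(x) * x@counts) / tot
})

#' Histogram CSV serialization
#'
#' Histograms travel as plain CSV with header \code{bin_lo,bin_hi,count},
#' preceded by comment lines \code{# scale=linear|log} and
#' \code{# time_h=<float>}. Values use 17 significant digits so round
#' trips are exact.
#'
#' @param hist an \linkS4class{IntensityHistogram}
#' @param path file path
#' @return \code{writeHistogram}: \code{path} invisibly;
#'   \code{readHistogram}: an \linkS4class{IntensityHistogram}
#' @export
writeHistogram <- function(hist, path) {
  stopifnot(is(hist, "IntensityHistogram"))
  e <- hist@binEdges
  lines <- c(sprintf("# scale=%s", hist@scale),
             sprintf("# time_h=%.17g", hist@timeH),
             "bin_lo,bin_hi,count",
             sprintf("%.17g,%.17g,%.17g", e[-length(e)], e[-1L], hist@counts))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeHistogram
#' @export
readHistogram <- function(path) {
  if (!file.exists(path)) stop("histogram file not found: ", path)
  hdr <- readLines(path, n = 10L)
  meta <- hdr[startsWith(hdr, "#")]
  getMeta <- function(key, default) {
    m <- grep(paste0("^#\\s*", key, "="), meta, value = TRUE)
    if (!length(m)) return(default)
    sub(paste0("^#\\s*", key, "="), "", m[1])
  }
  scale <- getMeta("scale", NA_character_)
  tH <- as.numeric(getMeta("time_h", "0"))
  tab <- read.csv(path, comment.char = "#")
  need <- c("bin_lo", "bin_hi", "count")
  if (!all(need %in% names(tab)))
    stop("histogram file must have columns bin_lo, bin_hi, count: ", path)
  lo <- as.numeric(tab$bin_lo); hi <- as.numeric(tab$bin_hi)
  if (nrow(tab) > 1L &&
      any(abs(hi[-nrow(tab)] - lo[-1L]) >
          1e-9 * pmax(1, abs(hi[-nrow(tab)]))))
    stop("histogram bins must be contiguous (bin_hi[i] == bin_lo[i+1]): ", path)
  edges <- c(lo, hi[length(hi)])
  IntensityHistogram(edges, as.numeric(tab$count),
                     scale = if (is.na(scale)) NULL else scale, timeH = tH)
}

#' Kolmogorov-Smirnov distance between two histograms
#'
#' Maximum absolute difference between the normalized cumulative counts of
#' two histograms on identical edges. Used as the model-vs-simulation
#' equivalence metric.
#'
#' @param a,b \linkS4class{IntensityHistogram}s on the same edges
#' @return the KS distance in [0, 1]
#' @export
ksDistance <- function(a, b) {
  stopifnot(is(a, "IntensityHistogram"), is(b, "IntensityHistogram"))
  if (length(a@binEdges) != length(b@binEdges) ||
      max(abs(a@binEdges - b@binEdges)) >
      1e-9 * max(1, max(abs(a@binEdges))))
    stop("histograms must share identical bin edges")
  max(abs(cumsum(a@counts) / sum(a@counts) -
          cumsum(b@counts) / sum(b@counts)))
}
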