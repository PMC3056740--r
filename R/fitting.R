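## Inverse problem: estimate (alpha, deltaAlpha, ft) from a measured
## histogram pair by fitting the forward model with seeded differential
## evolution, plus the descriptive goodness-of-fit indices.

.checkPair <- function(h0, ht) {
  stopifnot(is(h0, "IntensityHistogram"), is(ht, "IntensityHistogram"))
  if (h0@scale != "linear" || ht@scale != "linear")
    stop("both histograms must be on a linear intensity axis ",
         "(use logToLinearRebin)")
  if (length(h0@binEdges) != length(ht@binEdges) ||
      max(abs(h0@binEdges - ht@binEdges)) >
      1e-9 * max(1, max(abs(h0@binEdges))))
    stop("h0 and ht must share identical bin edges")
  invisible(TRUE)
}

## Shared fast objective; the public objectiveValue() and the optimizer
## both call this, so the reported optimum re-evaluates exactly.
.objectiveFun <- function(edges, mids, diag, c0, obs, objective, w) {
  obsN <- obs / sum(obs)
  tot0 <- sum(c0)
  if (objective == "sse") {
    function(a, s, ft) {
      m <- forward_counts(edges, mids, c0, diag, a, s, ft) / tot0
      sum(w * (m - obsN)^2)
    }
  } else {
    function(a, s, ft) {
      m <- forward_counts(edges, mids, c0, diag, a, s, ft)
      if (sd(m) == 0 || sd(obs) == 0) return(1)
      1 - cor(m, obs)
    }
  }
}

#' Objective of the transfer-function fit
#'
#' Discrepancy between the forward-model prediction from \code{h0} and the
#' observed \code{ht}, both normalized to unit total: \code{"sse"} is the
#' sum of squared per-bin differences, \code{"neg_correlation"} is
#' 1 - Pearson correlation of the bin counts. Both are >= 0 and 0 for a
#' perfect fit.
#'
#' @param h0,ht \linkS4class{IntensityHistogram}s on common linear edges
#' @param params a \linkS4class{TransferParams}
#' @param objective \code{"sse"} or \code{"neg_correlation"}
#' @param weighting \code{"none"} or \code{"poisson"} (per-bin weight
#'   1/max(observed count, 1), for count heteroscedasticity; sse only)
#' @return a non-negative scalar, lower is better
#' @export
objectiveValue <- function(h0, ht, params,
                           objective = c("sse", "neg_correlation"),
                           weighting = c("none", "poisson")) {
  .checkPair(h0, ht)
  objective <- match.arg(objective)
  weighting <- match.arg(weighting)
  stopifnot(is(params, "TransferParams"))
  validObject(params)
  edges <- h0@binEdges
  mids <- (edges[-length(edges)] + edges[-1L]) / 2
  diag <- .diagBins(mids, edges)
  w <- if (weighting == "poisson") 1 / pmax(ht@counts, 1) else 1
  fn <- .objectiveFun(edges, mids, diag, h0@counts, ht@counts, objective, w)
  fn(params@partition@alpha, params@partition@deltaAlpha,
     params@dividingFraction)
}

#' Fit the transfer function to a measured histogram pair
#'
#' Recovers the splitting-ratio distribution (alpha, deltaAlpha) and the
#' dividing fraction ft by global stochastic search (differential
#' evolution, bound-constrained and seeded) minimizing the chosen
#' objective. When \code{fixDividingFraction} is set — typically at the
#' moment estimate from the two mean intensities — only (alpha,
#' deltaAlpha) are searched. Runs \code{nRestarts} independent restarts
#' with distinct sub-seeds and returns the best, with the maximum
#' parameter spread across restart optima as a convergence diagnostic.
#' Bit-reproducible given the seed.
#'
#' @param h0,ht \linkS4class{IntensityHistogram}s on common linear edges,
#'   ideally from equal-sized samples (a warning is issued otherwise,
#'   since the moment identity for ft assumes equal cell numbers)
#' @param options a \linkS4class{FitOptions}
#' @return a \linkS4class{FitResult}
#' @examples
#' cfg <- SimConfig(nCells = 2000, seed = 11)
#' hp <- sampleToHistograms(simulatePair(cfg), nBins = 64)
#' fit <- fitTransfer(hp$t0, hp$t,
#'                    FitOptions(seed = 1, nRestarts = 1,
#'                               populationSize = 15, maxGenerations = 25))
#' fit
#' @export
fitTransfer <- function(h0, ht, options = FitOptions()) {
  .checkPair(h0, ht)
  stopifnot(is(options, "FitOptions"))
  validObject(options)
  tot0 <- sum(h0@counts); tott <- sum(ht@counts)
  if (abs(tot0 - tott) > 0.01 * max(tot0, tott))
    warning("h0 and ht totals differ by more than 1%; the moment identity ",
            "for the dividing fraction assumes equal sample sizes")
  ftMom <- estimateDividingFraction(h0, ht)

  edges <- h0@binEdges
  mids <- (edges[-length(edges)] + edges[-1L]) / 2
  diag <- .diagBins(mids, edges)
  w <- if (options@weighting == "poisson") 1 / pmax(ht@counts, 1) else 1
  fn3 <- .objectiveFun(edges, mids, diag, h0@counts, ht@counts,
                       options@objective, w)

  fixFt <- options@fixDividingFraction
  b <- options@bounds
  if (length(fixFt)) {
    lower <- b[1, 1:2]; upper <- b[2, 1:2]
    evalPar <- function(p) fn3(p[1], p[2], fixFt)
    toParams <- function(p) c(p[1], p[2], fixFt)
  } else {
    lower <- b[1, ]; upper <- b[2, ]
    evalPar <- function(p) fn3(p[1], p[2], p[3])
    toParams <- function(p) p
  }

  runs <- vector("list", options@nRestarts)
  for (i in seq_len(options@nRestarts)) {
    runs[[i]] <- .deOptim(evalPar, lower, upper,
                          popSize = options@populationSize,
                          maxGen = options@maxGenerations,
                          seed = options@seed + (i - 1L) * 1009L)
  }
  vals <- vapply(runs, `[[`, numeric(1), "value")
  pars <- do.call(rbind, lapply(runs, `[[`, "par"))
  nev <- sum(vapply(runs, `[[`, integer(1), "nEvaluations"))
  improved <- any(vapply(runs, `[[`, logical(1), "improved"))
  bestPar <- toParams(pars[which.min(vals), ])
  spread <- if (nrow(pars) > 1L) max(apply(pars, 2L, function(col)
    max(col) - min(col))) else 0

  params <- TransferParams(bestPar[1], bestPar[2],
                           dividingFraction = bestPar[3],
                           intervalH = ht@timeH - h0@timeH)
  objVal <- objectiveValue(h0, ht, params, objective = options@objective,
                           weighting = options@weighting)
  gof <- goodnessOfFit(applyTransfer(h0, params), ht)
  if (!improved)
    warning("optimizer budget exhausted without improving on the initial ",
            "population; returning the best point found")
  new("FitResult", params = params, objective = options@objective,
      objectiveValue = objVal, pValue = gof$pValue,
      correlation = gof$correlation, ftMoment = as.numeric(ftMom),
      nEvaluations = as.integer(nev), converged = improved,
      restartSpread = spread, seed = options@seed, bounds = b)
}

#' Descriptive goodness-of-fit indices
#'
#' Two indices comparing a model histogram with an observed one on the
#' same edges: (a) the Pearson correlation of the bin counts and (b) the
#' p-value of a paired two-sided t-test on the per-bin differences between
#' the normalized model and observed counts, restricted to bins with a
#' nonzero observed count. A high p-value indicates no detectable
#' systematic per-bin offset. Neither index alone decides acceptance:
#' because both histograms are normalized, the mean per-bin difference is
#' pinned near zero whenever the model keeps its mass inside the observed
#' support, so the t-test index is sensitive mainly to mass escaping the
#' observed range, while the correlation tracks shape agreement. Both are
#' descriptive summaries, not calibrated inferential tests.
#'
#' @param modelHist,observedHist \linkS4class{IntensityHistogram}s on
#'   identical edges; the observed histogram must have at least 3 bins
#'   with nonzero counts
#' @return list with elements \code{correlation} and \code{pValue}
#'   (p = 1 when the per-bin differences are identically zero)
#' @export
goodnessOfFit <- function(modelHist, observedHist) {
  .checkPair(modelHist, observedHist)
  obs <- observedHist@counts
  mod <- modelHist@counts
  if (sum(obs) <= 0) stop("observed histogram has zero total count")
  keep <- obs > 0
  if (sum(keep) < 3L)
    stop("need at least 3 bins with nonzero observed count")
  r <- if (sd(mod) == 0 || sd(obs) == 0) NA_real_ else cor(mod, obs)
  d <- (mod / sum(mod) - obs / sum(obs))[keep]
  tol <- 1e-12 * max(1, max(abs(obs / sum(obs))))
  p <- if (all(abs(d) <= tol)) 1
       else if (sd(d) == 0) 0           # constant nonzero offset
       else t.test(d)$p.value
  list(correlation = r, pValue = p)
}

#' Serialize a fit result to JSON
#'
#' Writes every field of a \linkS4class{FitResult}, with the seed, bounds
#' and package version, sufficient to re-run the fit.
#'
#' @param result a \linkS4class{FitResult}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeFitResult <- function(result, path) {
  stopifnot(is(result, "FitResult"))
  p <- result@params
  out <- list(
    params = list(alpha = alpha(p), delta_alpha = deltaAlpha(p),
                  dividing_fraction = dividingFraction(p),
                  interval_h = intervalH(p), generations = generations(p),
                  generation_fractions = generationFractions(p)),
    objective = result@objective,
    objective_value = result@objectiveValue,
    p_value = result@pValue,
    correlation = result@correlation,
    ft_moment = result@ftMoment,
    n_evaluations = result@nEvaluations,
    converged = result@converged,
    restart_spread = result@restartSpread,
    seed = result@seed,
    bounds = list(lower = as.numeric(result@bounds[1, ]),
                  upper = as.numeric(result@bounds[2, ])),
    package_version = as.character(packageVersion("flowInherit")))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
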