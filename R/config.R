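## Flat structured-config (YAML/JSON) serialization of the parameter
## objects, used by the command-line pipeline and run manifests.

#' Flat config serialization of transfer parameters
#'
#' \code{transferParamsToConfig} renders a \linkS4class{TransferParams} as
#' a flat named list with keys \code{alpha}, \code{delta_alpha},
#' \code{dividing_fraction}, \code{interval_h}, \code{generations},
#' \code{generation_fractions}; \code{transferParamsFromConfig} is its
#' inverse. Unknown keys are ignored.
#'
#' @param params a \linkS4class{TransferParams}
#' @param config a named list (e.g. from \code{yaml::read_yaml})
#' @return a named list, or a \linkS4class{TransferParams}
#' @export
transferParamsToConfig <- function(params) {
  stopifnot(is(params, "TransferParams"))
  list(alpha = alpha(params), delta_alpha = deltaAlpha(params),
       dividing_fraction = dividingFraction(params),
       interval_h = intervalH(params),
       generations = generations(params),
       generation_fractions = generationFractions(params))
}

#' @rdname transferParamsToConfig
#' @export
transferParamsFromConfig <- function(config) {
  need <- c("alpha", "delta_alpha", "dividing_fraction")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config is missing required key(s): ", paste(miss, collapse = ", "))
  gens <- as.integer(config$generations %||% 1L)
  TransferParams(config$alpha, config$delta_alpha,
                 dividingFraction = config$dividing_fraction,
                 intervalH = config$interval_h %||% 19,
                 generations = gens,
                 generationFractions =
                   if (!is.null(config$generation_fractions))
                     as.numeric(unlist(config$generation_fractions))
                   else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a simulator configuration file
#'
#' Flat YAML (or JSON) with the simulator keys \code{n_cells},
#' \code{init_log_mean}, \code{init_log_sd}, \code{partition_mode},
#' \code{organelles_mean}, \code{unit_intensity}, \code{seed},
#' \code{retain_both}, \code{bias_mode} alongside the transfer-parameter
#' keys of \code{\link{transferParamsFromConfig}}. Missing keys take the
#' \code{\link{SimConfig}} defaults.
#'
#' @param path path to the config file
#' @return a \linkS4class{SimConfig}
#' @export
readSimConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a mapping of keys to values")
  params <- transferParamsFromConfig(cfg)
  def <- formals(SimConfig)
  SimConfig(nCells = cfg$n_cells %||% eval(def$nCells),
            initLogMean = cfg$init_log_mean %||% eval(def$initLogMean),
            initLogSd = cfg$init_log_sd %||% eval(def$initLogSd),
            params = params,
            partitionMode = cfg$partition_mode %||% "ratio",
            organellesMean = cfg$organelles_mean %||% eval(def$organellesMean),
            unitIntensity = cfg$unit_intensity %||% eval(def$unitIntensity),
            seed = cfg$seed %||% 1L,
            retainBoth = isTRUE(cfg$retain_both),
            biasMode = cfg$bias_mode %||% "mixture")
}

.simConfigToList <- function(config) {
  c(list(n_cells = config@nCells, init_log_mean = config@initLogMean,
         init_log_sd = config@initLogSd,
         partition_mode = config@partitionMode,
         organelles_mean = config@organellesMean,
         unit_intensity = config@unitIntensity, seed = config@seed,
         retain_both = config@retainBoth, bias_mode = config@biasMode),
    transferParamsToConfig(config@params))
}

#' Read fit options from a config file
#'
#' Flat YAML/JSON with keys \code{objective},
#' \code{fix_dividing_fraction}, \code{population_size},
#' \code{max_generations}, \code{seed}, \code{n_restarts},
#' \code{weighting}, and optional \code{bounds} (mapping each of
#' \code{alpha}, \code{delta_alpha}, \code{dividing_fraction} to a
#' [lower, upper] pair). Missing keys take the \code{\link{FitOptions}}
#' defaults.
#'
#' @param path path to the config file
#' @return a \linkS4class{FitOptions}
#' @export
readFitOptions <- function(path) {
  if (!file.exists(path)) stop("options file not found: ", path)
  cfg <- yaml::read_yaml(path)
  b <- .defaultFitBounds()
  if (!is.null(cfg$bounds)) {
    key <- c(alpha = "alpha", deltaAlpha = "delta_alpha",
             dividingFraction = "dividing_fraction")
    for (j in seq_along(key)) {
      v <- cfg$bounds[[key[j]]]
      if (!is.null(v)) b[, j] <- as.numeric(unlist(v))
    }
  }
  FitOptions(objective = cfg$objective %||% "sse",
             fixDividingFraction =
               if (is.null(cfg$fix_dividing_fraction)) numeric(0)
               else as.numeric(cfg$fix_dividing_fraction),
             bounds = b,
             populationSize = cfg$population_size %||% 30L,
             maxGenerations = cfg$max_generations %||% 60L,
             seed = cfg$seed %||% 1L,
             nRestarts = cfg$n_restarts %||% 5L,
             weighting = cfg$weighting %||% "none")
}
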