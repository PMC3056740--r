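#' @name flowInherit-generics
#' @title Accessor generics
#'
#' @description Accessor generics for the S4 containers. Each class
#'   documents the accessors that apply to it.
#' @param x,object an object of one of the package classes
#' @param ... further arguments for methods
#' @return the slot value; see the class documentation pages.
NULL

#' @rdname flowInherit-generics
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname flowInherit-generics
#' @export
setGeneric("timeH", function(x) standardGeneric("timeH"))

#' @rdname flowInherit-generics
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))

#' @rdname flowInherit-generics
#' @export
setGeneric("counts", function(object, ...) standardGeneric("counts"))

#' @rdname flowInherit-generics
#' @export
setGeneric("histScale", function(x) standardGeneric("histScale"))

#' Mean fluorescence intensity
#'
#' Count-weighted mean intensity of a histogram (bin representative points:
#' arithmetic midpoints for linear bins, geometric midpoints for log bins),
#' or the sample mean of an event list.
#'
#' @param x an \linkS4class{IntensityHistogram} or \linkS4class{EventList}
#' @return mean intensity in arbitrary fluorescence units (AU)
#' @examples
#' h <- IntensityHistogram(c(0, 2, 4), c(1, 1))
#' meanIntensity(h)  # midpoints 1 and 3 -> 2
#' @export
setGeneric("meanIntensity", function(x) standardGeneric("meanIntensity"))

#' @rdname flowInherit-generics
#' @export
setGeneric("alpha", function(x) standardGeneric("alpha"))

#' @rdname flowInherit-generics
#' @export
setGeneric("deltaAlpha", function(x) standardGeneric("deltaAlpha"))

#' @rdname flowInherit-generics
#' @export
setGeneric("dividingFraction", function(x) standardGeneric("dividingFraction"))

#' @rdname flowInherit-generics
#' @export
setGeneric("intervalH", function(x) standardGeneric("intervalH"))

#' @rdname flowInherit-generics
#' @export
setGeneric("generations", function(x) standardGeneric("generations"))

#' @rdname flowInherit-generics
#' @export
setGeneric("generationFractions", function(x) standardGeneric("generationFractions"))

#' @rdname flowInherit-generics
#' @export
setGeneric("partitionParams", function(x) standardGeneric("partitionParams"))

#' @rdname flowInherit-generics
#' @export
setGeneric("kernelMatrix", function(x) standardGeneric("kernelMatrix"))

#' @rdname flowInherit-generics
#' @export
setGeneric("divided", function(x) standardGeneric("divided"))

#' @rdname flowInherit-generics
#' @export
setGeneric("nDivisions", function(x) standardGeneric("nDivisions"))

#' @rdname flowInherit-generics
#' @export
setGeneric("realizedRatios", function(x) standardGeneric("realizedRatios"))

#' @rdname flowInherit-generics
#' @export
setGeneric("fittedParams", function(x) standardGeneric("fittedParams"))

#' @rdname flowInherit-generics
#' @export
setGeneric("fitObjective", function(x) standardGeneric("fitObjective"))

#' @rdname flowInherit-generics
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname flowInherit-generics
#' @export
setGeneric("ftMoment", function(x) standardGeneric("ftMoment"))
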