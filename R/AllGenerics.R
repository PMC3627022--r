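#' @export
setGeneric("npoints", function(x) standardGeneric("npoints"))

#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @export
setGeneric("markData", function(x) standardGeneric("markData"))

#' @export
setGeneric("scales", function(x) standardGeneric("scales"))

#' @export
setGeneric("funValues", function(x) standardGeneric("funValues"))

#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @export
setGeneric("envelopeClassification", function(x) {
  standardGeneric("envelopeClassification")
})

#' @export
setGeneric("bestFit", function(x) standardGeneric("bestFit"))

#' Accessors for densdep objects
#'
#' Small accessor generics: `npoints()`, `coords()`, `markData()` and
#' `intensity()` for [PointPattern] objects; `scales()` and `funValues()`
#' for [SummaryFunction] and [EnvelopeResult]; `pValue()` for [GofResult];
#' `envelopeClassification()` for [EnvelopeResult]; `bestFit()` for
#' [ModelComparison].
#'
#' `intensity()` returns n / |W|, the number of points per unit area.
#' `envelopeClassification()` returns, per scale, `"below"`, `"inside"` or
#' `"above"` depending on where the observed statistic falls relative to the
#' simulation envelope (`NA` where observed or bounds are missing).
#'
#' @param x the object.
#' @return See details; scalar, vector or `data.frame` accessors.
#' @name accessors
#' @aliases npoints intensity coords markData scales funValues pValue
#'   envelopeClassification bestFit
NULL

#' @rdname accessors
#' @export
setMethod("npoints", "PointPattern", function(x) length(x@x))

#' @rdname accessors
#' @export
setMethod("intensity", "PointPattern", function(x) {
  length(x@x) / windowArea(x@window)
})

#' @rdname accessors
#' @export
setMethod("coords", "PointPattern", function(x) {
  data.frame(x = x@x, y = x@y)
})

#' @rdname accessors
#' @export
setMethod("markData", "PointPattern", function(x) x@marks)

#' @rdname accessors
#' @export
setMethod("scales", "SummaryFunction", function(x) x@scales)

#' @rdname accessors
#' @export
setMethod("scales", "EnvelopeResult", function(x) x@scales)

#' @rdname accessors
#' @export
setMethod("funValues", "SummaryFunction", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("funValues", "EnvelopeResult", function(x) x@observed)

#' @rdname accessors
#' @export
setMethod("pValue", "GofResult", function(x) x@pValue)

#' @rdname accessors
#' @export
setMethod("envelopeClassification", "EnvelopeResult", function(x) {
  cl <- rep(NA_character_, length(x@scales))
  ok <- !is.na(x@observed) & !is.na(x@lower) & !is.na(x@upper)
  cl[ok & x@observed < x@lower] <- "below"
  cl[ok & x@observed > x@upper] <- "above"
  cl[ok & x@observed >= x@lower & x@observed <= x@upper] <- "inside"
  cl
})

#' @rdname accessors
#' @export
setMethod("bestFit", "ModelComparison", function(x) {
  x@fits[[match(x@bestFitId, vapply(x@fits, function(f) f@modelId, 1L))]]
})

#' Tabulate a summary function or envelope as a data frame
#'
#' @param x a [SummaryFunction] or [EnvelopeResult].
#' @return A `data.frame` in the serialization layout
#'   (`r,value,statistic,n_i,n_j` for summary functions; scales with
#'   observed, lower, upper, null mean and classification for envelopes).
#' @export
setGeneric("asDataFrame", function(x) standardGeneric("asDataFrame"))

#' @rdname asDataFrame
#' @export
setMethod("asDataFrame", "SummaryFunction", function(x) {
  data.frame(r = x@scales, value = x@values, statistic = x@statistic,
             n_i = x@nI, n_j = x@nJ)
})

#' @rdname asDataFrame
#' @export
setMethod("asDataFrame", "EnvelopeResult", function(x) {
  data.frame(r = x@scales, observed = x@observed, lower = x@lower,
             upper = x@upper, null_mean = x@nullMean,
             classification = envelopeClassification(x))
})
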