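#' Rectangular observation window
#'
#' A rectangular plot window in metres, the spatial domain of all point
#' patterns. The default corresponds to a 9-ha (300 x 300 m) forest dynamics
#' plot with its origin at the plot corner.
#'
#' @slot xMin,xMax,yMin,yMax window bounds in metres.
#' @export
setClass("Window",
         representation(xMin = "numeric", xMax = "numeric",
                        yMin = "numeric", yMax = "numeric"))

setValidity("Window", function(object) {
  msg <- NULL
  for (s in c("xMin", "xMax", "yMin", "yMax")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  }
  if (is.null(msg)) {
    if (object@xMax <= object@xMin) msg <- c(msg, "xMax must exceed xMin")
    if (object@yMax <= object@yMin) msg <- c(msg, "yMax must exceed yMin")
  }
  if (is.null(msg)) TRUE else msg
})

#' @param xMin,xMax,yMin,yMax window bounds in metres.
#' @return A `Window` object.
#' @examples
#' Window()               # the default 300 x 300 m plot
#' Window(0, 100, 0, 50)
#' @rdname Window-class
#' @export
Window <- function(xMin = 0, xMax = 300, yMin = 0, yMax = 300) {
  new("Window", xMin = xMin, xMax = xMax, yMin = yMin, yMax = yMax)
}

#' @param window a `Window`.
#' @return `windowArea()`: the window area in square metres.
#' @rdname Window-class
#' @export
windowArea <- function(window) {
  stopifnot(is(window, "Window"))
  (window@xMax - window@xMin) * (window@yMax - window@yMin)
}

setMethod("show", "Window", function(object) {
  cat(sprintf("Window: [%g, %g] x [%g, %g] m (area %g m^2)\n",
              object@xMin, object@xMax, object@yMin, object@yMax,
              windowArea(object)))
})

#' Marked planar point pattern
#'
#' A set of points at continuous coordinates inside a rectangular [Window],
#' optionally carrying per-point marks (species, life stage, dbh, ...).
#' This is the substrate of all spatial statistics in the package.
#'
#' @slot x,y point coordinates in metres.
#' @slot window the observation [Window].
#' @slot marks a `data.frame` with one row per point (possibly zero columns).
#' @export
setClass("PointPattern",
         representation(x = "numeric", y = "numeric",
                        window = "Window", marks = "data.frame"))

setValidity("PointPattern", function(object) {
  msg <- NULL
  if (length(object@x) != length(object@y))
    msg <- c(msg, "x and y must have equal length")
  w <- object@window
  if (length(object@x) && (any(object@x < w@xMin - 1e-9) ||
                           any(object@x > w@xMax + 1e-9) ||
                           any(object@y < w@yMin - 1e-9) ||
                           any(object@y > w@yMax + 1e-9)))
    msg <- c(msg, "all points must lie inside the window")
  if (nrow(object@marks) && nrow(object@marks) != length(object@x))
    msg <- c(msg, "marks must have one row per point")
  if (is.null(msg)) TRUE else msg
})

#' @param x,y point coordinates in metres.
#' @param window the observation [Window].
#' @param marks optional `data.frame` of per-point marks.
#' @return A `PointPattern`.
#' @examples
#' pp <- PointPattern(c(10, 20), c(30, 40), Window(0, 100, 0, 100))
#' npoints(pp)
#' intensity(pp)
#' @rdname PointPattern-class
#' @export
PointPattern <- function(x, y, window = Window(), marks = NULL) {
  if (is.null(marks)) marks <- data.frame()[seq_along(x), , drop = FALSE]
  new("PointPattern", x = as.numeric(x), y = as.numeric(y),
      window = window, marks = as.data.frame(marks))
}

setMethod("show", "PointPattern", function(object) {
  cat(sprintf("PointPattern: %d points in [%g, %g] x [%g, %g] m",
              length(object@x), object@window@xMin, object@window@xMax,
              object@window@yMin, object@window@yMax))
  if (ncol(object@marks))
    cat(sprintf("; marks: %s", paste(names(object@marks), collapse = ", ")))
  cat("\n")
})

#' @rdname PointPattern-class
#' @param i index vector for subsetting points.
#' @param j,drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "PointPattern", function(x, i, j, ..., drop = TRUE) {
  PointPattern(x@x[i], x@y[i], x@window,
               if (ncol(x@marks)) x@marks[i, , drop = FALSE] else NULL)
})

#' Estimator resolution settings
#'
#' Resolution of the grid-based second-order estimators: the cell size of the
#' area-correction grid, the ring width of the pair-correlation annuli, and
#' the distance scales at which statistics are evaluated. Defaults follow
#' common practice for a 300 x 300 m plot: 1 m^2 grid cells, a 3 m ring
#' width, and scales 0-30 m in 1 m steps. Scale r = 0 denotes the first
#' annulus, `[0, ring_width / 2]`.
#'
#' @slot cellSize grid cell side length (m).
#' @slot ringWidth annulus width (m).
#' @slot scales strictly increasing, non-negative distances r (m).
#' @export
setClass("EstimatorConfig",
         representation(cellSize = "numeric", ringWidth = "numeric",
                        scales = "numeric"))

setValidity("EstimatorConfig", function(object) {
  msg <- NULL
  if (length(object@cellSize) != 1L || object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (length(object@ringWidth) != 1L || object@ringWidth <= 0)
    msg <- c(msg, "ringWidth must be a single positive number")
  if (!length(object@scales) || any(object@scales < 0) ||
      any(diff(object@scales) <= 0))
    msg <- c(msg, "scales must be non-negative and strictly increasing")
  if (is.null(msg)) TRUE else msg
})

#' @param cellSize grid cell side length (m).
#' @param ringWidth annulus width (m).
#' @param scales distances r at which to evaluate statistics (m).
#' @return An `EstimatorConfig`.
#' @rdname EstimatorConfig-class
#' @export
estimatorConfig <- function(cellSize = 1, ringWidth = 3, scales = 0:30) {
  new("EstimatorConfig", cellSize = cellSize, ringWidth = ringWidth,
      scales = as.numeric(scales))
}

#' Tabulated second-order summary function
#'
#' A spatial summary statistic (g, bivariate g_ij, K, or L) tabulated over
#' distance scales, together with the estimator settings and the sizes of the
#' point patterns it was computed from. Values may be `NA` at scales where
#' the statistic was not computable.
#'
#' @slot scales distances r (m).
#' @slot values statistic values, one per scale.
#' @slot statistic one of `"g"`, `"g_ij"`, `"K"`, `"L"`.
#' @slot nI,nJ numbers of focal (i) and neighbour (j) points.
#' @slot config the [EstimatorConfig] used.
#' @export
setClass("SummaryFunction",
         representation(scales = "numeric", values = "numeric",
                        statistic = "character",
                        nI = "integer", nJ = "integer",
                        config = "EstimatorConfig"))

setValidity("SummaryFunction", function(object) {
  msg <- NULL
  if (length(object@scales) != length(object@values))
    msg <- c(msg, "scales and values must have equal length")
  if (!object@statistic %in% c("g", "g_ij", "K", "L"))
    msg <- c(msg, "statistic must be one of g, g_ij, K, L")
  v <- object@values[!is.na(object@values)]
  if (object@statistic %in% c("g", "g_ij", "K") && any(v < -1e-9))
    msg <- c(msg, sprintf("%s values must be non-negative", object@statistic))
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "SummaryFunction", function(object) {
  cat(sprintf("SummaryFunction '%s' at %d scales (%g-%g m), n_i = %d, n_j = %d\n",
              object@statistic, length(object@scales), min(object@scales),
              max(object@scales), object@nI, object@nJ))
})

#' Monte Carlo simulation envelope
#'
#' Pointwise simulation envelopes for a summary function: per scale, the
#' k-th lowest and k-th highest of `nSim` null-model simulations (defaults
#' k = 5, nSim = 999, i.e. the extreme 0.5 % at either end).
#'
#' @slot scales distances r (m).
#' @slot observed observed statistic per scale.
#' @slot lower,upper k-th lowest / k-th highest null values per scale.
#' @slot nullMean pointwise mean of the null simulations.
#' @slot nSim number of null simulations.
#' @slot rank the envelope rank k.
#' @slot seed RNG seed recorded for reproducibility (`NA` if unseeded).
#' @export
setClass("EnvelopeResult",
         representation(scales = "numeric", observed = "numeric",
                        lower = "numeric", upper = "numeric",
                        nullMean = "numeric", nSim = "integer",
                        rank = "integer", seed = "integer"))

setValidity("EnvelopeResult", function(object) {
  msg <- NULL
  n <- length(object@scales)
  if (any(lengths(list(object@observed, object@lower, object@upper,
                       object@nullMean)) != n))
    msg <- c(msg, "observed, lower, upper, nullMean must match scales")
  ok <- !is.na(object@lower) & !is.na(object@upper)
  if (any(object@lower[ok] > object@upper[ok] + 1e-12))
    msg <- c(msg, "lower envelope must not exceed upper envelope")
  if (object@nSim < 19L) msg <- c(msg, "nSim must be at least 19")
  if (object@rank < 1L || 2L * object@rank - 1L > object@nSim)
    msg <- c(msg, "rank k must satisfy 1 <= k and 2k - 1 <= nSim")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "EnvelopeResult", function(object) {
  cl <- table(factor(envelopeClassification(object),
                     levels = c("below", "inside", "above")))
  cat(sprintf(
    "EnvelopeResult: %d scales, %d simulations, rank %d envelope\n  observed below/inside/above: %d/%d/%d scales\n",
    length(object@scales), object@nSim, object@rank,
    cl[["below"]], cl[["inside"]], cl[["above"]]))
})

#' Goodness-of-fit test result
#'
#' The Loosmore-Ford goodness-of-fit u statistic: the squared deviation of a
#' summary function from its leave-one-out null mean, summed over a scale
#' range, with a rank-based Monte Carlo P value.
#'
#' @slot uObserved the observed u statistic.
#' @slot uNull u statistics of the null simulations.
#' @slot pValue rank-based P value in `[1/(nSim+1), 1]`.
#' @slot scaleRange the scale interval (m) the deviation was summed over.
#' @export
setClass("GofResult",
         representation(uObserved = "numeric", uNull = "numeric",
                        pValue = "numeric", scaleRange = "numeric"))

setValidity("GofResult", function(object) {
  msg <- NULL
  nsim <- length(object@uNull)
  if (object@pValue < 1 / (nsim + 1) - 1e-12 || object@pValue > 1 + 1e-12)
    msg <- c(msg, "pValue must lie in [1/(nSim+1), 1]")
  if (length(object@scaleRange) != 2L)
    msg <- c(msg, "scaleRange must be length 2")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "GofResult", function(object) {
  cat(sprintf("GofResult: u = %.4g, P = %.4g (%d simulations, scales %g-%g m)\n",
              object@uObserved, object@pValue, length(object@uNull),
              object@scaleRange[1], object@scaleRange[2]))
})

#' Habitat-heterogeneity screening result
#'
#' Result of testing the adult pattern of one species against complete
#' spatial randomness with the L function: aggregation at scales beyond
#' 10 m, where direct tree-tree interactions are assumed negligible, is
#' read as a sign of habitat heterogeneity.
#'
#' @slot species species name.
#' @slot envelope the L-function [EnvelopeResult] against CSR.
#' @slot gof the [GofResult] over the tested scale range.
#' @slot aggregatedBeyond10m `TRUE` when L exceeds the upper envelope at some
#'   r > 10 m and the GOF P value is below the screening threshold.
#' @slot nAdults number of adult stems tested.
#' @export
setClass("HabitatTestResult",
         representation(species = "character", envelope = "EnvelopeResult",
                        gof = "GofResult", aggregatedBeyond10m = "logical",
                        nAdults = "integer"))

setMethod("show", "HabitatTestResult", function(object) {
  cat(sprintf(
    "HabitatTestResult: %s (%d adults)\n  GOF P = %.4g; aggregated beyond 10 m: %s\n",
    object@species, object@nAdults, object@gof@pValue,
    object@aggregatedBeyond10m))
})

#' Conspecific density-dependent thinning result
#'
#' Per-species output of the later-stage analysis: additional aggregation of
#' saplings and juveniles relative to adult controls, the thinning statistic
#' d(r) = a_juveniles(r) - a_saplings(r), its maximum d_max over 0-30 m, the
#' per-scale classifications, and the thinning verdict.
#'
#' @slot species species name.
#' @slot scales distances r (m).
#' @slot aSap,aJuv additional aggregation a_i(r) for saplings and juveniles.
#' @slot d the thinning statistic d(r).
#' @slot dMax,dMaxScale maximum of d(r) and the scale where it is attained.
#' @slot sapEnvelope,juvEnvelope random-labeling envelopes for a_i(r).
#' @slot sapGof,juvGof GOF tests over the local scale range.
#' @slot sapClass,juvClass per-scale classification: `"aggregation"`,
#'   `"random"`, or `"regular"`.
#' @slot thinningDetected `TRUE` when saplings show significant additional
#'   aggregation at some scale within the local range and d(r) > 0 there.
#' @slot controlMode `"observed_adults"` or `"randomized_adults"`.
#' @export
setClass("ThinningResult",
         representation(species = "character", scales = "numeric",
                        aSap = "numeric", aJuv = "numeric", d = "numeric",
                        dMax = "numeric", dMaxScale = "numeric",
                        sapEnvelope = "EnvelopeResult",
                        juvEnvelope = "EnvelopeResult",
                        sapGof = "GofResult", juvGof = "GofResult",
                        sapClass = "character", juvClass = "character",
                        thinningDetected = "logical",
                        controlMode = "character"))

setValidity("ThinningResult", function(object) {
  msg <- NULL
  dd <- object@aJuv - object@aSap
  same <- is.na(dd) == is.na(object@d) &
    (is.na(dd) | abs(dd - object@d) < 1e-9)
  if (!all(same))
    msg <- c(msg, "d must equal aJuv - aSap elementwise (NA propagating)")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ThinningResult", function(object) {
  cat(sprintf(
    "ThinningResult: %s (controls: %s)\n  d_max = %.3g at r = %g m; thinning detected: %s\n  sapling GOF P = %.4g, juvenile GOF P = %.4g\n",
    object@species, object@controlMode, object@dMax, object@dMaxScale,
    object@thinningDetected, object@sapGof@pValue, object@juvGof@pValue))
})

#' Fitted seedling-survival model
#'
#' One binomial (logit link) mixed model of seedling survival, fitted by
#' Laplace-approximated maximum likelihood, with its coefficient table,
#' random-effect variances, log-likelihood and AIC.
#'
#' @slot modelId model number 1-9 of the standard comparison set.
#' @slot coefficients `data.frame` with columns term, estimate, se, z, p.
#' @slot ranef `data.frame` of random-effect standard deviations.
#' @slot logLik maximized log-likelihood.
#' @slot aic Akaike information criterion, `2k - 2 logLik` with k counting
#'   fixed effects and variance components.
#' @slot nPar number of estimated parameters k.
#' @slot nObs number of observations.
#' @slot converged honest convergence flag.
#' @slot fit the underlying fitted model object.
#' @export
setClass("ModelFit",
         representation(modelId = "integer", coefficients = "data.frame",
                        ranef = "data.frame", logLik = "numeric",
                        aic = "numeric", nPar = "integer", nObs = "integer",
                        converged = "logical", fit = "ANY"))

setValidity("ModelFit", function(object) {
  if (is.finite(object@aic) &&
      abs(object@aic - (2 * object@nPar - 2 * object@logLik)) > 1e-6)
    "AIC must equal 2k - 2 logLik" else TRUE
})

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit: model %d, n = %d, logLik = %.2f, AIC = %.1f%s\n",
              object@modelId, object@nObs, object@logLik, object@aic,
              if (object@converged) "" else " (NOT converged)"))
  print(object@coefficients, digits = 3, row.names = FALSE)
})

#' Nine-model AIC comparison
#'
#' The nine seedling-survival model structures fitted to one record set,
#' their AICs, and the best fit (minimum AIC; ties broken toward the model
#' with fewer parameters).
#'
#' @slot fits list of [ModelFit] objects (converged or flagged).
#' @slot aicTable `data.frame` with columns model, df, aic, converged.
#' @slot bestFitId model id attaining the minimum AIC among converged fits.
#' @slot datasetLabel e.g. `"whole"`, `"subset"`, or `"species:<name>"`.
#' @export
setClass("ModelComparison",
         representation(fits = "list", aicTable = "data.frame",
                        bestFitId = "integer", datasetLabel = "character"))

setMethod("show", "ModelComparison", function(object) {
  cat(sprintf("ModelComparison (%s): best fit = model %d\n",
              object@datasetLabel, object@bestFitId))
  print(object@aicTable, digits = 6, row.names = FALSE)
})
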