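# Grid-based (Wiegand-Moloney style) second-order estimators. Points are
# kept at continuous coordinates; only the area normalization is
# discretized: the area of an annulus (or disc) around a focal point is the
# count of grid cells whose centres lie both in the annulus and in the
# window, times the cell area. No Ripley isotropic correction is applied.

# Annulus bounds for each scale: [max(r - w/2, 0), r + w/2]; a lower bound
# of -1 marks "include distance zero" so the first annulus is closed at 0.
annulusBounds <- function(scales, ringWidth) {
  lo <- scales - ringWidth / 2
  lo[lo <= 0] <- -1
  list(lo = lo, hi = scales + ringWidth / 2)
}

# Sum over focal points of annulus pair counts and annulus cell counts.
# Returns list(num, cells): numeric vectors over scales.
annulusSums <- function(xi, yi, xj, yj, window, config, self) {
  b <- annulusBounds(config@scales, config@ringWidth)
  numHi <- .cumPairCounts(xi, yi, xj, yj, b$hi, self)
  numLo <- .cumPairCounts(xi, yi, xj, yj, b$lo, self)
  cellsHi <- colSums(.cumCellCounts(xi, yi, b$hi, window@xMin, window@xMax,
                                    window@yMin, window@yMax,
                                    config@cellSize))
  cellsLo <- colSums(.cumCellCounts(xi, yi, b$lo, window@xMin, window@xMax,
                                    window@yMin, window@yMax,
                                    config@cellSize))
  list(num = numHi - numLo, cells = cellsHi - cellsLo)
}

# Fast internal pcf curve on raw coordinates; returns values only.
pcfCurve <- function(xi, yi, xj, yj, window, config, self) {
  s <- annulusSums(xi, yi, xj, yj, window, config, self)
  area <- s$cells * config@cellSize^2
  lambda <- if (self) (length(xj) - 1) / windowArea(window)
            else length(xj) / windowArea(window)
  g <- s$num / (lambda * area)
  g[area <= 0] <- NA_real_
  g
}

#' Estimate the (bivariate) pair correlation function on a grid
#'
#' Estimates g(r) (univariate) or g_ij(r) (bivariate, neighbours drawn from
#' a second pattern) with ring-width annuli and grid-cell area
#' normalization: for each focal point the annulus area is the area of the
#' grid cells whose centres fall inside both the annulus and the window,
#' which handles plot edges without an isotropic correction. The estimate at
#' scale r is the summed neighbour count over focal points divided by
#' lambda_j times the summed annulus area, where lambda_j is the neighbour
#' intensity: `n_j / |W|` in bivariate mode and `(n - 1) / |W|` in
#' univariate mode (the conditional-on-n choice that makes E g = 1 exact
#' under binomial CSR). Self pairs are excluded in univariate mode.
#'
#' @param patternI focal [PointPattern] (cases).
#' @param patternJ neighbour [PointPattern] (controls); omit or pass
#'   `patternI` itself for the univariate g.
#' @param config an [EstimatorConfig].
#' @return A [SummaryFunction] with statistic `"g"` or `"g_ij"`; values are
#'   `NA` at scales whose in-window annulus area vanishes.
#' @examples
#' pp <- simulateCSR(200, Window(0, 100, 0, 100), seed = 1)
#' estimatePcf(pp, config = estimatorConfig(scales = 0:10))
#' @export
estimatePcf <- function(patternI, patternJ = NULL,
                        config = estimatorConfig()) {
  self <- is.null(patternJ) || identical(patternJ, patternI)
  if (self) patternJ <- patternI
  if (!identical(patternI@window, patternJ@window))
    stop("patterns must share a window")
  if (self && npoints(patternI) < 2)
    stop("insufficient points: univariate g needs at least 2")
  if (!self && (npoints(patternI) < 1 || npoints(patternJ) < 1))
    stop("insufficient points: bivariate g needs at least 1 point per pattern")
  vals <- pcfCurve(patternI@x, patternI@y, patternJ@x, patternJ@y,
                   patternI@window, config, self)
  new("SummaryFunction", scales = config@scales, values = vals,
      statistic = if (self) "g" else "g_ij",
      nI = npoints(patternI), nJ = npoints(patternJ), config = config)
}

# Fast internal K curve; r = 0 gives K = 0 by definition.
kCurve <- function(x, y, window, config) {
  scales <- config@scales
  num <- .cumPairCounts(x, y, x, y, scales, TRUE)
  cells <- colSums(.cumCellCounts(x, y, scales, window@xMin, window@xMax,
                                  window@yMin, window@yMax, config@cellSize))
  area <- cells * config@cellSize^2
  lambda <- (length(x) - 1) / windowArea(window)
  K <- pi * scales^2 * num / (lambda * area)
  K[scales == 0] <- 0
  K[scales > 0 & area <= 0] <- NA_real_
  K
}

#' Estimate Ripley's K with grid-cell area normalization
#'
#' Cumulative analogue of [estimatePcf()]: the disc of radius r around each
#' focal point is area-normalized by the count of grid cells whose centres
#' lie in both the disc and the window, so that
#' `K(r) = pi r^2 * sum(counts) / (lambda * sum(areas))` with
#' `lambda = (n - 1) / |W|`. `K(0) = 0` by definition.
#'
#' @inheritParams estimatePcf
#' @param pattern the [PointPattern] (n >= 2).
#' @return A [SummaryFunction] with statistic `"K"`.
#' @export
estimateK <- function(pattern, config = estimatorConfig()) {
  if (npoints(pattern) < 2)
    stop("insufficient points: K needs at least 2")
  new("SummaryFunction", scales = config@scales,
      values = kCurve(pattern@x, pattern@y, pattern@window, config),
      statistic = "K", nI = npoints(pattern), nJ = npoints(pattern),
      config = config)
}

#' Estimate the L function
#'
#' The variance-stabilized transform `L(r) = sqrt(K(r) / pi) - r` of the
#' grid-normalized K of [estimateK()]; L = 0 under complete spatial
#' randomness, L > 0 indicates aggregation.
#'
#' @inheritParams estimateK
#' @return A [SummaryFunction] with statistic `"L"`.
#' @export
estimateL <- function(pattern, config = estimatorConfig()) {
  K <- estimateK(pattern, config)
  new("SummaryFunction", scales = config@scales,
      values = sqrt(K@values / pi) - config@scales,
      statistic = "L", nI = K@nI, nJ = K@nJ, config = config)
}

#' Write a summary function to CSV
#'
#' Serializes a [SummaryFunction] in the `r,value,statistic,n_i,n_j` layout.
#'
#' @param sf a [SummaryFunction].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSummaryFunction <- function(sf, path) {
  write.csv(asDataFrame(sf), path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Brute-force oracles: O(n^2) pure-R reimplementations with the identical
# annulus / grid-cell normalization, kept deliberately naive (explicit loops
# over points and over every grid cell) so they are an independent check on
# the fast path.

cellCentres <- function(window, cellSize) {
  cx <- seq(window@xMin + cellSize / 2, window@xMax, by = cellSize)
  cy <- seq(window@yMin + cellSize / 2, window@yMax, by = cellSize)
  cx <- cx[cx <= window@xMax - cellSize / 2 + 1e-9]
  cy <- cy[cy <= window@yMax - cellSize / 2 + 1e-9]
  expand.grid(x = cx, y = cy)
}

#' Brute-force oracles for the grid-based estimators
#'
#' Naive O(n^2) reference implementations of [estimatePcf()], [estimateK()]
#' and [estimateL()] using explicit loops over points and grid cells and the
#' same annulus / cell-centre normalization. Intended for verification on
#' small fixtures; orders of magnitude slower than the estimators.
#'
#' @inheritParams estimatePcf
#' @return A numeric vector of statistic values over `config@scales`.
#' @export
pcfBruteForce <- function(patternI, patternJ = NULL,
                          config = estimatorConfig()) {
  self <- is.null(patternJ) || identical(patternJ, patternI)
  if (self) patternJ <- patternI
  window <- patternI@window
  b <- annulusBounds(config@scales, config@ringWidth)
  cells <- cellCentres(window, config@cellSize)
  nI <- npoints(patternI); nJ <- npoints(patternJ)
  lambda <- if (self) (nJ - 1) / windowArea(window)
            else nJ / windowArea(window)
  out <- numeric(length(config@scales))
  for (k in seq_along(config@scales)) {
    lo2 <- if (b$lo[k] < 0) -1 else b$lo[k]^2
    hi2 <- b$hi[k]^2
    count <- 0; ncell <- 0
    for (i in seq_len(nI)) {
      for (j in seq_len(nJ)) {
        if (self && i == j) next
        d2 <- (patternJ@x[j] - patternI@x[i])^2 +
              (patternJ@y[j] - patternI@y[i])^2
        if (d2 > lo2 && d2 <= hi2) count <- count + 1
      }
      for (m in seq_len(nrow(cells))) {
        d2 <- (cells$x[m] - patternI@x[i])^2 + (cells$y[m] - patternI@y[i])^2
        if (d2 > lo2 && d2 <= hi2) ncell <- ncell + 1
      }
    }
    area <- ncell * config@cellSize^2
    out[k] <- if (area > 0) count / (lambda * area) else NA_real_
  }
  out
}

#' @rdname pcfBruteForce
#' @param pattern the [PointPattern].
#' @export
lBruteForce <- function(pattern, config = estimatorConfig()) {
  window <- pattern@window
  cells <- cellCentres(window, config@cellSize)
  n <- npoints(pattern)
  lambda <- (n - 1) / windowArea(window)
  K <- numeric(length(config@scales))
  for (k in seq_along(config@scales)) {
    r <- config@scales[k]
    if (r == 0) { K[k] <- 0; next }
    r2 <- r^2
    count <- 0; ncell <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        d2 <- (pattern@x[j] - pattern@x[i])^2 + (pattern@y[j] - pattern@y[i])^2
        if (d2 <= r2) count <- count + 1
      }
      for (m in seq_len(nrow(cells))) {
        d2 <- (cells$x[m] - pattern@x[i])^2 + (cells$y[m] - pattern@y[i])^2
        if (d2 <= r2) ncell <- ncell + 1
      }
    }
    area <- ncell * config@cellSize^2
    K[k] <- if (area > 0) pi * r2 * count / (lambda * area) else NA_real_
  }
  sqrt(K / pi) - config@scales
}
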