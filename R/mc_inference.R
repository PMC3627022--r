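# Null-model simulation, envelope construction and the goodness-of-fit test.

# Evaluate an expression under a temporary RNG state seeded by `seed`
# (NULL = use the current stream). Restores the caller's RNG state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Simulate complete spatial randomness
#'
#' Draws `n` points uniformly and independently in the window (the
#' conditional-on-n, binomial variant of the homogeneous Poisson process, so
#' envelopes compare patterns of the observed size). Reproducible under
#' `seed`.
#'
#' @param n number of points (>= 0).
#' @param window the [Window] to fill.
#' @param seed optional RNG seed; the caller's RNG state is restored.
#' @return A [PointPattern].
#' @examples
#' identical(coords(simulateCSR(5, seed = 1)), coords(simulateCSR(5, seed = 1)))
#' @export
simulateCSR <- function(n, window = Window(), seed = NULL) {
  stopifnot(n >= 0)
  withSeed(seed, {
    PointPattern(runif(n, window@xMin, window@xMax),
                 runif(n, window@yMin, window@yMax), window)
  })
}

#' Randomly permute case/control labels over fixed locations
#'
#' The random-labeling null model of the case-control design: the joint
#' point pattern keeps every location, and its `label` mark (values
#' `"case"` / `"control"`) is permuted uniformly at random, conserving both
#' label counts. Under the null that cases are a random thinning of the
#' joint process, any label-contrast statistic is exchangeable across
#' permutations.
#'
#' @param joint a [PointPattern] whose marks contain a `label` column with
#'   values `"case"` and `"control"`.
#' @param seed optional RNG seed.
#' @return The relabeled [PointPattern].
#' @export
randomLabelPermutation <- function(joint, seed = NULL) {
  lab <- joint@marks$label
  if (is.null(lab))
    stop("joint pattern must carry a 'label' mark")
  if (sum(lab == "case") < 2 || sum(lab == "control") < 2)
    stop("need at least 2 points of each label")
  withSeed(seed, {
    out <- joint
    out@marks$label <- sample(lab)
    out
  })
}

# Coerce a list of SummaryFunctions (or a numeric matrix, simulations in
# rows) to a matrix of null values, checking the scale grid.
nullMatrix <- function(nullFunctions, scales) {
  if (is.matrix(nullFunctions)) {
    if (ncol(nullFunctions) != length(scales))
      stop("null function matrix does not match the scale grid")
    return(nullFunctions)
  }
  vals <- lapply(nullFunctions, function(f) {
    if (is(f, "SummaryFunction")) {
      if (!isTRUE(all.equal(f@scales, scales)))
        stop("null functions must share the observed scale grid")
      f@values
    } else as.numeric(f)
  })
  do.call(rbind, vals)
}

# Rank-k envelope from a raw observed vector and a null matrix.
envelopeFromMatrix <- function(scalesVec, obs, H, k, seed = NULL) {
  nSim <- nrow(H)
  if (nSim < 2 * k - 1)
    stop("need at least 2k - 1 simulations for a rank-k envelope")
  lower <- apply(H, 2, function(v) sort(v)[k])
  upper <- apply(H, 2, function(v) sort(v, decreasing = TRUE)[k])
  new("EnvelopeResult", scales = scalesVec, observed = obs,
      lower = lower, upper = upper, nullMean = colMeans(H),
      nSim = as.integer(nSim), rank = as.integer(k),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Build pointwise Monte Carlo simulation envelopes
#'
#' Per scale, the lower envelope is the k-th smallest and the upper envelope
#' the k-th largest of the null-simulation values; with the defaults
#' (k = 5, 999 simulations) these are the extreme 0.5 % cases at either
#' end, giving a per-tail pointwise non-coverage of k / (nSim + 1) under the
#' null.
#'
#' @param observed the observed [SummaryFunction].
#' @param nullFunctions list of null [SummaryFunction]s (or a numeric matrix
#'   with one simulation per row) on the same scale grid.
#' @param k envelope rank (default 5).
#' @param seed optional seed to record in the result metadata.
#' @return An [EnvelopeResult].
#' @export
buildEnvelope <- function(observed, nullFunctions, k = 5, seed = NULL) {
  H <- nullMatrix(nullFunctions, observed@scales)
  envelopeFromMatrix(observed@scales, observed@values, H, k, seed)
}

#' Goodness-of-fit test for a summary function
#'
#' The Loosmore-Ford correction for the multiple-scale character of
#' simulation envelopes: for every function k (observed and each null
#' simulation) the statistic `u_k = sum_r (H_k(r) - Hbar_{-k}(r))^2` is the
#' squared deviation from the leave-one-out mean of all other functions,
#' summed over the scales in `scaleRange`. The P value is the rank of the
#' observed u from the top among all u values, divided by nSim + 1; ties are
#' resolved conservatively (toward the larger P). Scales at which any
#' function is `NA` are dropped from the sum.
#'
#' @inheritParams buildEnvelope
#' @param scaleRange numeric length-2 scale interval (m) over which
#'   deviations are summed.
#' @return A [GofResult].
#' @export
gofTest <- function(observed, nullFunctions, scaleRange = c(0, 30)) {
  H <- rbind(observed@values, nullMatrix(nullFunctions, observed@scales))
  keep <- observed@scales >= scaleRange[1] & observed@scales <= scaleRange[2]
  keep <- keep & colSums(is.na(H)) == 0
  if (sum(keep) < 2)
    stop("scale range must contain at least 2 usable scales")
  H <- H[, keep, drop = FALSE]
  m <- nrow(H)
  tot <- colSums(H)
  # leave-one-out mean: (tot - H_k) / (m - 1)
  u <- vapply(seq_len(m), function(kk) {
    sum((H[kk, ] - (tot - H[kk, ]) / (m - 1))^2)
  }, numeric(1))
  uObs <- u[1]; uNull <- u[-1]
  p <- (1 + sum(uNull >= uObs)) / m
  new("GofResult", uObserved = uObs, uNull = uNull, pValue = p,
      scaleRange = as.numeric(scaleRange))
}

#' Write an envelope result to CSV
#'
#' Serializes an [EnvelopeResult] per scale (observed, bounds, null mean,
#' classification) with the simulation count, rank and seed recorded as
#' comment metadata in the first line.
#'
#' @param env an [EnvelopeResult].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEnvelope <- function(env, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nSim=%d rank=%d seed=%s", env@nSim, env@rank,
                     ifelse(is.na(env@seed), "NA", env@seed)), con)
  write.csv(asDataFrame(env), con, quote = FALSE, row.names = FALSE)
  invisible(path)
}
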