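# Later-stage pipeline: habitat-heterogeneity screening, additional
# aggregation a_i(r) = g_ij(r) - g_ii(r) under random-labeling nulls, the
# thinning statistic d(r) = a_juveniles(r) - a_saplings(r), d_max, and
# species-level summaries.

# GOF machinery shared with gofTest(): observed row first.
gofFromMatrix <- function(obs, H, scalesVec, scaleRange) {
  HH <- rbind(obs, H)
  keep <- scalesVec >= scaleRange[1] & scalesVec <= scaleRange[2]
  keep <- keep & colSums(is.na(HH)) == 0
  if (sum(keep) < 2)
    stop("scale range must contain at least 2 usable scales")
  HH <- HH[, keep, drop = FALSE]
  m <- nrow(HH)
  tot <- colSums(HH)
  u <- vapply(seq_len(m), function(kk) {
    sum((HH[kk, ] - (tot - HH[kk, ]) / (m - 1))^2)
  }, numeric(1))
  new("GofResult", uObserved = u[1], uNull = u[-1],
      pValue = (1 + sum(u[-1] >= u[1])) / m,
      scaleRange = as.numeric(scaleRange))
}

# a_i(r) for one labeling from precomputed pair/cell cumulative counts.
# cumHi/cumLo: 2 x nt matrices (rows case->case, case->control);
# aCase: summed annulus cell areas over case points; lamII, lamIJ:
# neighbour intensities.
aiFromCounts <- function(cumHi, cumLo, aCase, lamII, lamIJ) {
  numCC <- cumHi[1, ] - cumLo[1, ]
  numCJ <- cumHi[2, ] - cumLo[2, ]
  gII <- numCC / (lamII * aCase)
  gIJ <- numCJ / (lamIJ * aCase)
  a <- gIJ - gII
  a[aCase <= 0] <- NA_real_
  a
}

#' Additional aggregation of cases relative to controls
#'
#' The case-control contrast a_i(r) = g_ij(r) - g_ii(r), where i are the
#' cases (a sapling or juvenile pattern) and j the controls (adults).
#' Because the pair correlation function is invariant under random thinning,
#' a_i(r) = 0 when cases are a random thinning of the joint pattern,
#' irrespective of habitat heterogeneity shared with the controls; a_i(r) <
#' 0 means cases are aggregated beyond the clustering they share with
#' controls. Inference uses the random-labeling null model: case/control
#' labels are permuted over the fixed joint locations `nSim` times, a_i is
#' recomputed for each permutation, rank-k envelopes are built, and a
#' goodness-of-fit test is applied over `gofRange`.
#'
#' Scales where the observed a_i falls below the lower envelope are
#' classified `"aggregation"`, above the upper envelope `"regular"`, and
#' `"random"` otherwise.
#'
#' @param cases focal [PointPattern] (n >= 2).
#' @param controls control [PointPattern] (n >= 2) in the same window.
#' @param config an [EstimatorConfig].
#' @param nSim number of random relabelings (default 999).
#' @param k envelope rank (default 5).
#' @param seed optional RNG seed.
#' @param gofRange scale interval (m) for the GOF test (default 0-10, the
#'   range over which direct tree-tree interactions are assumed to act).
#' @return A list with elements `a` (observed a_i per scale), `envelope`
#'   (an [EnvelopeResult]), `gof` (a [GofResult]), `classification`, and
#'   `nullValues` (the nSim x length(scales) matrix of relabeled a_i
#'   curves, for calibration diagnostics).
#' @export
additionalAggregation <- function(cases, controls,
                                  config = estimatorConfig(),
                                  nSim = 999, k = 5, seed = NULL,
                                  gofRange = c(0, 10)) {
  if (npoints(cases) < 2 || npoints(controls) < 2)
    stop("degenerate patterns: need at least 2 cases and 2 controls")
  if (!identical(cases@window, controls@window))
    stop("patterns must share a window")
  window <- cases@window
  x <- c(cases@x, controls@x); y <- c(cases@y, controls@y)
  n <- length(x); nCase <- npoints(cases); nCtrl <- npoints(controls)
  isCase <- c(rep(TRUE, nCase), rep(FALSE, nCtrl))
  b <- annulusBounds(config@scales, config@ringWidth)
  nt <- length(config@scales)
  binsHi <- .pairBinMatrix(x, y, b$hi)
  binsLo <- .pairBinMatrix(x, y, b$lo)
  cellHi <- .cumCellCounts(x, y, b$hi, window@xMin, window@xMax,
                           window@yMin, window@yMax, config@cellSize)
  cellLo <- .cumCellCounts(x, y, b$lo, window@xMin, window@xMax,
                           window@yMin, window@yMax, config@cellSize)
  cellAnn <- (cellHi - cellLo) * config@cellSize^2
  lamII <- (nCase - 1) / windowArea(window)
  lamIJ <- nCtrl / windowArea(window)

  aiFor <- function(lab) {
    aiFromCounts(.labelPairCum(binsHi, lab, nt), .labelPairCum(binsLo, lab, nt),
                 colSums(cellAnn[lab, , drop = FALSE]), lamII, lamIJ)
  }
  aObs <- aiFor(isCase)
  H <- withSeed(seed, {
    t(vapply(seq_len(nSim), function(s) aiFor(sample(isCase)), numeric(nt)))
  })
  env <- envelopeFromMatrix(config@scales, aObs, H, k, seed)
  gof <- gofFromMatrix(aObs, H, config@scales, gofRange)
  cl <- envelopeClassification(env)
  classification <- ifelse(cl == "below", "aggregation",
                           ifelse(cl == "above", "regular",
                                  ifelse(cl == "inside", "random",
                                         NA_character_)))
  list(a = aObs, envelope = env, gof = gof,
       classification = classification, nullValues = H)
}

#' Test adult spatial patterns for habitat heterogeneity
#'
#' Compares the L function of the adult pattern of a species against rank-k
#' envelopes from conditional CSR simulations, with a GOF test over
#' `gofRange`. Aggregation at scales beyond 10 m -- where direct tree-tree
#' interactions are assumed negligible -- is interpreted as a signature of
#' large-scale habitat heterogeneity: the result is flagged when L exceeds
#' the upper envelope at some r > 10 m and the GOF P value is below
#' `alpha`.
#'
#' @param adults adult [PointPattern] (n >= 2).
#' @param config an [EstimatorConfig] (default scales 0-30 m).
#' @param nSim number of CSR simulations (default 999).
#' @param k envelope rank (default 5).
#' @param seed optional RNG seed.
#' @param gofRange GOF scale interval (default 0-30 m).
#' @param alpha GOF screening threshold (default 0.005).
#' @param species species name recorded in the result.
#' @return A [HabitatTestResult].
#' @export
habitatHeterogeneityTest <- function(adults, config = estimatorConfig(),
                                     nSim = 999, k = 5, seed = NULL,
                                     gofRange = c(0, 30), alpha = 0.005,
                                     species = "unknown") {
  if (npoints(adults) < 2)
    stop("insufficient adults: need at least 2")
  window <- adults@window
  n <- npoints(adults)
  obs <- estimateL(adults, config)
  H <- withSeed(seed, {
    t(vapply(seq_len(nSim), function(s) {
      p <- simulateCSR(n, window)
      K <- kCurve(p@x, p@y, window, config)
      sqrt(K / pi) - config@scales
    }, numeric(length(config@scales))))
  })
  env <- buildEnvelope(obs, H, k = k, seed = seed)
  gof <- gofFromMatrix(obs@values, H, config@scales, gofRange)
  cl <- envelopeClassification(env)
  flag <- isTRUE(any(cl == "above" & config@scales > 10, na.rm = TRUE) &&
                 gof@pValue < alpha)
  new("HabitatTestResult", species = species, envelope = env, gof = gof,
      aggregatedBeyond10m = flag, nAdults = as.integer(n))
}

#' Change in additional aggregation between stages
#'
#' The conspecific thinning statistic d(r) = a_juveniles(r) - a_saplings(r):
#' a decline in additional aggregation from saplings to juveniles (d > 0
#' where a_saplings < 0) indicates conspecific density-dependent thinning
#' over the sapling-to-juvenile transition. Scales where either input is
#' missing propagate as `NA`.
#'
#' @param aSap,aJuv additional-aggregation vectors on the same scale grid.
#' @return Numeric vector d(r).
#' @export
thinningStatistic <- function(aSap, aJuv) {
  if (length(aSap) != length(aJuv))
    stop("mismatched scale grids")
  aJuv - aSap
}

#' Locate the maximum thinning strength
#'
#' d_max is the maximum of d(r) over the scale grid (canonically 0-30 m),
#' the maximum strength of conspecific thinning. Ties are broken toward the
#' smallest scale; missing values are ignored.
#'
#' @param d thinning statistic d(r).
#' @param scalesVec the scale grid (m).
#' @return A list with elements `dMax` and `scale`.
#' @examples
#' findDmax(c(NA, 0.1, 0.8, 0.8, 0.2), 0:4)  # 0.8 at r = 2
#' @export
findDmax <- function(d, scalesVec = seq_along(d) - 1) {
  if (length(d) != length(scalesVec))
    stop("d and scales must have equal length")
  if (all(is.na(d)))
    stop("all d values are missing")
  m <- max(d, na.rm = TRUE)
  idx <- which(!is.na(d) & d == m)[1]
  list(dMax = m, scale = scalesVec[idx])
}

#' Run the later-stage thinning analysis for one species
#'
#' The full case-control pipeline for a single species: classifies its stems
#' into stages, computes additional aggregation of saplings and of juveniles
#' relative to the adult controls under random-labeling nulls, applies the
#' GOF screening, and derives d(r), d_max and the thinning verdict.
#' Conspecific density-dependent thinning is reported when the sapling
#' GOF P value is below `gofAlpha` and, at some scale within `localRange`,
#' saplings are classified as additionally aggregated while d(r) > 0 there.
#'
#' With `controlMode = "randomized_adults"` the adult locations are replaced
#' by a fresh conditional-CSR draw of the observed adult count, removing the
#' habitat-heterogeneity control; comparing the two modes shows how
#' unmodelled habitat structure displaces apparent thinning to larger
#' scales.
#'
#' @param stems stem `data.frame` with columns `species`, `x`, `y`, `dbh`
#'   and `growth_form`.
#' @param species the focal species.
#' @param window the plot [Window].
#' @param rules stage rule table, see [stageRules()].
#' @param config an [EstimatorConfig].
#' @param controlMode `"observed_adults"` (factor out habitat heterogeneity)
#'   or `"randomized_adults"`.
#' @param nSim number of random relabelings (default 999).
#' @param k envelope rank (default 5).
#' @param seed optional RNG seed.
#' @param gofAlpha GOF screening threshold (default 0.005).
#' @param localRange scale interval (m) for classification and the thinning
#'   verdict (default 0-10).
#' @param minPerStage minimum stems required per stage (default 40); species
#'   below the minimum are skipped with a message and `NULL` is returned.
#' @return A [ThinningResult], or `NULL` when the species is skipped.
#' @export
runThinningPipeline <- function(stems, species, window = Window(),
                                rules = stageRules(),
                                config = estimatorConfig(),
                                controlMode = c("observed_adults",
                                                "randomized_adults"),
                                nSim = 999, k = 5, seed = NULL,
                                gofAlpha = 0.005, localRange = c(0, 10),
                                minPerStage = 40) {
  controlMode <- match.arg(controlMode)
  sp <- stems[stems$species == species, ]
  if (!nrow(sp)) {
    message("skipping ", species, ": no stems")
    return(NULL)
  }
  stage <- classifyStage(sp$dbh, sp$growth_form, rules)
  counts <- table(factor(stage, levels = c("sapling", "juvenile", "adult")))
  if (any(counts < minPerStage)) {
    message("skipping ", species, ": stage counts (",
            paste(counts, collapse = "/"), ") below minimum ", minPerStage)
    return(NULL)
  }
  sap <- PointPattern(sp$x[stage == "sapling"], sp$y[stage == "sapling"],
                      window)
  juv <- PointPattern(sp$x[stage == "juvenile"], sp$y[stage == "juvenile"],
                      window)
  adults <- PointPattern(sp$x[stage == "adult"], sp$y[stage == "adult"],
                         window)
  if (controlMode == "randomized_adults")
    adults <- simulateCSR(npoints(adults), window,
                          seed = if (is.null(seed)) NULL else seed + 7L)
  aaS <- additionalAggregation(sap, adults, config, nSim = nSim, k = k,
                               seed = if (is.null(seed)) NULL else seed + 1L,
                               gofRange = localRange)
  aaJ <- additionalAggregation(juv, adults, config, nSim = nSim, k = k,
                               seed = if (is.null(seed)) NULL else seed + 2L,
                               gofRange = localRange)
  d <- thinningStatistic(aaS$a, aaJ$a)
  dm <- findDmax(d, config@scales)
  local <- config@scales >= localRange[1] & config@scales <= localRange[2]
  detected <- isTRUE(aaS$gof@pValue < gofAlpha &&
                     any(local & aaS$classification == "aggregation" & d > 0,
                         na.rm = TRUE))
  new("ThinningResult", species = species, scales = config@scales,
      aSap = aaS$a, aJuv = aaJ$a, d = d, dMax = dm$dMax,
      dMaxScale = dm$scale, sapEnvelope = aaS$envelope,
      juvEnvelope = aaJ$envelope, sapGof = aaS$gof, juvGof = aaJ$gof,
      sapClass = aaS$classification, juvClass = aaJ$classification,
      thinningDetected = detected, controlMode = controlMode)
}

#' Count species by per-scale classification
#'
#' Summarizes a set of [ThinningResult]s into per-scale counts of species
#' whose cases show additional aggregation, random labeling, or regularity
#' relative to adults, for the sapling and juvenile stages, over the local
#' scale range. Scales with an undefined classification are tallied in
#' `na`; the four columns sum to the number of species at every scale.
#'
#' @param results list of [ThinningResult] objects.
#' @param scaleRange scale interval (m) to tabulate (default 0-10).
#' @return A `data.frame` with columns `stage`, `r`, `aggregation`,
#'   `random`, `regular`, `na` and `n_species`, plus an attribute
#'   `n_thinning` counting species with `thinningDetected`.
#' @export
countClassifications <- function(results, scaleRange = c(0, 10)) {
  results <- Filter(Negate(is.null), results)
  if (!length(results)) stop("no thinning results supplied")
  scalesVec <- results[[1]]@scales
  keep <- scalesVec >= scaleRange[1] & scalesVec <= scaleRange[2]
  tally <- function(slotName) {
    m <- vapply(results, function(r) slot(r, slotName)[keep],
                character(sum(keep)))
    m <- matrix(m, nrow = sum(keep))
    data.frame(
      r = scalesVec[keep],
      aggregation = rowSums(m == "aggregation", na.rm = TRUE),
      random = rowSums(m == "random", na.rm = TRUE),
      regular = rowSums(m == "regular", na.rm = TRUE),
      na = rowSums(is.na(m)),
      n_species = length(results))
  }
  out <- rbind(cbind(stage = "sapling", tally("sapClass")),
               cbind(stage = "juvenile", tally("juvClass")))
  attr(out, "n_thinning") <-
    sum(vapply(results, function(r) r@thinningDetected, logical(1)))
  out
}

#' Tabulate thinning curves across species
#'
#' Builds the summary table of d(r) for a set of species over the local
#' scale range, with d_max and its scale -- the per-species digest of the
#' thinning analysis.
#'
#' @inheritParams countClassifications
#' @return A `data.frame`: one row per species, columns `d_0` ... over the
#'   scale range plus `d_max`, `d_max_scale` and `thinning_detected`.
#' @export
thinningSummaryTable <- function(results, scaleRange = c(0, 10)) {
  results <- Filter(Negate(is.null), results)
  if (!length(results)) stop("no thinning results supplied")
  scalesVec <- results[[1]]@scales
  keep <- scalesVec >= scaleRange[1] & scalesVec <= scaleRange[2]
  dmat <- t(vapply(results, function(r) r@d[keep], numeric(sum(keep))))
  colnames(dmat) <- paste0("d_", scalesVec[keep])
  data.frame(
    species = vapply(results, function(r) r@species, character(1)),
    dmat,
    d_max = vapply(results, function(r) r@dMax, numeric(1)),
    d_max_scale = vapply(results, function(r) r@dMaxScale, numeric(1)),
    thinning_detected = vapply(results, function(r) r@thinningDetected,
                               logical(1)),
    row.names = NULL)
}
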