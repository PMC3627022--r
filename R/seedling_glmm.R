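# Early-stage analysis: neighbourhood covariates, the nine binomial
# mixed-model structures, AIC comparison, and neighbourhood-radius
# selection.

#' Compute neighbourhood covariates for seedlings
#'
#' For each focal seedling: the number of conspecific (`S_CON`),
#' heterospecific (`S_HET`) and all (`S_TOTAL`) seedling neighbours sharing
#' its 4-m^2 quadrat (the focal seedling excluded), and the summed basal
#' area in m^2 of conspecific (`B_CON`), heterospecific (`B_HET`) and all
#' (`B_TOTAL`) stems >= 1 cm dbh within `radius` metres of the quadrat
#' centre (stems strictly beyond the radius are excluded; basal area of one
#' stem is `pi * (dbh / 200)^2` with dbh in cm). Neighbourhoods extending
#' beyond the plot boundary are used as truncated; no edge correction is
#' applied.
#'
#' @param seedlings seedling `data.frame` with columns `quadrat_id`,
#'   `species`, `height_cm` and quadrat-centre coordinates `x`, `y` (as
#'   returned by [readSeedlingCensus()] or [generateSeedlingDataset()]).
#' @param stems stem `data.frame` with columns `species`, `x`, `y`, `dbh`.
#' @param radius neighbourhood radius in metres (default 10).
#' @param registry species allowed for seedlings (default: the stem table's
#'   species); a seedling species outside the registry is an error.
#' @param excludeSpecies species to drop before computing covariates (e.g.
#'   shrubs with no stems >= 1 cm dbh).
#' @return The seedling `data.frame` with columns `H`, `S_CON`, `S_HET`,
#'   `S_TOTAL`, `B_CON`, `B_HET`, `B_TOTAL` appended.
#' @export
computeNeighborCovariates <- function(seedlings, stems, radius = 10,
                                      registry = unique(stems$species),
                                      excludeSpecies = NULL) {
  if (!is.null(excludeSpecies))
    seedlings <- seedlings[!seedlings$species %in% excludeSpecies, ]
  unknown <- setdiff(unique(seedlings$species), registry)
  if (length(unknown))
    stop("seedling species absent from species registry: ",
         paste(unknown, collapse = ", "),
         " (drop them via excludeSpecies or extend the registry)")
  n <- nrow(seedlings)
  qkey <- paste(seedlings$quadrat_id)
  qskey <- paste(seedlings$quadrat_id, seedlings$species)
  qCount <- table(qkey)
  qsCount <- table(qskey)
  S_TOTAL <- as.integer(qCount[qkey]) - 1L
  S_CON <- as.integer(qsCount[qskey]) - 1L
  basal <- pi * (stems$dbh / 200)^2
  B_CON <- numeric(n); B_TOTAL <- numeric(n)
  quads <- unique(seedlings$quadrat_id)
  for (q in quads) {
    rows <- which(seedlings$quadrat_id == q)
    cx <- seedlings$x[rows[1]]; cy <- seedlings$y[rows[1]]
    within <- (stems$x - cx)^2 + (stems$y - cy)^2 <= radius^2
    tot <- sum(basal[within])
    bySp <- tapply(basal[within], stems$species[within], sum)
    B_TOTAL[rows] <- tot
    bc <- bySp[seedlings$species[rows]]
    B_CON[rows] <- ifelse(is.na(bc), 0, bc)
  }
  seedlings$H <- seedlings$height_cm
  seedlings$S_CON <- S_CON
  seedlings$S_HET <- S_TOTAL - S_CON
  seedlings$S_TOTAL <- S_TOTAL
  seedlings$B_CON <- B_CON
  seedlings$B_HET <- B_TOTAL - B_CON
  seedlings$B_TOTAL <- B_TOTAL
  seedlings
}

# Fixed-effect neighbourhood terms of the nine standard model structures.
nineModelTerms <- function() {
  list(`1` = "H",
       `2` = c("H", "S_TOTAL"),
       `3` = c("H", "S_TOTAL", "B_TOTAL"),
       `4` = c("H", "B_TOTAL"),
       `5` = c("H", "S_CON", "S_HET"),
       `6` = c("H", "S_CON", "S_HET", "B_TOTAL"),
       `7` = c("H", "B_CON", "B_HET"),
       `8` = c("H", "S_TOTAL", "B_CON", "B_HET"),
       `9` = c("H", "S_CON", "S_HET", "B_CON", "B_HET"))
}

#' Model formula for one of the nine survival models
#'
#' Builds the `lme4` formula for model `modelId`: the neighbourhood fixed
#' effects of the standard nine-model set, a quadrat random intercept
#' (always), a species random intercept at the community level, and --
#' when habitat controls are on -- canopy openness and topographic class as
#' fixed effects (species level) or additionally as independent
#' species-varying effects (community level: a random openness slope and a
#' species-by-topography intercept, diagonal covariance).
#'
#' @param modelId integer 1-9.
#' @param level `"species"` (single-species data) or `"community"`.
#' @param habitatControls include habitat covariates?
#' @return A formula.
#' @export
survivalModelFormula <- function(modelId, level = c("community", "species"),
                                 habitatControls = FALSE) {
  level <- match.arg(level)
  terms <- nineModelTerms()[[as.character(modelId)]]
  if (is.null(terms)) stop("modelId must be 1..9")
  rhs <- c(terms, "(1 | quadrat_id)")
  if (level == "community") rhs <- c(rhs, "(1 | species)")
  if (habitatControls) {
    rhs <- c(rhs, "canopy_openness", "topo_class")
    if (level == "community")
      rhs <- c(rhs, "(0 + canopy_openness | species)",
               "(1 | species:topo_class)")
  }
  as.formula(paste("survival ~", paste(rhs, collapse = " + ")))
}

# z-score the continuous predictors used by the nine models (+ openness),
# recording centre/scale as attributes.
standardizePredictors <- function(data) {
  vars <- intersect(c("H", "S_CON", "S_HET", "S_TOTAL", "B_CON", "B_HET",
                      "B_TOTAL", "canopy_openness"), names(data))
  scaling <- data.frame(variable = vars, center = NA_real_, scale = NA_real_)
  for (i in seq_along(vars)) {
    v <- data[[vars[i]]]
    mu <- mean(v); sdv <- sd(v)
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
    data[[vars[i]]] <- (v - mu) / sdv
    scaling$center[i] <- mu; scaling$scale[i] <- sdv
  }
  attr(data, "scaling") <- scaling
  data
}

#' Fit one binomial mixed model of seedling survival
#'
#' Fits the model structure `modelId` (see [survivalModelFormula()]) to
#' per-seedling Bernoulli survival outcomes by Laplace-approximated maximum
#' likelihood (`lme4::glmer`, logit link). Continuous predictors are
#' z-scored by default, with the scaling recorded in the returned object.
#' The convergence flag is honest: optimizer failures and convergence
#' warnings mark the fit as non-converged, as does apparent separation
#' (absurd standardized coefficients); singular (boundary) variance
#' estimates do not.
#'
#' @param data seedling records with covariates (see
#'   [computeNeighborCovariates()]) and a binary `survival` column.
#' @param modelId integer 1-9.
#' @param level `"species"` or `"community"` (adds a species random
#'   intercept).
#' @param habitatControls include habitat covariates (needs
#'   `canopy_openness`, `topo_class`)?
#' @param standardize z-score continuous predictors before fitting
#'   (default `TRUE`); set `FALSE` for raw-scale coefficients.
#' @param ... passed on to [lme4::glmer()].
#' @return A [ModelFit].
#' @export
fitSurvivalModel <- function(data, modelId,
                             level = c("community", "species"),
                             habitatControls = FALSE, standardize = TRUE,
                             ...) {
  level <- match.arg(level)
  if (level == "community" && length(unique(data$species)) < 2)
    stop("community-level models need at least 2 species")
  if (length(unique(data$quadrat_id)) < 2)
    stop("need at least 2 quadrats")
  if (standardize) data <- standardizePredictors(data)
  form <- survivalModelFormula(modelId, level, habitatControls)
  warn <- character(0)
  fit <- withCallingHandlers(
    lme4::glmer(form, data = data, family = binomial(link = "logit"),
                nAGQ = 1, ...),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  conv <- fit@optinfo$conv$opt == 0 &&
    !any(grepl("failed to converge", warn, ignore.case = TRUE)) &&
    is.null(fit@optinfo$conv$lme4$code)
  co <- summary(fit)$coefficients
  coefTab <- data.frame(term = rownames(co), estimate = co[, 1],
                        se = co[, 2], z = co[, 3], p = co[, 4],
                        row.names = NULL)
  neigh <- coefTab$term %in% c("H", "S_CON", "S_HET", "S_TOTAL", "B_CON",
                               "B_HET", "B_TOTAL")
  if (standardize && any(abs(coefTab$estimate[neigh]) > 15))
    conv <- FALSE  # symptom of separation on the z-scored scale
  vc <- as.data.frame(lme4::VarCorr(fit))
  ll <- logLik(fit)
  mf <- new("ModelFit", modelId = as.integer(modelId),
            coefficients = coefTab,
            ranef = data.frame(group = vc$grp, name = vc$var1,
                               sd = vc$sdcor),
            logLik = as.numeric(ll), aic = AIC(fit),
            nPar = as.integer(attr(ll, "df")),
            nObs = nrow(data), converged = conv, fit = fit)
  attr(mf, "scaling") <- attr(data, "scaling")
  mf
}

#' Compare the nine survival models by AIC
#'
#' Fits all nine model structures to the identical record set and ranks
#' them by AIC. Species-level comparisons follow the abundance rule used
#' for single-species analyses (at least 100 seedlings of the species);
#' community comparisons can exclude species (e.g. those already showing
#' density dependence species-by-species, to test whether community-wide
#' results are driven by a few species). Non-converged fits are reported
#' but excluded from best-fit selection; AIC ties are broken toward the
#' model with fewer parameters.
#'
#' @inheritParams fitSurvivalModel
#' @param species for `level = "species"`, the focal species.
#' @param excludeSpecies species dropped from the record set first.
#' @param minSeedlings abundance rule for species-level runs (default 100).
#' @return A [ModelComparison].
#' @export
compareNineModels <- function(data, level = c("community", "species"),
                              habitatControls = FALSE, species = NULL,
                              excludeSpecies = NULL, minSeedlings = 100,
                              standardize = TRUE, ...) {
  level <- match.arg(level)
  label <- "whole"
  if (!is.null(excludeSpecies)) {
    data <- data[!data$species %in% excludeSpecies, ]
    label <- "subset"
  }
  if (level == "species") {
    if (is.null(species)) stop("species-level comparison needs a species")
    data <- data[data$species == species, ]
    if (nrow(data) < minSeedlings)
      stop(sprintf("species %s has %d seedlings; need at least %d",
                   species, nrow(data), minSeedlings))
    label <- paste0("species:", species)
  }
  fits <- lapply(1:9, function(id) {
    fitSurvivalModel(data, id, level = level,
                     habitatControls = habitatControls,
                     standardize = standardize, ...)
  })
  aicTable <- data.frame(
    model = 1:9,
    df = vapply(fits, function(f) f@nPar, integer(1)),
    aic = vapply(fits, function(f) f@aic, numeric(1)),
    converged = vapply(fits, function(f) f@converged, logical(1)))
  ok <- aicTable$converged
  if (!any(ok)) stop("no model converged")
  if (!all(ok))
    warning("model(s) ", paste(aicTable$model[!ok], collapse = ", "),
            " did not converge and were excluded from best-fit selection")
  cand <- aicTable[ok, ]
  cand <- cand[order(cand$aic, cand$df), ]
  new("ModelComparison", fits = fits, aicTable = aicTable,
      bestFitId = as.integer(cand$model[1]), datasetLabel = label)
}

#' Select the neighbourhood radius by AIC
#'
#' Recomputes the basal-area covariates for each candidate radius, fits the
#' full model (model 9) on the identical seedling records, and returns the
#' radius with the lowest AIC (ties broken toward the smaller radius).
#'
#' @inheritParams computeNeighborCovariates
#' @inheritParams fitSurvivalModel
#' @param radii candidate radii in metres (default 5, 10, 15, 20).
#' @return A list with elements `radius` (the selection) and `aicTable`.
#' @export
selectNeighborhoodRadius <- function(seedlings, stems,
                                     radii = c(5, 10, 15, 20),
                                     level = c("community", "species"),
                                     standardize = TRUE, ...) {
  level <- match.arg(level)
  radii <- sort(radii)
  aic <- vapply(radii, function(r) {
    cov <- computeNeighborCovariates(seedlings, stems, radius = r)
    fitSurvivalModel(cov, 9, level = level, standardize = standardize,
                     ...)@aic
  }, numeric(1))
  tab <- data.frame(radius = radii, aic = aic)
  list(radius = radii[which.min(aic)], aicTable = tab)
}
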