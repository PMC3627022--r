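# Synthetic stands and seedling censuses with recorded ground truth: the
# generator reproduces the processes the analysis assumes -- dispersal-
# limited clustered recruitment, large-scale habitat-driven intensity
# variation in adults, density-dependent mortality between stages, and
# logistic seedling survival driven by neighbourhood densities -- so every
# pipeline stage is testable without field data.

#' Generate adult trees under a habitat intensity surface
#'
#' Draws a fixed number of adults by rejection sampling against a habitat
#' intensity surface: either a monotone exponential gradient in x,
#' intensity proportional to `exp(gamma * x / x_max)`, or a two-patch
#' (good/bad habitat) surface in which the right half of the window is
#' favourable and the left half has relative intensity `exp(-gamma)`.
#' `gamma = 0` reduces to conditional CSR in both cases.
#'
#' @param n number of adults.
#' @param window the [Window].
#' @param gamma habitat gradient strength (>= 0).
#' @param surface `"gradient"` or `"patches"`.
#' @param seed optional RNG seed.
#' @return A [PointPattern].
#' @export
generateAdults <- function(n, window = Window(), gamma = 0,
                           surface = c("gradient", "patches"),
                           seed = NULL) {
  surface <- match.arg(surface)
  stopifnot(n >= 0, gamma >= 0)
  withSeed(seed, {
    xs <- numeric(0); ys <- numeric(0)
    while (length(xs) < n) {
      m <- max(2 * (n - length(xs)), 16)
      x <- runif(m, window@xMin, window@xMax)
      y <- runif(m, window@yMin, window@yMax)
      xn <- (x - window@xMin) / (window@xMax - window@xMin)
      p <- switch(surface,
                  gradient = exp(gamma * (xn - 1)),
                  patches = ifelse(xn >= 0.5, 1, exp(-gamma)))
      keep <- runif(m) < p
      xs <- c(xs, x[keep]); ys <- c(ys, y[keep])
    }
    PointPattern(xs[seq_len(n)], ys[seq_len(n)], window)
  })
}

#' Generate dispersal-limited offspring around adults
#'
#' Each adult produces a Poisson(`mu`) number of offspring displaced by an
#' isotropic Gaussian with standard deviation `sigma` (the Thomas cluster
#' mechanism of seed dispersal limitation); offspring falling outside
#' `window` are discarded.
#'
#' @param adults adult [PointPattern] (n >= 1).
#' @param sigma dispersal standard deviation (m).
#' @param mu mean offspring per adult.
#' @param seed optional RNG seed.
#' @param window window to retain offspring in (default: the adults'
#'   window; pass a smaller window to crop, e.g. when adults were placed in
#'   a dilated window to emulate a stationary cluster process).
#' @return A [PointPattern] of offspring in `window`.
#' @export
generateOffspring <- function(adults, sigma, mu, seed = NULL,
                              window = adults@window) {
  stopifnot(npoints(adults) >= 1, sigma > 0, mu >= 0)
  withSeed(seed, {
    counts <- rpois(npoints(adults), mu)
    px <- rep(adults@x, counts) + rnorm(sum(counts), 0, sigma)
    py <- rep(adults@y, counts) + rnorm(sum(counts), 0, sigma)
    keep <- px >= window@xMin & px <= window@xMax &
            py >= window@yMin & py <= window@yMax
    PointPattern(px[keep], py[keep], window)
  })
}

#' Theoretical pair correlation function of the Thomas process
#'
#' For a Thomas cluster process with parent intensity `rho`, Gaussian
#' dispersal `sigma` and any offspring mean, the pair correlation function
#' is `g(r) = 1 + exp(-r^2 / (4 sigma^2)) / (4 pi sigma^2 rho)`.
#' `thomasPcfRingAverage()` averages g over the annulus
#' `[max(r - w/2, 0), r + w/2]` with the annular weighting `2 pi t dt`,
#' which is what a ring-width-w estimator targets; the average has the
#' closed form
#' `1 + (exp(-lo^2/(4 s^2)) - exp(-hi^2/(4 s^2))) / (rho pi (hi^2 - lo^2))`.
#'
#' @param r distance(s) in metres.
#' @param sigma dispersal standard deviation (m).
#' @param rho parent intensity (parents per m^2).
#' @param ringWidth estimator ring width (m).
#' @return Numeric vector of g values.
#' @export
thomasPcfTheory <- function(r, sigma, rho) {
  1 + exp(-r^2 / (4 * sigma^2)) / (4 * pi * sigma^2 * rho)
}

#' @rdname thomasPcfTheory
#' @export
thomasPcfRingAverage <- function(r, sigma, rho, ringWidth = 3) {
  lo <- pmax(r - ringWidth / 2, 0)
  hi <- r + ringWidth / 2
  1 + (exp(-lo^2 / (4 * sigma^2)) - exp(-hi^2 / (4 * sigma^2))) /
    (rho * pi * (hi^2 - lo^2))
}

#' Apply density-dependent thinning to a point pattern
#'
#' Each point survives independently with probability
#' `pi0 * exp(-beta * D_i)`, where `D_i` is the number of conspecific
#' points within radius `rho` (the point itself excluded). `beta = 0` is a
#' uniform random thinning, which leaves the expected pair correlation
#' function unchanged; `beta > 0` preferentially removes points in dense
#' conspecific neighbourhoods, the mortality mechanism behind the decline
#' in additional clustering between life stages.
#'
#' @param pattern the [PointPattern] to thin.
#' @param beta density-dependence strength (>= 0).
#' @param rho interaction radius (m), default 5.
#' @param pi0 baseline survival probability in `[0, 1]`.
#' @param seed optional RNG seed.
#' @return A [PointPattern] that is a subset of `pattern`.
#' @export
applyDDThinning <- function(pattern, beta, rho = 5, pi0 = 1, seed = NULL) {
  stopifnot(beta >= 0, rho > 0, pi0 >= 0, pi0 <= 1)
  n <- npoints(pattern)
  if (n == 0) return(pattern)
  withSeed(seed, {
    bins <- .pairBinMatrix(pattern@x, pattern@y, rho)
    D <- rowSums(bins == 1L)  # conspecifics within rho, self excluded
    keep <- rbinom(n, 1, pi0 * exp(-beta * D)) == 1
    pattern[keep]
  })
}

#' Per-species configuration of a synthetic stand
#'
#' The default stand emulates a temperate mixed stand in a 9-ha window:
#' five species spanning growth forms, adult abundances giving all three
#' life stages comfortably above the 40-stem focal rule, dispersal scales
#' sigma of 2-4 m (strongly cluster-forming), moderate habitat gradients,
#' and density-dependent thinning strengths beta from none to strong with a
#' 5 m interaction radius (so that maximum thinning lands at small scales).
#' `pi0Sap` is the uniform retention of recruits into the sapling cohort;
#' `pi0Juv` is the baseline retention of the juvenile cohort before density
#' dependence acts.
#'
#' @param species data.frame of per-species parameters; the default is
#'   described above.
#' @param window the plot [Window].
#' @return A list with components `window` and `species`.
#' @export
standConfig <- function(species = NULL, window = Window()) {
  if (is.null(species))
    species <- data.frame(
      species  = c("PINKOR", "ABINEP", "ACEMON", "TILAMU", "PHISCH"),
      growth_form = c("CL", "CL", "UL", "CS", "S"),
      n_adults = c(180, 130, 150, 110, 80),
      gamma    = c(2, 1.5, 1, 0, 0.5),
      sigma    = c(3, 2.5, 4, 3, 2),
      mu       = c(7, 7, 6, 6, 6),
      beta     = c(0.4, 0.3, 0.2, 0, 0),
      rho      = c(5, 5, 5, 5, 5),
      pi0Sap   = c(0.8, 0.8, 0.8, 0.8, 0.8),
      pi0Juv   = c(0.7, 0.7, 0.7, 0.5, 0.5))
  list(window = window, species = species)
}

# dbh draws for one stage of a growth form; upper margins keep values
# inside the stage interval after rounding to the 0.1 cm census resolution.
drawDbh <- function(stage, growthForm, n, rules = stageRules()) {
  row <- rules[rules$growth_form == growthForm, ]
  switch(stage,
         sapling = runif(n, row$sapling_lower, row$juvenile_lower - 0.05),
         juvenile = runif(n, row$juvenile_lower, row$adult_lower - 0.05),
         adult = row$adult_lower + rexp(n, 1 / 5))
}

#' Simulate a stem-mapped stand with known structure
#'
#' For each configured species: adults are placed under the habitat
#' surface ([generateAdults()]). Recruits are dispersal-limited: they are
#' generated by [generateOffspring()] around recruitment foci (former
#' parents and canopy gaps) drawn independently from the *same* habitat
#' surface as the adults. Decoupling the cluster centres from the surviving
#' adults is deliberate: were recruits centred on the adult pattern itself,
#' the parent-offspring cross correlation g_ij would exceed the sibling
#' correlation g_ii (their Thomas-process peaks are `1/(2 pi sigma^2 rho)`
#' versus `1/(4 pi sigma^2 rho)`), inverting the additional-aggregation
#' signature a_i < 0 that dispersal-limited recruitment shows in real
#' stands, where current survivors are not the centres of current recruit
#' clusters. The recruit pool is split at random into a sapling half,
#' retained uniformly at rate `pi0Sap`, and a juvenile half, subjected to
#' density-dependent thinning ([applyDDThinning()] with the species'
#' `beta`, `rho`, `pi0Juv`); both cohorts thus share one generative law and
#' differ only in the mortality acting on them. dbh values are drawn within
#' the stage intervals of the species' growth form, so [classifyStage()]
#' recovers the generating cohorts exactly.
#'
#' @param config a [standConfig()] list.
#' @param seed optional RNG seed.
#' @return A list with components `stems` (a `data.frame` with `tag`,
#'   `species`, `x`, `y`, `dbh`, `growth_form`), `window`, and `truth` (the
#'   per-species generating parameters).
#' @export
simulateStand <- function(config = standConfig(), seed = NULL) {
  withSeed(seed, {
    window <- config$window
    pieces <- lapply(seq_len(nrow(config$species)), function(i) {
      p <- config$species[i, ]
      adults <- generateAdults(p$n_adults, window, p$gamma)
      foci <- generateAdults(p$n_adults, window, p$gamma)
      recruits <- generateOffspring(foci, p$sigma, p$mu)
      toSap <- runif(npoints(recruits)) < 0.5
      sap <- applyDDThinning(recruits[toSap], beta = 0, rho = p$rho,
                             pi0 = p$pi0Sap)
      juv <- applyDDThinning(recruits[!toSap], beta = p$beta, rho = p$rho,
                             pi0 = p$pi0Juv)
      stageOf <- c(rep("adult", npoints(adults)),
                   rep("sapling", npoints(sap)),
                   rep("juvenile", npoints(juv)))
      data.frame(
        species = p$species,
        x = c(adults@x, sap@x, juv@x),
        y = c(adults@y, sap@y, juv@y),
        dbh = round(c(drawDbh("adult", p$growth_form, npoints(adults)),
                      drawDbh("sapling", p$growth_form, npoints(sap)),
                      drawDbh("juvenile", p$growth_form, npoints(juv))), 1),
        growth_form = p$growth_form,
        stage_truth = stageOf)
    })
    stems <- do.call(rbind, pieces)
    stems <- cbind(tag = sprintf("T%05d", seq_len(nrow(stems))), stems)
    list(stems = stems, window = window, truth = config$species)
  })
}

#' Ground-truth survival coefficients for the seedling generator
#'
#' Coefficients of the full survival model (intercept a, height b,
#' conspecific/heterospecific seedling effects c1, c2, conspecific/
#' heterospecific basal-area effects d1, d2) on the z-scored covariate
#' scale, plus quadrat- and species-level random-intercept standard
#' deviations and the basal-area neighbourhood radius. The defaults give
#' roughly 30 % five-year mortality, a positive height effect and a weak
#' negative conspecific seedling-density effect, in line with magnitudes
#' typically reported for temperate seedling banks.
#'
#' @param a,b,c1,c2,d1,d2 fixed-effect coefficients (standardized scale).
#' @param sdQuadrat,sdSpecies random-intercept standard deviations.
#' @param radius basal-area neighbourhood radius (m).
#' @return A list of generator truth parameters.
#' @export
survivalTruth <- function(a = 0.9, b = 0.3, c1 = -0.1, c2 = 0, d1 = 0,
                          d2 = 0.1, sdQuadrat = 0.6, sdSpecies = 0.6,
                          radius = 10) {
  list(a = a, b = b, c1 = c1, c2 = c2, d1 = d1, d2 = d2,
       sdQuadrat = sdQuadrat, sdSpecies = sdSpecies, radius = radius)
}

#' Generate a seedling census with known survival truth
#'
#' Lays the standard seedling-plot lattice over the stand window (900
#' quadrats for a 300 m window), populates each 4-m^2 quadrat with a
#' Poisson number of seedlings whose species follow the local stem
#' composition (stems within 20 m; global composition as fallback), and
#' draws five-year survival from the full survival model: the linear
#' predictor applies the [survivalTruth()] coefficients to the z-scored
#' neighbourhood covariates -- computed by [computeNeighborCovariates()],
#' the same operation the analysis uses -- plus quadrat and species random
#' intercepts. Death times for non-survivors are spread over the
#' intermediate censuses so the table is monotone. A habitat table with
#' spatially structured canopy openness and topographic class is emitted
#' for all quadrats.
#'
#' @param stand a [simulateStand()] result.
#' @param truth a [survivalTruth()] list.
#' @param meanPerQuadrat mean seedlings per quadrat (default 6.4, i.e.
#'   about 5,760 seedlings on the 900-quadrat lattice).
#' @param seed optional RNG seed.
#' @return A list with components `seedlings` (census records including
#'   covariates, z-scored covariate columns used by the generator, and the
#'   `survival` outcome), `habitat`, and `truth` (the input truth plus the
#'   covariate scaling actually applied).
#' @export
generateSeedlingDataset <- function(stand, truth = survivalTruth(),
                                    meanPerQuadrat = 6.4, seed = NULL) {
  withSeed(seed, {
    window <- stand$window
    lattice <- quadratLattice(window)
    nq <- nrow(lattice)
    stems <- stand$stems
    speciesPool <- sort(unique(stems$species))
    globalTab <- table(stems$species)

    counts <- rpois(nq, meanPerQuadrat)
    qid <- rep(lattice$quadrat_id, counts)
    qx <- rep(lattice$x, counts)
    qy <- rep(lattice$y, counts)
    n <- sum(counts)
    sp <- character(n)
    for (q in which(counts > 0)) {
      near <- (stems$x - lattice$x[q])^2 + (stems$y - lattice$y[q])^2 <= 400
      tab <- if (any(near)) table(stems$species[near]) else globalTab
      sp[qid == lattice$quadrat_id[q]] <-
        sample(names(tab), counts[q], replace = TRUE, prob = as.numeric(tab))
    }
    seedlings <- data.frame(
      tag = sprintf("S%05d", seq_len(n)),
      quadrat_id = qid, species = sp,
      height_cm = round(30 + stats::rlnorm(n, log(20), 0.6), 1),
      x = qx, y = qy)

    seedlings <- computeNeighborCovariates(seedlings, stems,
                                           radius = truth$radius)
    zs <- standardizePredictors(seedlings)
    qEff <- rnorm(nq, 0, truth$sdQuadrat)
    spEff <- setNames(rnorm(length(speciesPool), 0, truth$sdSpecies),
                      speciesPool)
    eta <- truth$a + truth$b * zs$H + truth$c1 * zs$S_CON +
      truth$c2 * zs$S_HET + truth$d1 * zs$B_CON + truth$d2 * zs$B_HET +
      qEff[match(qid, lattice$quadrat_id)] + spEff[sp]
    surv <- rbinom(n, 1, plogis(eta))

    death <- sample(c("2007", "2008", "2010"), n, replace = TRUE)
    seedlings$alive_2005 <- 1L
    seedlings$alive_2007 <- as.integer(surv == 1L | death %in% c("2008", "2010"))
    seedlings$alive_2008 <- as.integer(surv == 1L | death == "2010")
    seedlings$alive_2010 <- surv
    seedlings$survival <- surv

    topoLevels <- c("ridge", "upper slope", "lower slope", "valley")
    band <- findInterval(lattice$y, quantile(lattice$y, c(0.25, 0.5, 0.75)))
    habitat <- data.frame(
      quadrat_id = lattice$quadrat_id,
      canopy_openness = pmin(pmax(
        12 + 6 * sin(lattice$x / 40) + rnorm(nq, 0, 3), 0), 100),
      topo_class = topoLevels[band + 1L])
    truth$scaling <- attr(zs, "scaling")
    list(seedlings = seedlings, habitat = habitat, truth = truth)
  })
}
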