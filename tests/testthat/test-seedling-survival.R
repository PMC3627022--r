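test_that("neighbourhood covariates follow the counting and area rules", {
  w <- Window(0, 100, 0, 100)
  lat <- quadratLattice(w)
  # focal seedling with 2 conspecific and 3 heterospecific quadrat mates
  sdl <- data.frame(
    tag = paste0("S", 1:7),
    quadrat_id = c(rep(1, 6), 2),
    species = c("A", "A", "A", "B", "B", "B", "A"),
    height_cm = 40,
    x = lat$x[c(rep(1, 6), 2)], y = lat$y[c(rep(1, 6), 2)])
  # one conspecific stem, dbh 10 cm, 5 m from quadrat 1's centre
  stems <- data.frame(species = c("A", "B"),
                      x = c(lat$x[1] + 5, lat$x[1] + 30),
                      y = c(lat$y[1], lat$y[1]), dbh = c(10, 50))
  cov <- computeNeighborCovariates(sdl, stems, radius = 10)
  f <- cov[cov$tag == "S1", ]
  expect_equal(f$S_CON, 2)
  expect_equal(f$S_HET, 3)
  expect_equal(f$S_TOTAL, 5)
  expect_equal(f$B_CON, pi * 0.05^2)  # ~7.854e-3 m^2
  expect_equal(f$B_HET, 0)            # the 50 cm stem is beyond 10 m
  expect_error(computeNeighborCovariates(
    transform(sdl, species = "ZZZ"), stems), "registry")
})

test_that("covariates match a brute-force oracle on a random configuration", {
  w <- Window(0, 60, 0, 60)
  lat <- quadratLattice(w)
  set.seed(12)
  n <- 40
  q <- sample(nrow(lat), n, replace = TRUE)
  sdl <- data.frame(tag = paste0("S", 1:n), quadrat_id = lat$quadrat_id[q],
                    species = sample(c("A", "B", "C"), n, TRUE),
                    height_cm = runif(n, 30, 100),
                    x = lat$x[q], y = lat$y[q])
  stems <- data.frame(species = sample(c("A", "B", "C"), 50, TRUE),
                      x = runif(50, 0, 60), y = runif(50, 0, 60),
                      dbh = runif(50, 1, 40))
  cov <- computeNeighborCovariates(sdl, stems, radius = 10)
  oracle <- neighborCovariatesOracle(sdl, stems, radius = 10)
  expect_equal(cov$S_CON, oracle$S_CON)
  expect_equal(cov$S_HET, oracle$S_HET)
  expect_equal(cov$B_CON, oracle$B_CON)
  expect_equal(cov$B_HET, oracle$B_HET)
  # additivity invariants
  expect_equal(cov$S_TOTAL, cov$S_CON + cov$S_HET)
  expect_equal(cov$B_TOTAL, cov$B_CON + cov$B_HET)
})

test_that("a boundary-variance mixed fit collapses to plain logistic regression", {
  set.seed(3)
  n <- 2000
  d <- data.frame(
    quadrat_id = sample(1:50, n, TRUE),
    species = sample(c("A", "B", "C"), n, TRUE),
    H = rnorm(n), S_CON = rnorm(n), S_HET = rnorm(n),
    B_CON = rnorm(n), B_HET = rnorm(n))
  d$S_TOTAL <- d$S_CON + d$S_HET
  d$B_TOTAL <- d$B_CON + d$B_HET
  d$survival <- rbinom(n, 1, plogis(0.4 + 0.3 * d$H - 0.2 * d$S_CON))
  f <- suppressMessages(
    fitSurvivalModel(d, 5, level = "community", standardize = FALSE))
  g <- glm(survival ~ H + S_CON + S_HET, binomial, d)
  expect_lt(max(abs(f@coefficients$estimate - coef(g))), 1e-4)
  expect_true(f@converged)
  # AIC identity (k counts fixed effects + variance components)
  expect_equal(f@aic, 2 * f@nPar - 2 * f@logLik)
  expect_equal(f@nPar, 4L + 2L)
})

test_that("nested models never lose log-likelihood and comparisons are ordered", {
  st <- simulateStand(seed = 111)
  ds <- generateSeedlingDataset(st, survivalTruth(), seed = 112)
  fits <- suppressMessages(lapply(c(1, 2, 5, 6, 9), function(id) {
    fitSurvivalModel(ds$seedlings, id, level = "community")
  }))
  names(fits) <- c("1", "2", "5", "6", "9")
  expect_gte(fits[["2"]]@logLik, fits[["1"]]@logLik - 1e-4)
  expect_gte(fits[["6"]]@logLik, fits[["5"]]@logLik - 1e-4)
  expect_gte(fits[["9"]]@logLik, fits[["5"]]@logLik - 1e-4)
})

test_that("nine-model comparison enforces the abundance rule and labels datasets", {
  st <- simulateStand(seed = 121)
  ds <- generateSeedlingDataset(st, survivalTruth(), seed = 122)
  expect_error(
    compareNineModels(ds$seedlings, level = "species", species = "none"),
    "need at least")
  sp <- names(sort(table(ds$seedlings$species), decreasing = TRUE))[1]
  cmp <- suppressMessages(
    compareNineModels(ds$seedlings, level = "species", species = sp))
  expect_equal(nrow(cmp@aicTable), 9)
  expect_equal(cmp@datasetLabel, paste0("species:", sp))
  okTab <- cmp@aicTable[cmp@aicTable$converged, ]
  expect_equal(cmp@bestFitId, okTab$model[which.min(okTab$aic)])
  expect_s4_class(bestFit(cmp), "ModelFit")
})

test_that("habitat controls enter as fixed or species-varying terms", {
  f <- survivalModelFormula(6, "species", habitatControls = TRUE)
  expect_match(deparse1(f), "canopy_openness")
  expect_match(deparse1(f), "topo_class")
  expect_false(grepl("\\| species", deparse1(f)))
  f2 <- survivalModelFormula(6, "community", habitatControls = TRUE)
  expect_match(deparse1(f2), "0 \\+ canopy_openness \\| species")
  expect_match(deparse1(f2), "species:topo_class")
  st <- simulateStand(seed = 131)
  ds <- generateSeedlingDataset(st, survivalTruth(), seed = 132)
  sdl <- merge(ds$seedlings, ds$habitat, by = "quadrat_id")
  fit <- suppressMessages(
    fitSurvivalModel(sdl, 1, level = "species", habitatControls = TRUE))
  expect_true(any(grepl("topo_class", fit@coefficients$term)))
})

test_that("a single candidate radius is returned as-is", {
  st <- simulateStand(seed = 141)
  ds <- generateSeedlingDataset(st, survivalTruth(), seed = 142)
  sel <- suppressMessages(selectNeighborhoodRadius(
    ds$seedlings, st$stems, radii = 10, level = "species"))
  expect_equal(sel$radius, 10)
  expect_equal(nrow(sel$aicTable), 1)
})
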