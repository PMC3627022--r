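test_that("thinning statistic is the elementwise stage difference", {
  expect_equal(thinningStatistic(-2, -1), 1)
  a <- c(-1.5, -0.2, 0.3, NA)
  expect_equal(thinningStatistic(a, a), c(0, 0, 0, NA))
  expect_equal(thinningStatistic(c(-2, NA), c(-1, 3)), c(1, NA))
  expect_error(thinningStatistic(1:3, 1:4), "mismatched")
})

test_that("d_max locator handles published rows, ties and missing cells", {
  tab <- exampleThinningTable()
  pinus <- as.numeric(tab[tab$species == "Pinus koraiensis", -1])
  expect_equal(findDmax(pinus, 0:10), list(dMax = 58.1, scale = 0))
  acer <- as.numeric(tab[tab$species == "Acer tegmentosum", -1])
  expect_equal(findDmax(acer, 0:10), list(dMax = 0.8, scale = 6))
  expect_equal(findDmax(c(1, 1, 1), 0:2), list(dMax = 1, scale = 0))
  expect_error(findDmax(c(NA, NA), 0:1), "missing")
})

test_that("random splits of one CSR pattern are classified random", {
  w <- Window(0, 150, 0, 150)
  cfg <- estimatorConfig(scales = 0:10)
  set.seed(33)
  cls <- unlist(lapply(1:8, function(s) {
    pp <- simulateCSR(300, w)
    pick <- sample(300, 120)
    aa <- additionalAggregation(pp[pick], pp[-pick], cfg, nSim = 199,
                                seed = 1000 + s)
    aa$classification
  }))
  expect_gt(mean(cls == "random"), 0.9)
})

test_that("clustered cases against CSR controls show additional aggregation", {
  w <- Window(0, 200, 0, 200)
  cfg <- estimatorConfig(scales = 0:10)
  set.seed(44)
  hits <- vapply(1:5, function(s) {
    cases <- generateOffspring(simulateCSR(30, w), sigma = 2, mu = 8)
    controls <- simulateCSR(250, w)
    aa <- additionalAggregation(cases, controls, cfg, nSim = 199,
                                seed = 2000 + s)
    # sign convention: a_i < 0 (below the envelope) = additional aggregation
    isTRUE(any(aa$classification[cfg@scales <= 5] == "aggregation") &&
           all(aa$a[cfg@scales <= 3] < 0) &&
           pValue(aa$gof) <= 0.01)
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("the species pipeline detects constructed thinning and skips sparse species", {
  st <- simulateStand(seed = 61)
  res <- runThinningPipeline(st$stems, "PINKOR", nSim = 199, seed = 62,
                             gofAlpha = 0.05)
  expect_s4_class(res, "ThinningResult")
  expect_equal(res@d, res@aJuv - res@aSap)
  expect_equal(res@dMax, max(res@d, na.rm = TRUE))
  expect_true(res@thinningDetected)

  expect_message(
    out <- runThinningPipeline(st$stems, "PINKOR", minPerStage = 10000),
    "below minimum")
  expect_null(out)
  expect_message(runThinningPipeline(st$stems, "nosuch"), "no stems")
})

test_that("a species without additional sapling aggregation is not called thinning", {
  # recruits without dispersal limitation: saplings are not additionally
  # aggregated relative to adults, so uniform between-stage mortality must
  # not register as density-dependent thinning
  w <- Window()
  set.seed(71)
  hits <- vapply(1:5, function(s) {
    stems <- rbind(
      data.frame(species = "X", coords(simulateCSR(300, w)), dbh = 1.2),
      data.frame(species = "X", coords(simulateCSR(180, w)), dbh = 9.0),
      data.frame(species = "X", coords(simulateCSR(120, w)), dbh = 20))
    stems$growth_form <- "CL"
    stems$tag <- seq_len(nrow(stems))
    r <- runThinningPipeline(stems, "X", nSim = 99, seed = 700 + s,
                             gofAlpha = 0.05)
    r@thinningDetected
  }, logical(1))
  expect_lte(sum(hits), 1)
})

test_that("classification counts conserve totals across species", {
  st <- simulateStand(seed = 81)
  res <- lapply(c("PINKOR", "ACEMON"), function(sp) {
    runThinningPipeline(st$stems, sp, nSim = 99, seed = 82, gofAlpha = 0.05)
  })
  tab <- countClassifications(res)
  expect_true(all(tab$aggregation + tab$random + tab$regular + tab$na ==
                  tab$n_species))
  expect_equal(unique(tab$n_species), 2)
  expect_setequal(unique(tab$stage), c("sapling", "juvenile"))
  summ <- thinningSummaryTable(res)
  expect_equal(nrow(summ), 2)
  expect_true(all(c("d_0", "d_10", "d_max", "d_max_scale") %in% names(summ)))
})

test_that("habitat heterogeneity screening flags gradients, not CSR", {
  w <- Window()
  cfg <- estimatorConfig(scales = 0:15)
  set.seed(91)
  flagged <- vapply(1:4, function(s) {
    adults <- generateAdults(250, w, gamma = 3)
    habitatHeterogeneityTest(adults, cfg, nSim = 99, seed = 900 + s,
                             gofRange = c(0, 15),
                             alpha = 0.05)@aggregatedBeyond10m
  }, logical(1))
  expect_true(all(flagged))
  unflagged <- vapply(1:4, function(s) {
    adults <- generateAdults(250, w, gamma = 0)
    habitatHeterogeneityTest(adults, cfg, nSim = 99, seed = 950 + s,
                             gofRange = c(0, 15),
                             alpha = 0.05)@aggregatedBeyond10m
  }, logical(1))
  expect_lte(sum(unflagged), 1)
})
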