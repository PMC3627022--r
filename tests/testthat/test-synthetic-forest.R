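test_that("generators are bit-reproducible under a fixed seed", {
  w <- Window()
  expect_identical(coords(generateAdults(200, w, gamma = 2, seed = 5)),
                   coords(generateAdults(200, w, gamma = 2, seed = 5)))
  ad <- generateAdults(50, w, gamma = 0, seed = 6)
  expect_identical(coords(generateOffspring(ad, 3, 4, seed = 7)),
                   coords(generateOffspring(ad, 3, 4, seed = 7)))
  expect_identical(simulateStand(seed = 8)$stems,
                   simulateStand(seed = 8)$stems)
  st <- simulateStand(seed = 8)
  expect_identical(
    generateSeedlingDataset(st, seed = 9)$seedlings$survival,
    generateSeedlingDataset(st, seed = 9)$seedlings$survival)
})

test_that("density-dependent thinning returns a subset and respects pi0", {
  w <- Window(0, 100, 0, 100)
  pp <- generateOffspring(simulateCSR(30, w, seed = 1), 2, 8, seed = 2)
  th <- applyDDThinning(pp, beta = 0.5, rho = 5, pi0 = 0.8, seed = 3)
  expect_lte(npoints(th), npoints(pp))
  expect_true(all(paste(th@x, th@y) %in% paste(pp@x, pp@y)))
  expect_equal(npoints(applyDDThinning(pp, 0.5, 5, pi0 = 0, seed = 4)), 0L)
})

test_that("uniform thinning keeps g, density-dependent thinning lowers it", {
  w <- Window()
  cfg <- estimatorConfig(scales = c(0, 2, 4))
  set.seed(55)
  rel <- replicate(30, {
    pp <- generateOffspring(simulateCSR(120, w), 2.5, 6)
    g0 <- funValues(estimatePcf(pp, config = cfg))
    gU <- funValues(estimatePcf(applyDDThinning(pp, 0, 5, 0.5),
                                config = cfg))
    gD <- funValues(estimatePcf(applyDDThinning(pp, 1, 5, 0.9),
                                config = cfg))
    c(gU / g0, gD / g0)
  })
  uniformRatio <- rowMeans(rel)[1:3]
  ddRatio <- rowMeans(rel)[4:6]
  expect_true(all(abs(uniformRatio - 1) < 0.1))
  expect_true(all(ddRatio < 0.8))
})

test_that("offspring totals and co-location limits behave", {
  w <- Window()
  ad <- simulateCSR(100, w, seed = 10)
  counts <- vapply(1:30, function(s) {
    npoints(generateOffspring(ad, 0.5, 5, seed = s))
  }, numeric(1))
  # E[total] = mu * n_adults, minus a tiny boundary loss
  expect_lt(abs(mean(counts) - 500), 4 * sqrt(500 / 30) + 5)
  tight <- generateOffspring(ad, 0.01, 5, seed = 11)
  g0 <- funValues(estimatePcf(tight, config = estimatorConfig(scales = 0)))
  expect_gt(g0, 50)  # near-coincident siblings blow up the first annulus
})

test_that("the seedling lattice emits exactly 900 quadrats on a 300 m window", {
  lat <- quadratLattice(Window())
  expect_equal(nrow(lat), 900)
  expect_equal(lat$quadrat_id, 1:900)
  st <- simulateStand(seed = 15)
  ds <- generateSeedlingDataset(st, seed = 16)
  expect_equal(sort(unique(ds$habitat$quadrat_id)), 1:900)
  expect_true(all(ds$seedlings$quadrat_id %in% 1:900))
  # census table is monotone: no seedling re-appears alive
  alive <- as.matrix(ds$seedlings[, c("alive_2005", "alive_2007",
                                      "alive_2008", "alive_2010")])
  expect_true(all(apply(alive, 1, function(a) all(diff(a) <= 0))))
})

test_that("habitat gradient strength controls the heterogeneity flag", {
  w <- Window()
  cfg <- estimatorConfig(scales = 0:15)
  # gamma = 0 reduces to CSR: x-coordinates uniform
  ad0 <- generateAdults(400, w, gamma = 0, seed = 21)
  expect_gt(suppressWarnings(
    ks.test(ad0@x, "punif", 0, 300)$p.value), 0.01)
  # strong gradient concentrates points at high x
  ad3 <- generateAdults(400, w, gamma = 3, seed = 22)
  expect_gt(mean(ad3@x), mean(ad0@x) + 30)
  ht <- habitatHeterogeneityTest(ad3, cfg, nSim = 99, seed = 23,
                                 gofRange = c(0, 15), alpha = 0.05)
  expect_true(ht@aggregatedBeyond10m)
  # the two-patch surface is also detected
  adP <- generateAdults(400, w, gamma = 2, surface = "patches", seed = 24)
  htP <- habitatHeterogeneityTest(adP, cfg, nSim = 99, seed = 25,
                                  gofRange = c(0, 15), alpha = 0.05)
  expect_true(htP@aggregatedBeyond10m)
})
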