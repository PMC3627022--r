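test_that("conditional CSR is uniform, sized, and reproducible", {
  w <- Window()
  expect_equal(npoints(simulateCSR(0, w)), 0L)
  a <- simulateCSR(100, w, seed = 4)
  b <- simulateCSR(100, w, seed = 4)
  expect_identical(coords(a), coords(b))
  # quadrat-count chi-square over a 10 x 10 partition
  pvals <- vapply(1:20, function(s) {
    p <- simulateCSR(10000, w, seed = s)
    counts <- table(factor(findInterval(p@x, seq(0, 300, 30),
                                        rightmost.closed = TRUE), 1:10),
                    factor(findInterval(p@y, seq(0, 300, 30),
                                        rightmost.closed = TRUE), 1:10))
    chisq.test(as.vector(counts), p = rep(1 / 100, 100))$p.value
  }, numeric(1))
  expect_gte(sum(pvals > 0.01), 18)
})

test_that("random labeling conserves locations and label counts", {
  w <- Window(0, 50, 0, 50)
  joint <- PointPattern(runif(5, 0, 50), runif(5, 0, 50), w,
                        marks = data.frame(label = c("case", "case", "case",
                                                     "control", "control")))
  out <- randomLabelPermutation(joint, seed = 2)
  expect_identical(coords(out), coords(joint))
  expect_equal(sum(markData(out)$label == "case"), 3)
  expect_equal(sum(markData(out)$label == "control"), 2)
  expect_identical(markData(randomLabelPermutation(joint, seed = 7))$label,
                   markData(randomLabelPermutation(joint, seed = 7))$label)
  tooFew <- PointPattern(1:3, 1:3, w,
                         marks = data.frame(label = c("case", "case",
                                                      "control")))
  expect_error(randomLabelPermutation(tooFew), "at least 2")
})

test_that("envelope bounds are the k-th extreme order statistics", {
  cfg <- estimatorConfig(scales = 0:3)
  obs <- new("SummaryFunction", scales = 0:3 + 0.0,
             values = rep(500, 4), statistic = "g", nI = 10L, nJ = 10L,
             config = cfg)
  H <- matrix(rep(1:999, 4), ncol = 4)  # null values 1..999 at every scale
  env <- buildEnvelope(obs, H, k = 5)
  expect_equal(unname(env@lower), rep(5, 4))
  expect_equal(unname(env@upper), rep(995, 4))
  expect_identical(envelopeClassification(env), rep("inside", 4))
  obs@values <- rep(996, 4)
  env <- buildEnvelope(obs, H, k = 5)
  expect_identical(envelopeClassification(env), rep("above", 4))
  expect_error(buildEnvelope(obs, H[1:5, ], k = 5), "at least 2k - 1")
})

test_that("GOF u statistic and rank P value behave at the extremes", {
  cfg <- estimatorConfig(scales = 0:5)
  set.seed(8)
  H <- matrix(rnorm(99 * 6), ncol = 6)
  # observed at the pointwise null mean: u = 0, P = 1 (ties toward larger P)
  obs <- new("SummaryFunction", scales = 0:5 + 0.0, values = colMeans(H),
             statistic = "L", nI = 5L, nJ = 5L, config = cfg)
  g <- gofTest(obs, H, scaleRange = c(0, 5))
  expect_lt(g@uObserved, 1e-20)
  expect_equal(pValue(g), 1)
  expect_error(gofTest(obs, H, scaleRange = c(100, 200)), "at least 2")

  # a strongly clustered observation against CSR nulls is separated: P at
  # the attainable minimum 1/(nSim + 1)
  w <- Window(0, 100, 0, 100)
  cl <- generateOffspring(simulateCSR(8, w, seed = 1), sigma = 1.5, mu = 30,
                          seed = 2)
  cfg2 <- estimatorConfig(scales = 0:10)
  obsG <- estimatePcf(cl, config = cfg2)
  Hnull <- t(vapply(1:99, function(s) {
    funValues(estimatePcf(simulateCSR(npoints(cl), w, seed = 100 + s),
                          config = cfg2))
  }, numeric(11)))
  g2 <- gofTest(obsG, Hnull, scaleRange = c(0, 10))
  expect_equal(pValue(g2), 1 / 100)
})

test_that("GOF P values are uniform under the null", {
  # exchangeability makes the rank-based P exactly discrete-uniform; check
  # with a Kolmogorov-Smirnov test on simulated Gaussian summary functions
  set.seed(21)
  ps <- replicate(300, {
    H <- matrix(rnorm(99 * 4), ncol = 4)
    obs <- new("SummaryFunction", scales = c(0, 1, 2, 3),
               values = rnorm(4), statistic = "L", nI = 5L, nJ = 5L,
               config = estimatorConfig(scales = 0:3))
    pValue(gofTest(obs, H, scaleRange = c(0, 3)))
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
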