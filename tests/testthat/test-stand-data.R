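test_that("stage classification honours the printed dbh cut-offs", {
  expect_identical(classifyStage(8.1, "CL"), "juvenile")
  expect_identical(classifyStage(2.1, "S"), "adult")
  expect_identical(classifyStage(5.0, "CS"), "sapling")
  expect_identical(classifyStage(15.0, "CL"), "juvenile")
  expect_identical(classifyStage(15.1, "CL"), "adult")
  # measurement-resolution gaps are closed half-open: 8.05 stays a sapling
  expect_identical(classifyStage(8.05, "CL"), "sapling")
  expect_error(classifyStage(0.9, "CL"), "dbh")
  expect_error(classifyStage(2, "XX"), "growth form")
})

test_that("stage intervals tile [1, Inf) with no gaps for every growth form", {
  grid <- seq(1, 30, by = 0.1)
  for (gf in stageRules()$growth_form) {
    st <- classifyStage(grid, gf)
    expect_true(all(st %in% c("sapling", "juvenile", "adult")))
    # stages appear in order and never revert
    codes <- match(st, c("sapling", "juvenile", "adult"))
    expect_true(all(diff(codes) >= 0))
    expect_setequal(unique(st), c("sapling", "juvenile", "adult"))
  }
})

test_that("stem table reading validates and round-trips byte-identically", {
  w <- Window()
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("tag,species,x,y,dbh",
               "T001,Pinus koraiensis,12.5,40,33.2",
               "T002,Acer mono,299.1,3.25,2.1"), path)
  stems <- readStemTable(path, w)
  expect_equal(nrow(stems), 2L)
  out <- withr::local_tempfile(fileext = ".csv")
  writeStemTable(stems, out)
  expect_identical(readLines(out), readLines(path))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("tag,species,x,y,dbh", "T001,A,301,5,4"), bad)
  expect_error(readStemTable(bad, w), "row 1.*'x'.*301")
  writeLines(c("tag,species,x,y,dbh", "T001,A,5,5,4", "T001,B,6,6,4"), bad)
  expect_error(readStemTable(bad, w), "duplicate tag")
  writeLines(c("tag,species,x,y,dbh", "T001,A,5,5,0.8"), bad)
  expect_error(readStemTable(bad, w), "dbh")
})

test_that("synthetic stands parse back with all invariants holding", {
  st <- simulateStand(seed = 101)
  path <- withr::local_tempfile(fileext = ".csv")
  writeStemTable(st$stems, path)
  back <- readStemTable(path, st$window)
  expect_equal(nrow(back), nrow(st$stems))
  expect_equal(back$x, st$stems$x)
  expect_equal(back$dbh, st$stems$dbh)
  expect_true(all(back$dbh >= 1))
  # dbh intervals reproduce the generating cohorts
  expect_identical(classifyStage(st$stems$dbh, st$stems$growth_form),
                   st$stems$stage_truth)
})

test_that("focal species selection applies the per-stage minimum", {
  set.seed(20)
  counts <- data.frame(
    species = c("alpha", "bravo", "charlie", "delta", "echo"),
    sapling = c(50, 39, 120, 45, 400),
    juvenile = c(45, 400, 80, 41, 39),
    adult = c(41, 400, 44, 50, 400))
  stems <- makeStems(counts)
  expect_identical(selectFocalSpecies(stems, minPerStage = 40),
                   c("alpha", "charlie", "delta"))
  expect_identical(selectFocalSpecies(stems, minPerStage = 500),
                   character(0))
})

test_that("seedling census reading derives survival and flags problems", {
  w <- Window()
  sdl <- withr::local_tempfile(fileext = ".csv")
  hab <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "tag,quadrat_id,species,height_cm,alive_2005,alive_2007,alive_2008,alive_2010",
    "S1,1,A,45,1,1,1,1",
    "S2,1,A,32,1,1,0,0",
    "S3,2,B,60,1,0,0,0"), sdl)
  writeLines(c("quadrat_id,canopy_openness,topo_class",
               "1,12.5,ridge"), hab)
  cen <- readSeedlingCensus(sdl, hab, w)
  expect_equal(cen$seedlings$survival, c(1L, 0L, 0L))
  expect_equal(cen$seedlings$habitat_missing, c(FALSE, FALSE, TRUE))

  # a dead seedling may not re-appear alive
  writeLines(c(
    "tag,quadrat_id,species,height_cm,alive_2005,alive_2007,alive_2008,alive_2010",
    "S1,1,A,45,1,0,0,1"), sdl)
  expect_error(readSeedlingCensus(sdl, hab, w), "alive after death.*S1")

  # quadrat ids must belong to the lattice
  writeLines(c(
    "tag,quadrat_id,species,height_cm,alive_2005,alive_2007,alive_2008,alive_2010",
    "S1,2000,A,45,1,1,1,1"), sdl)
  expect_error(readSeedlingCensus(sdl, hab, w), "unknown quadrat_id")

  # graduation to >= 1 cm dbh counts as survival and is flagged
  writeLines(c(
    "tag,quadrat_id,species,height_cm,alive_2005,alive_2007,alive_2008,alive_2010,graduated_2010",
    "S1,1,A,95,1,1,1,0,1"), sdl)
  cen <- readSeedlingCensus(sdl, hab, w)
  expect_equal(cen$seedlings$survival, 1L)
  expect_true(cen$seedlings$graduated)

  writeLines(c("quadrat_id,canopy_openness,topo_class", "1,130,ridge"), hab)
  expect_error(readSeedlingCensus(sdl, hab, w), "canopy_openness")
})

test_that("generated seedling mortality matches generator truth", {
  st <- simulateStand(seed = 31)
  truth <- survivalTruth(a = 0, b = 0, c1 = 0, c2 = 0, d1 = 0, d2 = 0,
                         sdQuadrat = 0, sdSpecies = 0)
  ds <- generateSeedlingDataset(st, truth, seed = 32)
  n <- nrow(ds$seedlings)
  m <- mean(ds$seedlings$survival)
  expect_lt(abs(m - 0.5), 4 * sqrt(0.25 / n))
})
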