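test_that("carrying capacity arithmetic rounds half up", {
  expect_identical(computeK(0.77, 21254), 164L)
  expect_identical(computeK(1, 100), 1L)
  expect_identical(computeK(0.5, 100), 1L)   # exact half rounds up
  expect_error(computeK(0, 100))
})

test_that("founder lethal loads follow the infinite-loci Poisson model", {
  expect_true(all(lengths(assignFounderLethals(50, 0, 0.5, seed = 1)) == 0))
  expect_true(all(lengths(assignFounderLethals(50, 6.26, 0, seed = 2)) == 0))
  leth <- assignFounderLethals(1000, 6.26, 0.5, seed = 3)
  m <- mean(lengths(leth))
  se <- sqrt(3.13 / 1000)
  expect_lt(abs(m - 3.13), 3 * se)
  # ids are globally unique across founders
  all <- unlist(leth)
  expect_identical(anyDuplicated(all), 0L)
})

test_that("kinship bookkeeping matches the brute-force pedigree oracle", {
  for (seed in 1:4) {
    ped <- randomPedigree(6, 5, 6, selfing = (seed %% 2 == 0), seed = seed)
    K <- pedigreeKinship(ped)$kinship
    expect_equal(K, kinshipOracle(ped), tolerance = 1e-15)
  }
  # textbook spot values via the incremental update
  K0 <- matrix(0, 2, 2); diag(K0) <- 0.5
  po <- kinshipAddOffspring(K0, 1, 2)       # outbred unrelated parents
  expect_equal(po$F, 0)
  expect_equal(po$K[3, 3], 0.5)
  sib2 <- kinshipAddOffspring(po$K, 1, 2)
  fsMating <- kinshipAddOffspring(sib2$K, 3, 4)  # full-sib mating
  expect_equal(fsMating$F, 0.25)
  # founder kinship k0 feeds straight into first-generation inbreeding
  kf <- matrix(0.0868, 2, 2); diag(kf) <- 0.5 * (1 + 0.0868)
  expect_equal(kinshipAddOffspring(kf, 1, 2)$F, 0.0868)
})

test_that("degenerate vital rates behave as constructed", {
  # no mortality, guaranteed breeding, no ceiling: never shrinks
  up <- pvaConfig(initialSize = 10, pctFemalesBreeding = 1,
                  mortality = c(firstYear = 0, subadult = 0, adult = 0),
                  K = Inf, LE = 0, F0 = 0, k0 = 0, horizon = 10,
                  iterations = 3, maxLifespan = 100, maxBreedAge = 99)
  r <- runPVA(up, seed = 4)
  expect_true(all(diff(c(10, r@years$meanN)) >= 0))

  # total first-year mortality: extinction within one lifespan
  dead <- pvaConfig(initialSize = 20,
                    mortality = c(firstYear = 1, subadult = 0.1,
                                  adult = 0.1),
                    horizon = 30, iterations = 5, maxLifespan = 17)
  rd <- runPVA(dead, seed = 5)
  expect_equal(rd@pExtinct, 1)
  expect_lte(max(rd@years$year[rd@years$survival > 0]), 17)
})

test_that("a fixed seed reproduces the simulation bit-identically", {
  cfg <- pvaConfig(horizon = 15, iterations = 10)
  r1 <- runPVA(cfg, seed = 6)
  r2 <- runPVA(cfg, seed = 6)
  expect_identical(r1@years, r2@years)
  expect_identical(r1@finalSizes, r2@finalSizes)
})

test_that("with zero lethal equivalents the genetic load machinery is inert", {
  c1 <- pvaConfig(LE = 0, pLethal = 0.5, horizon = 25, iterations = 15)
  c2 <- pvaConfig(LE = 0, pLethal = 0.9, horizon = 25, iterations = 15)
  r1 <- runPVA(c1, seed = 7)
  r2 <- runPVA(c2, seed = 7)
  expect_identical(r1@years, r2@years)
})

test_that("early growth matches the Leslie-matrix oracle within 2 percent", {
  cfg <- pvaConfig(LE = 0, F0 = 0, k0 = 0, K = Inf, horizon = 20,
                   iterations = 400)
  r <- runPVA(cfg, seed = 8)
  growth <- (r@years$meanN[20] / r@years$meanN[1])^(1 / 19)
  # female-only projection with end-of-year census (ages 1..16):
  # newborn females = breeding prob x mean litter x P(female) x cub survival
  meanLitter <- sum(seq_along(cfg@litterSizeProbs) * cfg@litterSizeProbs)
  b <- cfg@pctFemalesBreeding * meanLitter * (1 - cfg@sexRatioMale) *
    (1 - cfg@mortality["firstYear"])
  M <- matrix(0, 16, 16)
  for (a in 3:15) M[1, a] <- b
  M[2, 1] <- 1 - cfg@mortality["subadult"]
  M[3, 2] <- 1 - cfg@mortality["subadult"]
  for (a in 3:15) M[a + 1, a] <- 1 - cfg@mortality["adult"]
  lambda <- max(Re(eigen(M)$values))
  expect_lt(abs(growth - lambda) / lambda, 0.02)
})

test_that("survival responds monotonically to load and breeding females", {
  base <- pvaConfig(horizon = 60, iterations = 80)
  s <- vapply(c(0, 6.26, 12.26), function(le) {
    cfg <- base; cfg@LE <- le
    runPVA(cfg, seed = 9)@years$survival[60]
  }, numeric(1))
  expect_true(all(diff(s) <= 0.05))   # non-increasing up to MC noise
  expect_gt(s[1] - s[3], 0.2)         # and strictly overall

  sf <- vapply(c(0.25, 0.75), function(fb) {
    cfg <- base; cfg@pctFemalesBreeding <- fb
    runPVA(cfg, seed = 10)@years$survival[60]
  }, numeric(1))
  expect_gte(sf[2], sf[1])
})

test_that("survival trajectories and the result object are coherent", {
  cfg <- pvaConfig(horizon = 40, iterations = 40, LE = 12.26)
  r <- runPVA(cfg, seed = 11)
  expect_true(all(diff(r@years$survival) <= 1e-12))
  expect_true(all(r@years$meanN >= 0))
  expect_equal(r@pExtinct, 1 - r@years$survival[40])
  expect_true(all(r@years$lo95 <= r@years$hi95))
  # sweep output is long-format over the three factors
  sw <- scenarioSweep(pvaConfig(horizon = 5, iterations = 3),
                      LEvalues = c(0, 6.26), femaleRatios = 0.5,
                      pLethalValues = 0.5, seed = 12)
  expect_setequal(unique(sw$factor), c("LE", "femaleRatio", "pLethal"))
  expect_equal(nrow(sw), 4 * 5)
})

test_that("invalid configurations are rejected by the validity method", {
  expect_error(pvaConfig(pctFemalesBreeding = 1.2), "probabilities")
  expect_error(pvaConfig(LE = -1), "LE")
  expect_error(pvaConfig(horizon = 0), "horizon")
})
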