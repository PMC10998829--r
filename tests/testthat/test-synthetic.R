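test_that("generated allele frequencies are valid and seed-stable", {
  fr <- genAlleleFreqs(14, 4, seed = 1)
  expect_length(fr, 14)
  for (fl in fr) {
    expect_equal(sum(fl$freq), 1, tolerance = 1e-12)
    sizes <- as.integer(names(fl$freq))
    expect_true(all(sizes >= 100))
    expect_true(all(diff(sizes) == 4))
  }
  expect_identical(genAlleleFreqs(14, 4, seed = 1), fr)
  # high concentration approaches uniformity
  fu <- genAlleleFreqs(5, 4, concentration = 5000, seed = 2)
  for (fl in fu) expect_lt(max(abs(fl$freq - 0.25)), 0.05)
})

test_that("gene drop respects Mendelian transmission and pedigree truth", {
  fr <- genAlleleFreqs(30, 4, seed = 3)
  ped <- pedigree(c("d", "s", "o1", "o2"),
                  c(NA, NA, "d", "d"), c(NA, NA, "s", "s"))
  gd <- geneDrop(ped, fr, seed = 4)
  # every offspring allele pair shares at least one allele with each parent
  for (kid in c("o1", "o2")) for (l in seq_along(fr)) {
    kidAl <- c(gd$gt@alleleA[kid, l], gd$gt@alleleB[kid, l])
    damAl <- c(gd$gt@alleleA["d", l], gd$gt@alleleB["d", l])
    sireAl <- c(gd$gt@alleleA["s", l], gd$gt@alleleB["s", l])
    expect_true(any(kidAl %in% damAl))
    expect_true(any(kidAl %in% sireAl))
  }
  # full sibs have true r = 0.5 from the recursion
  expect_equal(2 * gd$kinship["o1", "o2"], 0.5)
  expect_equal(unname(gd$F), rep(0, 4))
})

test_that("genotype-based estimates converge to pedigree truth with loci", {
  ped <- pedigree(c("d", "s", "o1", "o2"),
                  c(NA, NA, "d", "d"), c(NA, NA, "s", "s"))
  err <- vapply(c(20, 200), function(L) {
    fr <- genAlleleFreqs(L, 5, concentration = 3, seed = L)
    rs <- vapply(1:40, function(s) {
      gd <- geneDrop(ped, fr, seed = 1000 * L + s)
      msatpva:::qgPair(gd$gt@alleleA["o1", ], gd$gt@alleleB["o1", ],
                       gd$gt@alleleA["o2", ], gd$gt@alleleB["o2", ], fr)
    }, numeric(1))
    sd(rs)
  }, numeric(1))
  expect_lt(err[2], err[1])          # spread shrinks with panel size
  fr <- genAlleleFreqs(200, 5, concentration = 3, seed = 200)
  gd <- geneDrop(ped, fr, seed = 99)
  est <- msatpva:::qgPair(gd$gt@alleleA["o1", ], gd$gt@alleleB["o1", ],
                          gd$gt@alleleA["o2", ], gd$gt@alleleB["o2", ], fr)
  expect_lt(abs(est - 0.5), 0.15)
})

test_that("deme divergence controls the Wahlund signal", {
  fr <- genAlleleFreqs(14, 4, seed = 5)
  tiny <- genTwoDemes(0.005, 40, fr, seed = 6)
  expect_lt(abs(fisWC(tiny)$multilocus), 0.06)
  strong <- genTwoDemes(0.25, 40, fr, seed = 7)
  expect_gt(fisWC(strong)$multilocus, fisWC(tiny)$multilocus)
  expect_identical(popLabels(strong), rep(c("deme1", "deme2"), each = 40))
})

test_that("Wright-Fisher drift erodes heterozygosity at the expected rate", {
  # large N: no visible drift
  frBig <- genAlleleFreqs(10, 4, concentration = 5, seed = 8)
  he0 <- mean(vapply(frBig, function(fl) 1 - sum(fl$freq^2), numeric(1)))
  big <- genWrightFisher(5000, 3, 100, frBig, seed = 9)
  heBig <- mean(diversitySummary(big)$perLocus$He)
  expect_lt(abs(heBig - he0) / he0, 0.06)

  # small N: mean He ratio tracks (1 - 1/(2N))^t
  N <- 20; t <- 5
  ratios <- vapply(1:150, function(s) {
    fr <- genAlleleFreqs(5, 4, concentration = 5, seed = 1000 + s)
    he0 <- mean(vapply(fr, function(fl) 1 - sum(fl$freq^2), numeric(1)))
    wf <- genWrightFisher(N, t, N, fr, seed = 2000 + s)
    # population-level expected heterozygosity (biased form, matches theory)
    fr2 <- alleleFreqs(wf)
    he1 <- mean(vapply(fr2, function(fl) 1 - sum(fl$freq^2), numeric(1)))
    he1 / he0
  }, numeric(1))
  expect_equal(mean(ratios), (1 - 1 / (2 * N))^t, tolerance = 0.04)
})

test_that("replicate noise reduces to the identity when switched off", {
  fr <- genAlleleFreqs(6, 4, seed = 10)
  gt <- sampleHWGenotypes(fr, 6, seed = 11)
  rc <- addReplicateNoise(gt, seed = 12)
  cons <- callConsensus(rc)
  expect_identical(cons@alleleA[indNames(gt), lociNames(gt)], gt@alleleA)
  expect_identical(cons@alleleB[indNames(gt), lociNames(gt)], gt@alleleB)
})

test_that("heterozygote recovery under dropout matches the binomial bound", {
  # P(a clean het call) = (1 - dropout); with 4 replicates the >=2 rule
  # succeeds with P(X >= 2), X ~ Binomial(4, 0.8) = 0.9728
  fr <- genAlleleFreqs(10, 4, seed = 13)
  gt <- sampleHWGenotypes(fr, 40, seed = 14)
  rc <- addReplicateNoise(gt, dropout = 0.2, seed = 15)
  cons <- callConsensus(rc)
  het <- gt@alleleA != gt@alleleB
  called <- !isMissing(cons)[indNames(gt), lociNames(gt)]
  ok <- (cons@alleleA[indNames(gt), lociNames(gt)] == gt@alleleA) &
    (cons@alleleB[indNames(gt), lociNames(gt)] == gt@alleleB)
  recovery <- mean(ok[het & called], na.rm = TRUE)
  expect_gt(recovery, 0.95)
  # unconditional recovery: P(>=2 clean calls) minus the ambiguity case
  # (exactly 2 clean, the other 2 dropped to the same allele):
  # 0.9728 - choose(4,2) * 0.8^2 * 0.2^2 * 0.5 = 0.896
  expected <- stats::pbinom(1, 4, 0.8, lower.tail = FALSE) -
    choose(4, 2) * 0.8^2 * 0.2^2 * 0.5
  expect_equal(mean(called[het] & ok[het], na.rm = TRUE), expected,
               tolerance = 0.03)
})

test_that("generators are deterministic given a seed", {
  expect_identical(genTwoDemes(0.2, 5, genAlleleFreqs(4, 3, seed = 16),
                               seed = 17)@alleleA,
                   genTwoDemes(0.2, 5, genAlleleFreqs(4, 3, seed = 16),
                               seed = 17)@alleleA)
  expect_identical(genWrightFisher(10, 3, 5, genAlleleFreqs(4, 3, seed = 18),
                                   seed = 19)@alleleA,
                   genWrightFisher(10, 3, 5, genAlleleFreqs(4, 3, seed = 18),
                                   seed = 19)@alleleA)
})

test_that("pedigree construction enforces ordering and pairing rules", {
  expect_error(pedigree(c("a", "b"), c("b", NA), c(NA, NA)), "two known")
  expect_error(pedigree(c("a", "b"), c(NA, "c"), c(NA, "c")), "before")
  expect_error(pedigree(c("a", "a"), c(NA, NA), c(NA, NA)), "duplicate")
  ped <- randomPedigree(5, 2, 4, seed = 20)
  expect_s3_class(ped, "pedigree_df")
  expect_equal(sum(is.na(ped$dam)), 5)
})
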