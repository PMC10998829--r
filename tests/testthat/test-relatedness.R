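test_that("identity-state genotype-pair probabilities are distributions", {
  set.seed(1)
  for (rep in 1:3) {
    k <- sample(3:5, 1)
    p <- stats::rgamma(k, 1); p <- p / sum(p)
    names(p) <- as.character(100 + 4 * seq_len(k))
    sizes <- as.integer(names(p))
    pf <- function(al) unname(p[as.character(al)])
    tot <- numeric(9)
    for (x1 in sizes) for (x2 in sizes) for (y1 in sizes) for (y2 in sizes) {
      if (x1 > x2 || y1 > y2) next
      tot <- tot + msatpva:::jacquardCellProbs(c(x1, x2), c(y1, y2), pf)
    }
    expect_equal(unname(tot), rep(1, 9), tolerance = 1e-12)
  }
})

test_that("the nine-state likelihood pinned to outbred states matches the
          three-state likelihood", {
  fr <- genAlleleFreqs(10, 4, seed = 2)
  gt <- sampleHWGenotypes(fr, 2, seed = 3)
  M <- msatpva:::jacquardProbMatrix(gt@alleleA[1, ], gt@alleleB[1, ],
                                    gt@alleleA[2, ], gt@alleleB[2, ], fr)
  d9 <- c(rep(0, 6), 0.2, 0.5, 0.3)
  ll9 <- sum(log(colSums(M * d9)))
  ll3 <- sum(log(colSums(M[7:9, ] * c(0.2, 0.5, 0.3))))
  expect_equal(ll9, ll3, tolerance = 1e-12)
})

test_that("duplicated genotypes are called full identity by the ML methods", {
  fr <- genAlleleFreqs(14, 5, seed = 4)
  gt <- sampleHWGenotypes(fr, 2, seed = 5)
  a <- rbind(gt@alleleA[1, ], gt@alleleA[1, ])
  b <- rbind(gt@alleleB[1, ], gt@alleleB[1, ])
  rownames(a) <- rownames(b) <- c("x", "y")
  dup <- genotypeTable(a, b)
  for (m in c("dyad_ml", "trio_ml")) {
    rr <- estimateRelatedness(dup, m, freqs = fr, seed = 6)
    expect_equal(unname(rr@r["x", "y"]), 1, tolerance = 0.01)
  }
})

test_that("moment estimators are near-unbiased on simulated dyads", {
  fr <- genAlleleFreqs(14, 5, concentration = 2, seed = 7)
  dy <- simulateDyads(fr, nPerClass = 2000, seed = 8)
  sel <- selectEstimator(dy, fr,
                         methods = c("queller_goodnight", "lynch_ritland",
                                     "similarity"))
  rep <- sel$report
  expect_equal(nrow(rep), 3 * 4)            # estimators x classes
  for (m in unique(rep$estimator)) {
    sub <- rep[rep$estimator == m, ]
    expect_true(all(abs(sub$mean - sub$trueR) < 0.03),
                info = paste("estimator", m))
  }
  # selection is the pooled-MSE argmin and is self-consistent
  pooledBest <- sel$pooled$estimator[which.min(sel$pooled$mse)]
  expect_identical(sel$selected, pooledBest)
})

test_that("estimator selection is stable across simulation seeds", {
  fr <- genAlleleFreqs(14, 5, concentration = 2, seed = 9)
  winners <- vapply(1:3, function(s) {
    dy <- simulateDyads(fr, nPerClass = 800, seed = 100 + s)
    selectEstimator(dy, fr, methods = c("queller_goodnight",
                                        "lynch_ritland",
                                        "similarity"))$selected
  }, character(1))
  expect_equal(length(unique(winners)), 1)
})

test_that("simulated dyads realise the relationship k-coefficients", {
  fr <- genAlleleFreqs(14, 4, seed = 10)
  dy <- simulateDyads(fr, nPerClass = 1500, seed = 11)
  fs <- dy$class == "full_sib"
  expect_equal(mean(dy$ibdCount[fs, ]), 1, tolerance = 0.05)
  un <- dy$class == "unrelated"
  expect_equal(mean(dy$ibdCount[un, ]), 0)
  # unrelated dyads: mean Queller-Goodnight relatedness near zero
  est <- vapply(which(un), function(i)
    msatpva:::qgPair(dy$ax[i, ], dy$bx[i, ], dy$ay[i, ], dy$by[i, ], fr),
    numeric(1))
  expect_lt(abs(mean(est, na.rm = TRUE)), 0.02)
  # reproducibility
  dy2 <- simulateDyads(fr, nPerClass = 1500, seed = 11)
  expect_identical(dy$ax, dy2$ax)
  expect_identical(dy$ibdCount, dy2$ibdCount)
  expect_error(simulateDyads(fr, classes = "sibling-ish"), "unknown")
})

test_that("parent-offspring dyads recover r near one half by likelihood", {
  fr <- genAlleleFreqs(14, 5, concentration = 2, seed = 12)
  ped <- pedigree(c("p1", "p2", "o1"), c(NA, NA, "p1"), c(NA, NA, "p2"))
  set.seed(13)
  rs <- replicate(250, {
    gd <- geneDrop(ped, fr)
    msatpva:::mlPair(gd$gt@alleleA[1, ], gd$gt@alleleB[1, ],
                     gd$gt@alleleA[3, ], gd$gt@alleleB[3, ], fr,
                     nStarts = 3, inbreeding = FALSE)$r
  })
  expect_lt(abs(mean(rs) - 0.5), 0.05)
})

test_that("selfed offspring carry f near one half, outbred near zero", {
  fr <- genAlleleFreqs(14, 5, concentration = 2, seed = 14)
  ped <- pedigree(c("p", "o"), c(NA, "p"), c(NA, "p"))
  set.seed(15)
  fs <- replicate(200, {
    gd <- geneDrop(ped, fr)
    estimateInbreeding(gd$gt[2, ], freqs = fr)$f
  })
  expect_lt(abs(mean(fs) - 0.5), 0.05)

  # null recovery: the boundary-constrained MLE folds noise upward, so the
  # null mean shrinks toward zero as the panel grows
  fr30 <- genAlleleFreqs(30, 5, concentration = 2, seed = 140)
  out30 <- sampleHWGenotypes(fr30, 100, seed = 16)
  fo30 <- estimateInbreeding(out30, freqs = fr30)
  expect_lt(mean(fo30$f), 0.05)
  expect_true(all(fo30$f >= 0 & fo30$f <= 1))
  # at a 14-locus panel the fold-bias is larger but bounded
  out14 <- sampleHWGenotypes(fr, 100, seed = 160)
  expect_lt(mean(estimateInbreeding(out14, freqs = fr)$f), 0.09)
})

test_that("inbreeding classes follow the conventional thresholds", {
  fr <- genAlleleFreqs(6, 3, seed = 17)
  gt <- sampleHWGenotypes(fr, 5, seed = 18)
  inb <- estimateInbreeding(gt, freqs = fr)
  expect_identical(inb$class,
                   ifelse(inb$f >= 0.25, "high",
                          ifelse(inb$f >= 0.125, "moderate", "low")))
  expect_equal(attr(inb, "meanF"), mean(inb$f))
})

test_that("a relatedness result is symmetric with bounded ML estimates", {
  fr <- genAlleleFreqs(10, 4, seed = 19)
  gt <- sampleHWGenotypes(fr, 6, seed = 20)
  rr <- estimateRelatedness(gt, "trio_ml", freqs = fr, seed = 21)
  expect_identical(rr@r, t(rr@r))
  off <- rr@r[upper.tri(rr@r)]
  expect_true(all(off >= 0 & off <= 1 + 1e-9))
  expect_true(all(rr@f >= 0 & rr@f <= 1))
})
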