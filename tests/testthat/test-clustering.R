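test_that("K = 1 degenerates to pooled-frequency likelihood", {
  fr <- genAlleleFreqs(10, 4, seed = 1)
  gt <- sampleHWGenotypes(fr, 20, seed = 2)
  m <- fitAdmixture(gt, 1, burnin = 500, reps = 1500, seed = 3)
  expect_true(all(m@Q == 1))
  # analytic likelihood under fixed pooled frequencies
  fro <- alleleFreqs(gt)
  ll <- 0
  for (l in seq_len(nLoc(gt))) {
    p <- fro[[l]]$freq
    genes <- c(gt@alleleA[, l], gt@alleleB[, l])
    ll <- ll + sum(log(p[as.character(genes)]))
  }
  # posterior-mean frequencies are prior-smoothed; allow a few percent
  expect_lt(abs(m@logLik - ll) / abs(ll), 0.05)
})

test_that("the sampler is deterministic under a fixed seed", {
  fr <- genAlleleFreqs(8, 4, seed = 4)
  gt <- genTwoDemes(0.2, 10, fr, seed = 5)
  m1 <- fitAdmixture(gt, 2, burnin = 300, reps = 600, seed = 42)
  m2 <- fitAdmixture(gt, 2, burnin = 300, reps = 600, seed = 42)
  expect_identical(m1@Q, m2@Q)
  expect_identical(m1@logLik, m2@logLik)
  expect_error(fitAdmixture(gt, 50), "exceeds")
})

test_that("two diverged demes are recovered at K = 2", {
  fr <- genAlleleFreqs(14, 4, seed = 6)
  gt <- genTwoDemes(0.35, 15, fr, seed = 7)
  m <- fitAdmixture(gt, 2, burnin = 1000, reps = 3000, seed = 8)
  expect_true(all(abs(rowSums(m@Q) - 1) < 1e-9))
  expect_gt(mean(apply(m@Q, 1, max)), 0.9)
  # majority cluster within each deme must differ; recovery > 90%
  best <- apply(m@Q, 1, which.max)
  deme <- popLabels(gt)
  maj1 <- as.integer(names(which.max(table(best[deme == "deme1"]))))
  maj2 <- as.integer(names(which.max(table(best[deme == "deme2"]))))
  expect_false(maj1 == maj2)
  recovery <- mean(c(best[deme == "deme1"] == maj1,
                     best[deme == "deme2"] == maj2))
  expect_gt(recovery, 0.9)
})

test_that("threshold assignment labels confident and admixed individuals", {
  Q <- rbind(c(0.95, 0.05), c(0.6, 0.4), c(0.05, 0.95), c(0.9, 0.1))
  rownames(Q) <- paste0("i", 1:4)
  lab <- assignClusters(Q, 0.9)
  expect_identical(unname(lab), c("1", "admixed", "2", "1"))
  expect_error(assignClusters(Q, 0.4))
})

test_that("replicate alignment repairs label switching", {
  fr <- genAlleleFreqs(10, 4, seed = 9)
  gt <- genTwoDemes(0.25, 10, fr, seed = 10)
  m <- fitAdmixture(gt, 2, burnin = 300, reps = 800, seed = 11)
  # manufacture a label-swapped replicate
  msw <- m
  msw@Q <- m@Q[, c(2, 1)]
  colnames(msw@Q) <- colnames(m@Q)
  msw@P <- lapply(m@P, function(pl) {
    pl2 <- pl[c(2, 1), , drop = FALSE]; rownames(pl2) <- rownames(pl); pl2
  })
  al <- alignReplicates(list(m, msw))
  expect_equal(al$models[[2]]@Q, m@Q)
  expect_true(all(abs(rowSums(al$meanQ) - 1) < 1e-9))

  # alignment is invariant to run order up to a global permutation
  m2 <- fitAdmixture(gt, 2, burnin = 300, reps = 800, seed = 12)
  a12 <- alignReplicates(list(m, m2))$meanQ
  a21 <- alignReplicates(list(m2, m))$meanQ
  direct <- max(abs(a12 - a21))
  flipped <- max(abs(a12 - a21[, c(2, 1)]))
  expect_lt(min(direct, flipped), 1e-9)
})

test_that("delta-K arithmetic follows the second-order definition", {
  mkModel <- function(K, ll) {
    Q <- matrix(1 / K, 2, K,
                dimnames = list(c("i1", "i2"), paste0("cluster", 1:K)))
    new("ClusterModel", K = as.integer(K), Q = Q, P = list(),
        logLik = ll, logLikVar = 1, settings = list())
  }
  lls <- list(`1` = c(-110, -112), `2` = c(-90, -91),
              `3` = c(-88, -89.5), `4` = c(-87.5, -89))
  runs <- unlist(lapply(names(lls), function(k)
    lapply(lls[[k]], function(v) mkModel(as.integer(k), v))),
    recursive = FALSE)
  ev <- evannoDeltaK(runs)
  meanL <- vapply(lls, mean, numeric(1))
  sdL <- vapply(lls, stats::sd, numeric(1))
  expD2 <- abs(meanL[3] - 2 * meanL[2] + meanL[1])
  expect_equal(ev$table$deltaK[2], unname(expD2 / sdL[2]))
  expect_equal(ev$bestK, 2)
  expect_true(is.na(ev$table$deltaK[1]) && is.na(ev$table$deltaK[4]))

  # zero between-replicate SD at every interior K is surfaced as an error
  runsFlat <- unlist(lapply(1:3, function(k)
    list(mkModel(k, -100 - k), mkModel(k, -100 - k))), recursive = FALSE)
  expect_error(evannoDeltaK(runsFlat), "undefined")
  expect_error(evannoDeltaK(runs[1:2]), "3 consecutive")
})

test_that("delta K peaks at the simulated deme count", {
  fr <- genAlleleFreqs(14, 4, seed = 13)
  # three demes: two pairwise-diverged populations built from two draws
  g1 <- genTwoDemes(0.3, 10, fr, seed = 14)
  g2 <- genTwoDemes(0.3, 10, fr, seed = 15)
  a <- rbind(g1@alleleA, g2@alleleA[g2@pop == "deme2", , drop = FALSE])
  b <- rbind(g1@alleleB, g2@alleleB[g2@pop == "deme2", , drop = FALSE])
  rownames(a) <- rownames(b) <- sprintf("i%02d", seq_len(nrow(a)))
  gt <- genotypeTable(a, b, pop = c(g1@pop, rep("deme3", 10)))
  runs <- list()
  for (K in 1:5) for (rep in 1:2)
    runs[[length(runs) + 1]] <-
      fitAdmixture(gt, K, burnin = 500, reps = 1500,
                   seed = 100 * K + rep)
  ev <- evannoDeltaK(runs)
  expect_equal(ev$bestK, 3)
})
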