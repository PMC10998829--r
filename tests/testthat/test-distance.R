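test_that("Dsw is zero on identical genotypes and exact on the 4-bp case", {
  gt <- gtFromStrings(list(i1 = c("100/104", "120/120"),
                           i2 = c("100/104", "120/120")))
  D <- dswMatrix(gt)
  expect_equal(unname(D["i1", "i2"]), 0)

  gt2 <- gtFromStrings(list(A = "100/100", B = "104/104"))
  expect_equal(unname(dswMatrix(gt2)["A", "B"]), 4)
})

test_that("Dsw is symmetric, shift-invariant and pair-order invariant", {
  fr <- genAlleleFreqs(8, 4, seed = 1)
  gt <- sampleHWGenotypes(fr, 12, seed = 2)
  D <- dswMatrix(gt)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  # uniform per-locus size shift leaves distances unchanged
  shift <- matrix(rep(40L * (1:8), each = 12), 12, 8)
  gtS <- genotypeTable(gt@alleleA + shift, gt@alleleB + shift)
  expect_equal(unclass(dswMatrix(gtS))[, ], unclass(D)[, ])
  # swapping the stored allele order changes nothing (pairs are unordered)
  gtR <- genotypeTable(gt@alleleB, gt@alleleA)
  expect_equal(dswMatrix(gtR), D)
})

test_that("pairs sharing loci are averaged; disjoint pairs are flagged", {
  gt <- gtFromStrings(list(i1 = c("100/100", "-"),
                           i2 = c("104/104", "-"),
                           i3 = c("-", "120/124")))
  D <- dswMatrix(gt)
  expect_equal(unname(D["i1", "i2"]), 4)
  expect_true(is.na(D["i1", "i3"]))
  expect_equal(attr(D, "sharedLoci")["i1", "i3"], 0L)
  expect_error(njTree(D), "undefined")
})

test_that("neighbor joining is exact on an additive four-taxon matrix", {
  # tree: (A:1,B:2):1 to (C:3,D:4); additive path distances
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- D["B", "A"] <- 3
  D["A", "C"] <- D["C", "A"] <- 5
  D["A", "D"] <- D["D", "A"] <- 6
  D["B", "C"] <- D["C", "B"] <- 6
  D["B", "D"] <- D["D", "B"] <- 7
  D["C", "D"] <- D["D", "C"] <- 7
  tr <- njTree(D)
  expect_equal(length(tr$tip.label), 4)
  # recovered tree reproduces the additive distances exactly
  pd <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(pd, D, tolerance = 1e-12)
  # AB | CD split present: the true topology
  split <- ape::prop.part(tr)
  expect_equal(ape::dist.topo(tr,
    ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);"))[1], 0)
})

test_that("tree topology is invariant to input order and needs 3 leaves", {
  fr <- genAlleleFreqs(10, 4, seed = 3)
  gt <- sampleHWGenotypes(fr, 10, seed = 4)
  D <- dswMatrix(gt)
  t1 <- njTree(D)
  perm <- sample(10)
  t2 <- njTree(D[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1], 0)
  expect_error(njTree(D[1:2, 1:2]), "3")
})

test_that("DAPC separates synthetic groups and respects rank bounds", {
  fr <- genAlleleFreqs(14, 4, seed = 5)
  gt <- genTwoDemes(0.4, 15, fr, seed = 6)
  grp <- popLabels(gt)
  fit <- dapcFit(gt, grp, nPca = 6)
  expect_equal(fit$nDa, 1)                   # two groups, one axis
  expect_gt(fit$propCorrect, 0.95)
  # centroid ordering on axis 1 matches group-mean projection ordering
  mean1 <- tapply(fit$scores[, 1], fit$groups, mean)
  expect_equal(as.numeric(fit$centroids), as.numeric(mean1),
               tolerance = 1e-9)
})

test_that("cross-validation picks a sufficient PC count for separable data", {
  fr <- genAlleleFreqs(14, 4, seed = 7)
  gt <- genTwoDemes(0.45, 15, fr, seed = 8)
  cv <- dapcCrossval(gt, popLabels(gt), candidatePcs = c(2, 4, 6, 8),
                     reps = 15, seed = 9)
  expect_true(cv$bestPcs %in% c(2, 4, 6, 8))
  top <- max(cv$table$meanSuccess, na.rm = TRUE)
  expect_gt(top, 0.95)
  # tie rule: among counts within noise of the top, the smallest wins
  best <- cv$table$nPcs[which(cv$table$meanSuccess == top)]
  expect_equal(cv$bestPcs, min(best[cv$table$mse[match(best, cv$table$nPcs)]
                                    == min(cv$table$mse[match(
                                      best, cv$table$nPcs)])]))
})

test_that("random labels yield chance-level cross-validated success", {
  fr <- genAlleleFreqs(14, 4, seed = 10)
  gt <- sampleHWGenotypes(fr, 30, seed = 11)
  set.seed(12)
  grp <- sample(rep(c("g1", "g2", "g3"), each = 10))
  cv <- dapcCrossval(gt, grp, candidatePcs = c(4), reps = 40, seed = 13)
  expect_lt(abs(cv$table$meanSuccess[1] - 1 / 3), 0.2)
})

test_that("three synthetic groups are reassigned almost perfectly", {
  fr <- genAlleleFreqs(14, 4, seed = 14)
  g1 <- genTwoDemes(0.4, 10, fr, seed = 15)
  g2 <- genTwoDemes(0.4, 10, fr, seed = 16)
  a <- rbind(g1@alleleA, g2@alleleA[g2@pop == "deme2", , drop = FALSE])
  b <- rbind(g1@alleleB, g2@alleleB[g2@pop == "deme2", , drop = FALSE])
  rownames(a) <- rownames(b) <- sprintf("i%02d", seq_len(nrow(a)))
  gt <- genotypeTable(a, b)
  grp <- c(g1@pop, rep("deme3", 10))
  fit <- dapcFit(gt, grp, nPca = 8)
  expect_equal(fit$nDa, 2)
  expect_gte(fit$propCorrect, 0.95)
  # candidate PC counts at or beyond the training size are skipped
  cv <- dapcCrossval(gt, grp, candidatePcs = c(4, 29), reps = 5, seed = 17)
  expect_match(cv$table$note[cv$table$nPcs == 29], "skipped")
})
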