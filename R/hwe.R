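# log conditional probability (up to a constant) of a genotype count table
# under Hardy-Weinberg given allele counts: h*log(2) - sum(log(g_ab!))
logTableProb <- function(gmat) {
  h <- sum(gmat[upper.tri(gmat)])
  -sum(lgamma(gmat[upper.tri(gmat, diag = TRUE)] + 1)) + h * log(2)
}

# Markov-chain exact HWE probability test for one locus.
# State: the allele-token pairing across individuals; the proposal swaps one
# allele between two random individuals, which leaves the conditional
# Hardy-Weinberg law (uniform over token pairings) invariant, so every move
# is accepted and visited genotype tables follow the exact conditional
# distribution.
hweChainLocus <- function(ga, gb, dememorization, batches, itersPerBatch) {
  sizes <- sort(unique(c(ga, gb)))
  ai <- match(ga, sizes); bi <- match(gb, sizes)
  n <- length(ai); A <- length(sizes)
  gmat <- matrix(0L, A, A)
  for (i in seq_len(n)) {
    lo <- min(ai[i], bi[i]); hi <- max(ai[i], bi[i])
    gmat[lo, hi] <- gmat[lo, hi] + 1L
  }
  lpObs <- logTableProb(gmat)
  tol <- 1e-9
  cur <- rbind(pmin(ai, bi), pmax(ai, bi))
  lpCur <- lpObs
  stepOnce <- function() {
    uv <- sample.int(n, 2)
    u <- uv[1]; v <- uv[2]
    cu <- sample.int(2, 1); cv <- sample.int(2, 1)
    iu <- cur[cu, u]; iv <- cur[cv, v]
    if (iu == iv) return(invisible(NULL))
    # remove old cells, add new
    ou <- c(min(cur[1, u], cur[2, u]), max(cur[1, u], cur[2, u]))
    ov <- c(min(cur[1, v], cur[2, v]), max(cur[1, v], cur[2, v]))
    lpCur <<- lpCur + lgamma(gmat[ou[1], ou[2]] + 1) - (ou[1] != ou[2]) * log(2)
    gmat[ou[1], ou[2]] <<- gmat[ou[1], ou[2]] - 1L
    lpCur <<- lpCur - lgamma(gmat[ou[1], ou[2]] + 1)
    lpCur <<- lpCur + lgamma(gmat[ov[1], ov[2]] + 1) - (ov[1] != ov[2]) * log(2)
    gmat[ov[1], ov[2]] <<- gmat[ov[1], ov[2]] - 1L
    lpCur <<- lpCur - lgamma(gmat[ov[1], ov[2]] + 1)
    cur[cu, u] <<- iv; cur[cv, v] <<- iu
    nu <- c(min(cur[1, u], cur[2, u]), max(cur[1, u], cur[2, u]))
    nv <- c(min(cur[1, v], cur[2, v]), max(cur[1, v], cur[2, v]))
    lpCur <<- lpCur + lgamma(gmat[nu[1], nu[2]] + 1)
    gmat[nu[1], nu[2]] <<- gmat[nu[1], nu[2]] + 1L
    lpCur <<- lpCur - lgamma(gmat[nu[1], nu[2]] + 1) + (nu[1] != nu[2]) * log(2)
    lpCur <<- lpCur + lgamma(gmat[nv[1], nv[2]] + 1)
    gmat[nv[1], nv[2]] <<- gmat[nv[1], nv[2]] + 1L
    lpCur <<- lpCur - lgamma(gmat[nv[1], nv[2]] + 1) + (nv[1] != nv[2]) * log(2)
    invisible(NULL)
  }
  for (s in seq_len(dememorization)) stepOnce()
  bm <- numeric(batches)
  for (b in seq_len(batches)) {
    hit <- 0L
    for (s in seq_len(itersPerBatch)) {
      stepOnce()
      if (lpCur <= lpObs + tol) hit <- hit + 1L
    }
    bm[b] <- hit / itersPerBatch
  }
  list(p = mean(bm), se = stats::sd(bm) / sqrt(batches))
}

#' Exact Hardy-Weinberg test (Markov-chain estimate)
#'
#' Estimates, per locus, the exact probability-test p-value: the
#' probability, conditional on the observed allele counts, of genotype
#' tables no more probable than the observed one under Hardy-Weinberg.
#' The chain operates on allele-token pairings (every proposal is accepted;
#' the stationary law is the exact conditional distribution); the standard
#' error comes from batch means.
#'
#' @param table a \linkS4class{GenotypeTable}.
#' @param dememorization burn-in steps.
#' @param batches number of batches.
#' @param itersPerBatch chain steps per batch.
#' @param seed optional integer seed.
#' @return data.frame with one row per locus: \code{locus}, \code{p},
#'   \code{se}, \code{n} (typed individuals), \code{Na}.  Monomorphic loci
#'   get \code{p = NA}.
#' @export
hweExactTest <- function(table, dememorization = 10000, batches = 20,
                         itersPerBatch = 5000, seed = NULL) {
  stopifnot(dememorization > 0, batches > 0, itersPerBatch > 0)
  if (!is.null(seed)) set.seed(seed)
  A <- table@alleleA; B <- table@alleleB
  rows <- lapply(seq_len(nLoc(table)), function(l) {
    typed <- which(!is.na(A[, l]))
    al <- A[typed, l]; bl <- B[typed, l]
    if (length(unique(c(al, bl))) < 2)
      return(data.frame(locus = lociNames(table)[l], p = NA_real_,
                        se = NA_real_, n = length(typed),
                        Na = length(unique(c(al, bl)))))
    r <- hweChainLocus(al, bl, dememorization, batches, itersPerBatch)
    data.frame(locus = lociNames(table)[l], p = r$p, se = r$se,
               n = length(typed), Na = length(unique(c(al, bl))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# G log-likelihood-ratio statistic of a contingency table
gStatistic <- function(tab) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  o <- tab[tab > 0]
  2 * sum(o * log(o / e[tab > 0]))
}

#' Exact test of genotypic disequilibrium between two loci
#'
#' Monte-Carlo exact conditional test on the genotype x genotype
#' contingency table of individuals typed at both loci, using the
#' log-likelihood-ratio (G) statistic: the genotypes of the second locus
#' are permuted across individuals, which samples the null of independent
#' genotypes with both margins fixed.  p is the fraction of permuted
#' tables with G at least the observed; the SE comes from batch means.
#'
#' @param table a \linkS4class{GenotypeTable}.
#' @param pair length-2 vector of locus names or indices.
#' @param batches number of batches.
#' @param itersPerBatch permutations per batch.
#' @param seed optional integer seed.
#' @return A one-row data.frame: \code{locus1}, \code{locus2}, \code{p},
#'   \code{se}, \code{n}, \code{degenerate}.
#' @export
genotypicLDTest <- function(table, pair, batches = 20,
                            itersPerBatch = 5000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(pair)) pair <- match(pair, lociNames(table))
  stopifnot(length(pair) == 2, !anyNA(pair))
  A <- table@alleleA; B <- table@alleleB
  ok <- !is.na(A[, pair[1]]) & !is.na(A[, pair[2]])
  g1 <- paste(A[ok, pair[1]], B[ok, pair[1]], sep = "/")
  g2 <- paste(A[ok, pair[2]], B[ok, pair[2]], sep = "/")
  n <- sum(ok)
  base <- data.frame(locus1 = lociNames(table)[pair[1]],
                     locus2 = lociNames(table)[pair[2]],
                     p = 1, se = NA_real_, n = n, degenerate = TRUE)
  if (n < 2 || length(unique(g1)) < 2 || length(unique(g2)) < 2)
    return(base)
  gObs <- gStatistic(table(g1, g2))
  bm <- numeric(batches)
  for (b in seq_len(batches)) {
    hits <- 0L
    for (s in seq_len(itersPerBatch)) {
      gp <- gStatistic(table(g1, sample(g2)))
      if (gp >= gObs - 1e-9) hits <- hits + 1L
    }
    bm[b] <- hits / itersPerBatch
  }
  base$p <- mean(bm); base$se <- stats::sd(bm) / sqrt(batches)
  base$degenerate <- FALSE
  base
}

#' Genotypic disequilibrium tests for all locus pairs
#'
#' @inheritParams genotypicLDTest
#' @return data.frame with one row per locus pair, plus a Bonferroni-
#'   adjusted p column (raw p-values are the primary output).
#' @export
ldAllPairs <- function(table, batches = 20, itersPerBatch = 5000,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prs <- utils::combn(nLoc(table), 2)
  out <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k)
    genotypicLDTest(table, prs[, k], batches, itersPerBatch)))
  out$pBonferroni <- pmin(1, out$p * nrow(out))
  out
}
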