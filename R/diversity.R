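#' Per-locus diversity summary
#'
#' Computes, per locus over non-missing genotypes: the allele count Na,
#' observed heterozygosity Ho, Nei's unbiased expected heterozygosity
#' He = (2n/(2n-1)) (1 - sum p_i^2), and the polymorphism information
#' content PIC = 1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2.  Column means are
#' unweighted over loci with data.
#'
#' @param table a \linkS4class{GenotypeTable}.
#' @return A list: \code{perLocus}, data.frame with rows per locus and
#'   columns \code{n} (typed individuals), \code{Na}, \code{Ho}, \code{He},
#'   \code{PIC}; and \code{means}, the unweighted column means.
#' @export
diversitySummary <- function(table) {
  fr <- alleleFreqs(table)
  A <- table@alleleA; B <- table@alleleB
  per <- lapply(seq_len(nLoc(table)), function(l) {
    typed <- !is.na(A[, l])
    n <- sum(typed)
    if (n == 0)
      return(data.frame(n = 0L, Na = NA_integer_, Ho = NA_real_,
                        He = NA_real_, PIC = NA_real_))
    p <- fr[[l]]$freq
    Na <- length(p)
    Ho <- mean(A[typed, l] != B[typed, l])
    sp2 <- sum(p^2)
    He <- if (n > 0) (2 * n / (2 * n - 1)) * (1 - sp2) else NA_real_
    pp <- outer(p^2, p^2)
    PIC <- 1 - sp2 - sum(pp[upper.tri(pp)]) * 2
    data.frame(n = n, Na = Na, Ho = Ho, He = He, PIC = PIC)
  })
  perLocus <- do.call(rbind, per)
  rownames(perLocus) <- lociNames(table)
  means <- colMeans(perLocus[, c("Na", "Ho", "He", "PIC")], na.rm = TRUE)
  list(perLocus = perLocus, means = means)
}

#' Weir-Cockerham Fis
#'
#' The Weir-Cockerham (1984) within-population inbreeding estimator f for a
#' single sample, per locus and combined across loci by summing the
#' between-individual (b) and within-individual (c) variance components
#' over alleles and loci: f = 1 - sum(c) / sum(b + c).
#'
#' @param table a \linkS4class{GenotypeTable}.
#' @return A list: \code{perLocus}, named numeric vector of per-locus Fis
#'   (NA for monomorphic or undersampled loci); \code{multilocus}, the
#'   variance-component-sum estimate across loci.
#' @export
fisWC <- function(table) {
  A <- table@alleleA; B <- table@alleleB
  perLocus <- stats::setNames(rep(NA_real_, nLoc(table)), lociNames(table))
  bTot <- cTot <- 0
  for (l in seq_len(nLoc(table))) {
    typed <- which(!is.na(A[, l]))
    n <- length(typed)
    if (n < 2) next
    al <- c(A[typed, l], B[typed, l])
    sizes <- sort(unique(al))
    if (length(sizes) < 2) next
    bl <- cl <- 0
    for (s in sizes) {
      p <- mean(al == s)
      h <- mean((A[typed, l] == s) != (B[typed, l] == s))
      b <- (n / (n - 1)) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
      cc <- h / 2
      bl <- bl + b; cl <- cl + cc
    }
    if (bl + cl > 0) perLocus[l] <- 1 - cl / (bl + cl)
    bTot <- bTot + bl; cTot <- cTot + cl
  }
  multilocus <- if (bTot + cTot > 0) 1 - cTot / (bTot + cTot) else NA_real_
  list(perLocus = perLocus, multilocus = multilocus)
}
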