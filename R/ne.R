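# expected sampling r2 given sample size S (random mating)
expectedR2 <- function(S) {
  if (S >= 30) 1 / S + 3.19 / S^2 else 0.0018 + 0.907 / S + 4.44 / S^2
}

# transform mean r2 minus sampling expectation into an Ne point estimate
r2ToNe <- function(r2bar, S) {
  r2p <- r2bar - expectedR2(S)
  if (r2p <= 0) return(Inf)
  if (S >= 30) {
    disc <- 1 / 9 - 2.76 * r2p
    if (disc < 0) return(Inf)
    (1 / 3 + sqrt(disc)) / (2 * r2p)
  } else {
    disc <- 0.308^2 - 2.08 * r2p
    if (disc < 0) return(Inf)
    (0.308 + sqrt(disc)) / (2 * r2p)
  }
}

#' Linkage-disequilibrium effective population size
#'
#' Single-sample LD estimator of contemporary Ne.  Alleles rarer than
#' \code{pcrit} are excluded per locus (a locus is dropped when fewer than
#' two alleles remain).  For every locus pair, over the individuals typed
#' at both, the Burrows composite disequilibrium is computed from allele
#' dosages X, Y as Delta = (n/(n-1)) (mean(XY)/2 - 2 p q) + p q / (n-1)
#' and squared into the composite correlation
#' r2 = Delta^2 / [(p(1-p) + DA)(q(1-q) + DB)], with DA and DB the
#' within-locus homozygote-excess disequilibria (the genotypic-data
#' convention of the standard LD-Ne software).  The weighted mean r2 over
#' comparisons (weights = pairwise sample sizes) is corrected by the
#' sampling expectation E[r2|S] at the harmonic mean sample size S, and
#' transformed to Ne with the random-mating small-sample coefficients.
#' A mean r2 at or below its sampling expectation yields an infinite
#' estimate.  Confidence intervals: parametric via chi-square on the
#' number of comparisons, and jackknife over loci.
#'
#' @param table a \linkS4class{GenotypeTable}.
#' @param pcrit minimum allele frequency admitted.
#' @return A \linkS4class{NeEstimate}.
#' @export
ldNe <- function(table, pcrit = 0.02) {
  A <- table@alleleA; B <- table@alleleB
  fr <- alleleFreqs(table)
  keep <- list()
  for (l in seq_len(nLoc(table))) {
    f <- fr[[l]]$freq
    ok <- names(f)[f >= pcrit]
    if (length(ok) >= 2) keep[[lociNames(table)[l]]] <- as.integer(ok)
  }
  if (length(keep) < 2)
    stop("fewer than 2 usable polymorphic loci after Pcrit screening")
  loci <- match(names(keep), lociNames(table))
  L <- length(loci)

  r2s <- wts <- ns <- numeric(0)
  pairLocus <- matrix(integer(0), ncol = 2)
  for (x in 1:(L - 1)) for (y in (x + 1):L) {
    l1 <- loci[x]; l2 <- loci[y]
    sh <- which(!is.na(A[, l1]) & !is.na(A[, l2]))
    n <- length(sh)
    if (n < 4) next
    for (sA in keep[[x]]) {
      X <- (A[sh, l1] == sA) + (B[sh, l1] == sA)
      p <- mean(X) / 2
      if (p <= 0 || p >= 1) next
      # biallelic loci contribute one allele to avoid duplicate comparisons
      if (length(keep[[x]]) == 2 && sA != keep[[x]][1]) next
      for (sB in keep[[y]]) {
        if (length(keep[[y]]) == 2 && sB != keep[[y]][1]) next
        Y <- (A[sh, l2] == sB) + (B[sh, l2] == sB)
        q <- mean(Y) / 2
        if (q <= 0 || q >= 1) next
        delta <- (n / (n - 1)) * (mean(X * Y) / 2 - 2 * p * q) +
          p * q / (n - 1)
        DA <- mean(X == 2) - p^2
        DB <- mean(Y == 2) - q^2
        den <- (p * (1 - p) + DA) * (q * (1 - q) + DB)
        if (den <= 0) next
        r2 <- delta^2 / den
        r2s <- c(r2s, r2); wts <- c(wts, n); ns <- c(ns, n)
        pairLocus <- rbind(pairLocus, c(l1, l2))
      }
    }
  }
  if (!length(r2s)) stop("no usable locus-pair comparisons")
  S <- 1 / stats::weighted.mean(1 / ns, wts)
  if (S < 4) stop("harmonic mean sample size below 4")
  r2bar <- stats::weighted.mean(r2s, wts)
  ne <- r2ToNe(r2bar, S)
  J <- length(r2s)

  # parametric chi-square CI on the mean r2
  r2lo <- r2bar * J / stats::qchisq(0.975, J)
  r2hi <- r2bar * J / stats::qchisq(0.025, J)
  ciParam <- c(r2ToNe(r2hi, S), r2ToNe(r2lo, S))
  ciParam <- sort(ciParam)

  # jackknife over loci
  ul <- unique(as.vector(pairLocus))
  r2j <- vapply(ul, function(l) {
    kp <- pairLocus[, 1] != l & pairLocus[, 2] != l
    if (!any(kp)) return(NA_real_)
    stats::weighted.mean(r2s[kp], wts[kp])
  }, numeric(1))
  r2j <- r2j[!is.na(r2j)]
  ciJack <- c(NA_real_, NA_real_)
  if (length(r2j) >= 2) {
    Lj <- length(r2j)
    vj <- (Lj - 1) / Lj * sum((r2j - mean(r2j))^2)
    if (vj > 0) {
      nEff <- max(2, 2 * r2bar^2 / vj)
      lo <- r2bar * nEff / stats::qchisq(0.975, nEff)
      hi <- r2bar * nEff / stats::qchisq(0.025, nEff)
      ciJack <- sort(c(r2ToNe(hi, S), r2ToNe(lo, S)))
    }
  }
  new("NeEstimate", r2 = r2bar, expR2 = expectedR2(S), S = S,
      nComparisons = J, ne = ne, ciParam = ciParam, ciJack = ciJack,
      pcrit = pcrit)
}

setMethod("show", "NeEstimate", function(object) {
  cat("LD effective population size (Pcrit =", object@pcrit, ")\n")
  cat(sprintf("  mean r2 = %.6f (E[r2|S] = %.6f, S = %.1f, %d comparisons)\n",
              object@r2, object@expR2, object@S, object@nComparisons))
  ne <- if (is.finite(object@ne)) sprintf("%.1f", object@ne) else "infinite"
  cat("  Ne =", ne, "\n")
  cat(sprintf("  95%% CI (parametric): %.1f - %.1f\n",
              object@ciParam[1], object@ciParam[2]))
  if (!anyNA(object@ciJack))
    cat(sprintf("  95%% CI (jackknife):  %.1f - %.1f\n",
                object@ciJack[1], object@ciJack[2]))
})

#' Ratio of effective to census population size
#'
#' @param ne a \linkS4class{NeEstimate} or a finite numeric Ne.
#' @param census census population size.
#' @return Ne / census at full precision (round only for presentation).
#' @export
neRatio <- function(ne, census) {
  stopifnot(census > 0)
  v <- if (is(ne, "NeEstimate")) ne@ne else ne
  if (!is.finite(v)) {
    warning("infinite Ne estimate: Ne/N undefined")
    return(NA_real_)
  }
  v / census
}
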