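#' Stepwise-weighted (Dsw) genetic distance between individuals
#'
#' For each locus typed in both individuals, with within-individual allele
#' frequency vectors x, y (entries 0.5/0.5 for heterozygotes, 1 for
#' homozygotes) over allele sizes s:
#' W(u, v) = sum_ij u_i v_j |s_i - s_j| and
#' Dsw = W(x, y) - (W(x, x) + W(y, y)) / 2.
#' The individual-level distance is the mean over shared typed loci, so
#' pairs with different missingness remain comparable.  Identical genotypes
#' are at distance zero; the measure uses only allele-size differences, so
#' it is invariant to a uniform size shift at a locus and suits loci
#' mutating in repeat-unit steps.
#'
#' @param table a \linkS4class{GenotypeTable}.
#' @return A square symmetric numeric matrix with zero diagonal and an
#'   attribute \code{sharedLoci} (matrix of shared typed locus counts).
#'   Pairs sharing no typed locus get \code{NA}.
#' @export
dswMatrix <- function(table) {
  n <- nInd(table)
  A <- table@alleleA; B <- table@alleleB
  D <- matrix(0, n, n, dimnames = list(indNames(table), indNames(table)))
  SH <- matrix(0L, n, n, dimnames = dimnames(D))
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sh <- which(!is.na(A[i, ]) & !is.na(A[j, ]))
    SH[i, j] <- SH[j, i] <- length(sh)
    if (!length(sh)) { D[i, j] <- D[j, i] <- NA_real_; next }
    dl <- vapply(sh, function(l) {
      xa <- c(A[i, l], B[i, l]); ya <- c(A[j, l], B[j, l])
      wxy <- mean(abs(outer(xa, ya, "-")))
      wxx <- 0.5 * abs(xa[1] - xa[2])
      wyy <- 0.5 * abs(ya[1] - ya[2])
      wxy - (wxx + wyy) / 2
    }, numeric(1))
    D[i, j] <- D[j, i] <- mean(dl)
  }
  attr(D, "sharedLoci") <- SH
  attr(D, "metric") <- "Dsw"
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining via \code{\link[ape]{nj}}.  Negative branch
#' lengths (possible under NJ) are retained but flagged with a warning.
#'
#' @param d square distance matrix (complete; no NA entries).
#' @return An unrooted \code{phylo} tree.
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 individuals")
  if (anyNA(d)) stop("distance matrix has undefined entries")
  tr <- ape::nj(d)
  if (any(tr$edge.length < 0))
    warning("tree contains negative branch lengths (retained)")
  tr
}
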