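#' Construct a GenotypeTable
#'
#' Builds the package's central genotype container from two allele matrices.
#' Pairs are normalised so the smaller allele is stored first; ordering of
#' the input pair does not matter.
#'
#' @param alleleA,alleleB integer matrices (individuals x loci) holding the
#'   two alleles of each diploid genotype; \code{NA} in both marks a missing
#'   cell.  Dimnames of \code{alleleA} name individuals and loci.
#' @param pop optional character vector of population labels per individual.
#' @param metadata optional list of per-table metadata.
#'
#' @return A \linkS4class{GenotypeTable}.
#' @examples
#' a <- matrix(c(100L, 104L), 1, 2, dimnames = list("i1", c("L1", "L2")))
#' b <- matrix(c(104L, 104L), 1, 2, dimnames = list("i1", c("L1", "L2")))
#' genotypeTable(a, b)
#' @export
genotypeTable <- function(alleleA, alleleB, pop = NULL, metadata = list()) {
  storage.mode(alleleA) <- "integer"
  storage.mode(alleleB) <- "integer"
  if (is.null(dimnames(alleleB))) dimnames(alleleB) <- dimnames(alleleA)
  lo <- pmin(alleleA, alleleB)
  hi <- pmax(alleleA, alleleB)
  dimnames(lo) <- dimnames(hi) <- dimnames(alleleA)
  if (is.null(pop)) pop <- rep(NA_character_, nrow(lo))
  new("GenotypeTable", alleleA = lo, alleleB = hi,
      pop = as.character(pop), metadata = metadata)
}

#' @describeIn genotypeTable number of individuals
#' @param x a GenotypeTable
#' @export
nInd <- function(x) nrow(x@alleleA)

#' @describeIn genotypeTable number of loci
#' @export
nLoc <- function(x) ncol(x@alleleA)

#' @describeIn genotypeTable individual identifiers
#' @export
indNames <- function(x) rownames(x@alleleA)

#' @describeIn genotypeTable locus identifiers
#' @export
lociNames <- function(x) colnames(x@alleleA)

#' @describeIn genotypeTable population labels (NA when unknown)
#' @export
popLabels <- function(x) x@pop

#' @describeIn genotypeTable logical individuals x loci matrix of missing cells
#' @export
isMissing <- function(x) is.na(x@alleleA)

#' @describeIn genotypeTable the two allele matrices as a list(a, b)
#' @export
alleleMatrices <- function(x) list(a = x@alleleA, b = x@alleleB)

#' Subset a GenotypeTable
#'
#' @param x a GenotypeTable
#' @param i individual index (integer, logical or names)
#' @param j locus index
#' @param ... ignored
#' @param drop ignored; always returns a GenotypeTable
#' @export
setMethod("[", "GenotypeTable", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nInd(x))
  if (missing(j)) j <- seq_len(nLoc(x))
  a <- x@alleleA[i, j, drop = FALSE]
  b <- x@alleleB[i, j, drop = FALSE]
  ii <- seq_len(nInd(x)); names(ii) <- indNames(x)
  new("GenotypeTable", alleleA = a, alleleB = b,
      pop = x@pop[ii[i]], metadata = x@metadata)
})

setMethod("show", "GenotypeTable", function(object) {
  cat("GenotypeTable:", nInd(object), "individuals x", nLoc(object),
      "loci\n")
  miss <- mean(isMissing(object))
  cat(sprintf("  missing cells: %.1f%%\n", 100 * miss))
  pops <- unique(object@pop[!is.na(object@pop)])
  if (length(pops))
    cat("  populations:", paste(pops, collapse = ", "), "\n")
})

#' Observed allele frequencies per locus
#'
#' Frequencies are computed over non-missing cells only; the gene count 2n
#' per locus is returned alongside.
#'
#' @param x a \linkS4class{GenotypeTable}
#' @return A list with one element per locus, each a list with \code{freq}
#'   (named numeric, names are allele sizes, values sum to 1) and \code{n}
#'   (number of genes, i.e. twice the typed individuals).
#' @export
alleleFreqs <- function(x) {
  out <- lapply(seq_len(nLoc(x)), function(l) {
    g <- c(x@alleleA[, l], x@alleleB[, l])
    g <- g[!is.na(g)]
    if (!length(g)) return(list(freq = numeric(0), n = 0L))
    tab <- table(g)
    f <- as.numeric(tab) / length(g)
    names(f) <- names(tab)
    list(freq = f, n = length(g))
  })
  names(out) <- lociNames(x)
  out
}

# allele size registry per locus (sorted unique observed sizes)
alleleRegistry <- function(x) {
  lapply(stats::setNames(seq_len(nLoc(x)), lociNames(x)), function(l) {
    sort(unique(stats::na.omit(c(x@alleleA[, l], x@alleleB[, l]))))
  })
}
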