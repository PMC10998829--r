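#' Consensus genotypes from replicate PCR calls
#'
#' Applies the multi-tube consensus rule for noninvasive genotyping: a
#' homozygote is accepted when seen in at least \code{minHom} replicates, a
#' heterozygote when seen in at least \code{minHet}.  Because allelic
#' dropout makes false homozygotes far likelier than false heterozygotes,
#' a qualifying heterozygote is only accepted when no homozygous genotype
#' was itself observed \code{minHet} or more times; conflicting qualifying
#' genotypes yield a missing cell flagged \code{"ambiguous"}.
#'
#' @param calls a \linkS4class{ReplicateCalls}.
#' @param minHom minimum replicate occurrences to accept a homozygote.
#' @param minHet minimum replicate occurrences to accept a heterozygote.
#' @return A \linkS4class{GenotypeTable} (samples x loci); the consensus
#'   flag matrix (\code{"called"}, \code{"missing"}, \code{"ambiguous"})
#'   is in \code{metadata$flags}.
#' @export
callConsensus <- function(calls, minHom = 3, minHet = 2) {
  d <- calls@calls
  stopifnot(minHet <= minHom)
  samples <- unique(d$sample)
  loci <- unique(d$locus)
  a <- b <- matrix(NA_integer_, length(samples), length(loci),
                   dimnames = list(samples, loci))
  flags <- matrix("missing", length(samples), length(loci),
                  dimnames = list(samples, loci))
  key <- paste(d$sample, d$locus, sep = "\r")
  for (cell in split(seq_len(nrow(d)), key)) {
    dd <- d[cell, ]
    i <- match(dd$sample[1], samples); l <- match(dd$locus[1], loci)
    ok <- !is.na(dd$allele1)
    if (!any(ok)) next
    g <- paste(dd$allele1[ok], dd$allele2[ok], sep = "/")
    tab <- table(g)
    isHom <- vapply(strsplit(names(tab), "/"),
                    function(p) p[1] == p[2], logical(1))
    homQ <- names(tab)[isHom & tab >= minHom]
    hetQ <- names(tab)[!isHom & tab >= minHet]
    homSeen <- names(tab)[isHom & tab >= minHet]
    call <- NULL
    if (length(homQ) == 1 && !length(hetQ)) call <- homQ
    else if (length(hetQ) == 1 && !length(homQ)) {
      if (length(homSeen)) flags[i, l] <- "ambiguous" else call <- hetQ
    } else if (length(homQ) + length(hetQ) >= 2) flags[i, l] <- "ambiguous"
    if (!is.null(call)) {
      al <- as.integer(strsplit(call, "/")[[1]])
      a[i, l] <- al[1]; b[i, l] <- al[2]
      flags[i, l] <- "called"
    }
  }
  genotypeTable(a, b, metadata = list(flags = flags))
}

# per-pair allele mismatch count over loci typed in both; NA-shared handling
# returns list(mismatch = total differing alleles, shared = loci compared)
pairMismatch <- function(a1, b1, a2, b2) {
  sh <- which(!is.na(a1) & !is.na(a2))
  mm <- 0L
  for (l in sh) {
    # multiset intersection size of {a1,b1} and {a2,b2}
    x <- c(a1[l], b1[l]); y <- c(a2[l], b2[l])
    inter <- 0L
    for (v in x) {
      j <- match(v, y)
      if (!is.na(j)) { inter <- inter + 1L; y <- y[-j] }
    }
    mm <- mm + (2L - inter)
  }
  list(mismatch = mm, shared = length(sh))
}

#' Collapse recaptured samples into individuals
#'
#' Two samples are linked when, over loci typed in both, their genotypes
#' differ by at most \code{maxMismatch} alleles (mismatches counted per
#' allele after optimal pairing within each locus).  Pairs sharing fewer
#' than \code{minSharedLoci} typed loci are never linked.  Clusters are
#' formed by single linkage; the collapsed genotype is the majority call
#' per locus across cluster members.
#'
#' @param table a \linkS4class{GenotypeTable} of samples.
#' @param maxMismatch maximum allele mismatches tolerated between samples
#'   of one individual (1 = one allele at one locus).
#' @param minSharedLoci minimum shared typed loci to attempt a match.
#' @param prefix name prefix for the consolidated individuals.
#' @return A list: \code{table}, the collapsed \linkS4class{GenotypeTable}
#'   (one row per inferred individual, source sample ids in
#'   \code{metadata$sources}); \code{clusters}, a list of sample-id vectors.
#' @export
matchIndividuals <- function(table, maxMismatch = 1, minSharedLoci = 7,
                             prefix = "IND") {
  n <- nInd(table)
  A <- table@alleleA; B <- table@alleleB
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    pm <- pairMismatch(A[i, ], B[i, ], A[j, ], B[j, ])
    if (pm$shared >= minSharedLoci && pm$mismatch <= maxMismatch)
      parent[find(i)] <- find(j)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  clusters <- split(indNames(table), comp)
  ord <- order(vapply(clusters, function(s) min(match(s, indNames(table))),
                      integer(1)))
  clusters <- clusters[ord]
  names(clusters) <- sprintf("%s%02d", prefix, seq_along(clusters))

  L <- nLoc(table)
  a <- b <- matrix(NA_integer_, length(clusters), L,
                   dimnames = list(names(clusters), lociNames(table)))
  for (ci in seq_along(clusters)) {
    rows <- match(clusters[[ci]], indNames(table))
    for (l in seq_len(L)) {
      g <- paste(A[rows, l], B[rows, l], sep = "/")
      g <- g[!is.na(A[rows, l])]
      if (!length(g)) next
      tab <- sort(table(g), decreasing = TRUE)
      al <- as.integer(strsplit(names(tab)[1], "/")[[1]])
      a[ci, l] <- al[1]; b[ci, l] <- al[2]
    }
    # consistency: any member pair disagreeing at more than maxMismatch?
    if (length(rows) > 1) {
      for (x in seq_along(rows)[-1]) {
        pm <- pairMismatch(A[rows[1], ], B[rows[1], ],
                           A[rows[x], ], B[rows[x], ])
        if (pm$mismatch > maxMismatch)
          warning("cluster ", names(clusters)[ci],
                  " contains samples differing by ", pm$mismatch,
                  " alleles (single-linkage chaining)")
      }
    }
  }
  # majority pop label per cluster
  pops <- vapply(clusters, function(s) {
    pl <- table@pop[match(s, indNames(table))]
    pl <- pl[!is.na(pl)]
    if (!length(pl)) NA_character_ else names(sort(table(pl),
                                                   decreasing = TRUE))[1]
  }, character(1))
  list(table = genotypeTable(a, b, pop = pops,
                             metadata = list(sources = clusters)),
       clusters = clusters)
}

#' Drop failing or uninformative loci
#'
#' Removes loci whose call rate falls below \code{minCallRate}
#' (amplification failure) or with fewer than \code{minAlleles} observed
#' alleles (low polymorphism), reporting each removal with its reason.
#'
#' @param table a \linkS4class{GenotypeTable}.
#' @param minCallRate minimum fraction of individuals typed at a locus.
#' @param minAlleles minimum observed allele count.
#' @return A list: \code{table} (filtered) and \code{report}
#'   (data.frame locus/reason for every removed locus).
#' @export
filterLoci <- function(table, minCallRate = 0.5, minAlleles = 2) {
  stopifnot(minCallRate >= 0, minCallRate <= 1, minAlleles >= 1)
  cr <- colMeans(!isMissing(table))
  na <- vapply(alleleRegistry(table), length, integer(1))
  drop <- cr < minCallRate | na < minAlleles
  if (all(drop)) stop("all loci would be removed")
  reason <- ifelse(cr < minCallRate, "amplification failure",
                   "low polymorphism")
  report <- data.frame(locus = lociNames(table)[drop],
                       reason = reason[drop], row.names = NULL)
  list(table = table[, !drop], report = report)
}
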