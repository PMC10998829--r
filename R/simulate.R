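#' Draw a synthetic multi-allelic marker panel
#'
#' Per-locus allele frequencies are drawn from a symmetric Dirichlet;
#' allele sizes sit on a 4-bp ladder starting at 100 bp so distances and
#' dropout behaviour resemble tetranucleotide microsatellites.
#'
#' @param loci number of loci.
#' @param allelesPerLocus alleles per locus; either a single count or a
#'   vector of candidate counts sampled uniformly per locus.
#' @param concentration symmetric Dirichlet concentration; large values give
#'   near-uniform frequencies.
#' @param seed optional integer seed.
#' @return A list with one element per locus (\code{L1}, \code{L2}, ...),
#'   each a list with \code{freq} (named numeric summing to 1, names are
#'   allele sizes in bp) and \code{n = NA} (no sample behind it).
#' @export
genAlleleFreqs <- function(loci, allelesPerLocus = 4, concentration = 1,
                           seed = NULL) {
  stopifnot(loci >= 1, all(allelesPerLocus >= 1), concentration > 0)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(loci), function(l) {
    k <- if (length(allelesPerLocus) > 1)
      sample(allelesPerLocus, 1) else allelesPerLocus
    g <- stats::rgamma(k, shape = concentration)
    f <- g / sum(g)
    names(f) <- as.character(100L + 4L * seq_len(k) - 4L)
    list(freq = f, n = NA_integer_)
  })
  names(out) <- paste0("L", seq_len(loci))
  out
}

#' Sample unrelated Hardy-Weinberg genotypes
#'
#' @param freqs allele frequencies as returned by \code{\link{genAlleleFreqs}}
#'   or \code{\link{alleleFreqs}}.
#' @param n number of individuals.
#' @param pop optional population label applied to all individuals.
#' @param prefix individual-name prefix.
#' @param seed optional integer seed.
#' @return A \linkS4class{GenotypeTable}.
#' @export
sampleHWGenotypes <- function(freqs, n, pop = NA_character_,
                              prefix = "ind", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- length(freqs)
  a <- b <- matrix(NA_integer_, n, L,
                   dimnames = list(sprintf("%s%02d", prefix, seq_len(n)),
                                   names(freqs)))
  for (l in seq_len(L)) {
    sizes <- as.integer(names(freqs[[l]]$freq))
    p <- freqs[[l]]$freq
    a[, l] <- sample(sizes, n, replace = TRUE, prob = p)
    b[, l] <- sample(sizes, n, replace = TRUE, prob = p)
  }
  genotypeTable(a, b, pop = rep(pop, n))
}

#' Build a pedigree table
#'
#' @param id character ids, parents listed before offspring.
#' @param dam,sire parent ids (\code{NA} for founders); a founder must have
#'   both parents missing.
#' @return data.frame with class \code{"pedigree_df"}.
#' @export
pedigree <- function(id, dam, sire) {
  id <- as.character(id); dam <- as.character(dam); sire <- as.character(sire)
  stopifnot(length(id) == length(dam), length(id) == length(sire))
  if (anyDuplicated(id)) stop("duplicate pedigree ids")
  if (any(is.na(dam) != is.na(sire)))
    stop("individuals must have either two known parents or none")
  pos <- match(c(dam, sire), id)
  own <- rep(seq_along(id), 2)
  if (any(!is.na(c(dam, sire)) & (is.na(pos) | pos >= own)))
    stop("parents must be listed before their offspring")
  structure(data.frame(id = id, dam = dam, sire = sire,
                       stringsAsFactors = FALSE),
            class = c("pedigree_df", "data.frame"))
}

#' Kinship and inbreeding from a pedigree
#'
#' Standard tabular recursion: founders are mutually unrelated and
#' non-inbred unless \code{f0}/\code{k0} say otherwise;
#' k(new, z) = (k(dam, z) + k(sire, z)) / 2,
#' k(new, new) = (1 + k(dam, sire)) / 2, F(new) = k(dam, sire).
#'
#' @param ped a \code{\link{pedigree}}.
#' @param f0 founder inbreeding coefficient.
#' @param k0 founder pairwise kinship.
#' @return list(kinship = matrix, F = named vector).
#' @export
pedigreeKinship <- function(ped, f0 = 0, k0 = 0) {
  n <- nrow(ped)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  Fv <- stats::setNames(numeric(n), ped$id)
  for (i in seq_len(n)) {
    if (is.na(ped$dam[i])) {          # founder
      Fv[i] <- f0
      K[i, i] <- 0.5 * (1 + f0)
      if (i > 1) {
        fo <- which(is.na(ped$dam[seq_len(i - 1)]))
        K[i, fo] <- K[fo, i] <- k0
        nf <- setdiff(seq_len(i - 1), fo)
        # founders added after non-founders: treat as unrelated to them
        K[i, nf] <- K[nf, i] <- 0
      }
    } else {
      d <- match(ped$dam[i], ped$id); s <- match(ped$sire[i], ped$id)
      Fv[i] <- K[d, s]
      if (i > 1) {
        z <- seq_len(i - 1)
        K[i, z] <- K[z, i] <- 0.5 * (K[d, z] + K[s, z])
      }
      K[i, i] <- 0.5 * (1 + K[d, s])
    }
  }
  list(kinship = K, F = Fv)
}

#' Drop genes down a pedigree
#'
#' Founder alleles are drawn i.i.d. from the supplied frequencies and
#' transmitted Mendelianly; the true kinship matrix and inbreeding
#' coefficients from the pedigree recursion are returned alongside, giving
#' ground truth for relatedness and inbreeding estimators.
#'
#' @param ped a \code{\link{pedigree}}.
#' @param freqs per-locus allele frequencies (see \code{\link{genAlleleFreqs}}).
#' @param seed optional integer seed.
#' @return list(gt = GenotypeTable, kinship = matrix, F = named numeric).
#' @export
geneDrop <- function(ped, freqs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped); L <- length(freqs)
  a <- b <- matrix(NA_integer_, n, L, dimnames = list(ped$id, names(freqs)))
  for (l in seq_len(L)) {
    sizes <- as.integer(names(freqs[[l]]$freq))
    p <- freqs[[l]]$freq
    for (i in seq_len(n)) {
      if (is.na(ped$dam[i])) {
        a[i, l] <- sample(sizes, 1, prob = p)
        b[i, l] <- sample(sizes, 1, prob = p)
      } else {
        d <- match(ped$dam[i], ped$id); s <- match(ped$sire[i], ped$id)
        a[i, l] <- if (stats::runif(1) < 0.5) a[d, l] else b[d, l]
        b[i, l] <- if (stats::runif(1) < 0.5) a[s, l] else b[s, l]
      }
    }
  }
  kf <- pedigreeKinship(ped)
  list(gt = genotypeTable(a, b), kinship = kf$kinship, F = kf$F)
}

#' Two differentiated demes with Hardy-Weinberg structure within demes
#'
#' Deme-specific allele frequencies are drawn around the ancestral
#' frequencies from the Balding-Nichols distribution with the requested
#' fixation index, then genotypes are sampled in Hardy-Weinberg proportions
#' within each deme.  Pooling the demes induces a Wahlund homozygote excess.
#'
#' @param divergence target fixation index in (0, 1).
#' @param nPerDeme individuals per deme (length-1 or length-2).
#' @param freqs ancestral per-locus allele frequencies.
#' @param seed optional integer seed.
#' @return A \linkS4class{GenotypeTable} with pop labels "deme1"/"deme2".
#' @export
genTwoDemes <- function(divergence, nPerDeme, freqs, seed = NULL) {
  stopifnot(divergence > 0, divergence < 1)
  if (!is.null(seed)) set.seed(seed)
  if (length(nPerDeme) == 1) nPerDeme <- rep(nPerDeme, 2)
  shape <- (1 - divergence) / divergence
  tabs <- lapply(1:2, function(d) {
    df <- lapply(freqs, function(fl) {
      g <- stats::rgamma(length(fl$freq), shape = shape * fl$freq)
      while (all(g == 0)) g <- stats::rgamma(length(fl$freq),
                                             shape = shape * fl$freq)
      f <- g / sum(g)
      names(f) <- names(fl$freq)
      list(freq = f, n = NA_integer_)
    })
    sampleHWGenotypes(df, nPerDeme[d], pop = paste0("deme", d),
                      prefix = paste0("d", d, "i"))
  })
  a <- rbind(tabs[[1]]@alleleA, tabs[[2]]@alleleA)
  b <- rbind(tabs[[1]]@alleleB, tabs[[2]]@alleleB)
  genotypeTable(a, b, pop = c(tabs[[1]]@pop, tabs[[2]]@pop))
}

#' Sample from an ideal Wright-Fisher population after drift
#'
#' A constant-size monoecious population with discrete generations and
#' random union of gametes (no selection, no mutation) is simulated forward
#' from Hardy-Weinberg initial genotypes; a sample from the final
#' generation is returned.  Serves as ground truth for the
#' linkage-disequilibrium effective-size estimator.
#'
#' @param N true population size.
#' @param generations generations of drift.
#' @param sampleSize individuals sampled from the final generation.
#' @param freqs initial per-locus allele frequencies.
#' @param seed optional integer seed.
#' @param maxTries regenerate attempts if every locus fixes.
#' @return A \linkS4class{GenotypeTable}.
#' @export
genWrightFisher <- function(N, generations, sampleSize, freqs, seed = NULL,
                            maxTries = 10) {
  stopifnot(N >= 1, generations >= 1, sampleSize <= N)
  if (!is.null(seed)) set.seed(seed)
  L <- length(freqs)
  for (try in seq_len(maxTries)) {
    a <- b <- matrix(NA_integer_, N, L)
    for (l in seq_len(L)) {
      sizes <- as.integer(names(freqs[[l]]$freq)); p <- freqs[[l]]$freq
      a[, l] <- sample(sizes, N, replace = TRUE, prob = p)
      b[, l] <- sample(sizes, N, replace = TRUE, prob = p)
    }
    for (g in seq_len(generations)) {
      dam <- sample(N, N, replace = TRUE)
      sire <- sample(N, N, replace = TRUE)
      fromA1 <- stats::runif(N * L) < 0.5
      fromA2 <- stats::runif(N * L) < 0.5
      na <- ifelse(fromA1, a[dam, ], b[dam, ])
      nb <- ifelse(fromA2, a[sire, ], b[sire, ])
      a <- matrix(na, N, L); b <- matrix(nb, N, L)
    }
    poly <- vapply(seq_len(L), function(l)
      length(unique(c(a[, l], b[, l]))) > 1, logical(1))
    if (any(poly)) break
    if (try == maxTries) warning("all loci fixed; returning last attempt")
    else warning("all loci fixed before sampling; regenerating")
  }
  keep <- sample(N, sampleSize)
  dimnames(a) <- dimnames(b) <- list(NULL, names(freqs))
  a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
  rownames(a) <- rownames(b) <- sprintf("wf%03d", seq_len(sampleSize))
  genotypeTable(a, b)
}

#' Corrupt true genotypes into noisy replicate PCR calls
#'
#' Emulates the replicate-genotyping regime of noninvasive fecal samples:
#' per replicate, a heterozygote loses one allele (allelic dropout, becoming
#' a false homozygote) with probability \code{dropout}; any surviving call
#' has one allele substituted by a wrong allele with probability
#' \code{falseAllele}; and the replicate fails outright with probability
#' \code{failRate}.
#'
#' @param gt the true \linkS4class{GenotypeTable}.
#' @param dropout per-replicate allelic dropout probability (heterozygotes).
#' @param falseAllele per-replicate false-allele probability.
#' @param failRate per-replicate amplification failure probability.
#' @param replicates number of replicate PCRs per sample x locus.
#' @param seed optional integer seed.
#' @return A \linkS4class{ReplicateCalls}.
#' @export
addReplicateNoise <- function(gt, dropout = 0, falseAllele = 0,
                              failRate = 0, replicates = 4, seed = NULL) {
  stopifnot(dropout >= 0, dropout <= 1, falseAllele >= 0, falseAllele <= 1,
            failRate >= 0, failRate <= 1, replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  reg <- alleleRegistry(gt)
  rows <- vector("list", nInd(gt) * nLoc(gt) * replicates)
  k <- 0L
  for (i in seq_len(nInd(gt))) for (l in seq_len(nLoc(gt))) {
    a0 <- gt@alleleA[i, l]; b0 <- gt@alleleB[i, l]
    for (r in seq_len(replicates)) {
      k <- k + 1L
      if (is.na(a0) || stats::runif(1) < failRate) {
        rows[[k]] <- data.frame(sample = indNames(gt)[i],
                                locus = lociNames(gt)[l],
                                replicate = r, allele1 = NA_integer_,
                                allele2 = NA_integer_)
        next
      }
      a <- a0; b <- b0
      if (a != b && stats::runif(1) < dropout) {
        if (stats::runif(1) < 0.5) a <- b else b <- a
      }
      if (stats::runif(1) < falseAllele) {
        sizes <- reg[[l]]
        wrong <- setdiff(sizes, c(a, b))
        if (!length(wrong)) wrong <- max(sizes) + 4L
        sub <- wrong[sample.int(length(wrong), 1)]
        if (stats::runif(1) < 0.5) a <- sub else b <- sub
      }
      rows[[k]] <- data.frame(sample = indNames(gt)[i],
                              locus = lociNames(gt)[l], replicate = r,
                              allele1 = min(a, b), allele2 = max(a, b))
    }
  }
  new("ReplicateCalls", calls = do.call(rbind, rows))
}

#' Random multi-generation pedigree for estimator benchmarking
#'
#' Founders are unrelated; each later generation is produced by sampling
#' parent pairs (optionally allowing selfing and forced full-sib matings)
#' from the previous generations.
#'
#' @param founders number of founders.
#' @param generations number of bred generations after the founders.
#' @param perGeneration offspring per generation.
#' @param selfing allow self-fertilisation when sampling pairs.
#' @param seed optional integer seed.
#' @return A \code{\link{pedigree}}.
#' @export
randomPedigree <- function(founders, generations, perGeneration,
                           selfing = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  id <- sprintf("F%03d", seq_len(founders))
  dam <- sire <- rep(NA_character_, founders)
  pool <- id
  for (g in seq_len(generations)) {
    for (j in seq_len(perGeneration)) {
      p1 <- sample(pool, 1)
      p2 <- if (selfing) sample(pool, 1) else sample(setdiff(pool, p1), 1)
      nid <- sprintf("G%d_%03d", g, j)
      id <- c(id, nid); dam <- c(dam, p1); sire <- c(sire, p2)
    }
    pool <- id[(length(id) - perGeneration + 1):length(id)]
  }
  pedigree(id, dam, sire)
}
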