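# Shared fixture builders; everything is generated in code at test time.

# tiny GenotypeTable from a list of "a/b" strings per individual
gtFromStrings <- function(rows, loci = NULL, pop = NULL) {
  n <- length(rows); L <- length(rows[[1]])
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  a <- b <- matrix(NA_integer_, n, L,
                   dimnames = list(names(rows), loci))
  for (i in seq_len(n)) for (l in seq_len(L)) {
    g <- rows[[i]][l]
    if (is.na(g) || g == "-") next
    al <- as.integer(strsplit(g, "/")[[1]])
    a[i, l] <- al[1]; b[i, l] <- al[2]
  }
  genotypeTable(a, b, pop = pop)
}

# ReplicateCalls for a single sample x locus cell from "a/b" / "fail" strings
cellCalls <- function(reps, sample = "s1", locus = "L1") {
  rows <- lapply(seq_along(reps), function(r) {
    if (reps[r] == "fail")
      return(data.frame(sample = sample, locus = locus, replicate = r,
                        allele1 = NA_integer_, allele2 = NA_integer_))
    al <- as.integer(strsplit(reps[r], "/")[[1]])
    data.frame(sample = sample, locus = locus, replicate = r,
               allele1 = min(al), allele2 = max(al))
  })
  new("ReplicateCalls", calls = do.call(rbind, rows))
}

# independent brute-force kinship oracle: naive recursion with memoisation,
# deliberately written differently from the package's tabular sweep
kinshipOracle <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  memo <- new.env()
  kin <- function(i, j) {
    if (i > j) { t <- i; i <- j; j <- t }
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- if (i == j) {
      if (is.na(ped$dam[i])) 0.5
      else 0.5 * (1 + kin(idx[[ped$dam[i]]], idx[[ped$sire[i]]]))
    } else {
      # j is never an ancestor of i when j > i (parents precede offspring)
      if (is.na(ped$dam[j])) 0
      else 0.5 * (kin(i, idx[[ped$dam[j]]]) + kin(i, idx[[ped$sire[j]]]))
    }
    memo[[key]] <- v
    v
  }
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) K[i, j] <- K[j, i] <- kin(i, j)
  K
}

# enumeration oracle for the biallelic exact HWE probability test
hweExactEnum <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  logp <- function(ab) {
    aa <- (nA - ab) / 2; bb <- n - aa - ab
    if (ab %% 2 != nA %% 2 || aa < 0 || bb < 0) return(NA_real_)
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(ab + 1) - lgamma(bb + 1) +
      ab * log(2) + lgamma(nA + 1) + lgamma(2 * n - nA + 1) -
      lgamma(2 * n + 1)
  }
  abs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  lp <- vapply(abs, logp, numeric(1))
  lp <- lp[!is.na(lp)]
  obs <- logp(nAB)
  sum(exp(lp[lp <= obs + 1e-9]))
}
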