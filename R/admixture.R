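#' Fit the Bayesian admixture model for one K
#'
#' Gibbs sampler over per-allele-copy cluster assignments, cluster allele
#' frequencies (correlated-frequencies F-model: each cluster drifts from
#' shared ancestral frequencies, per-cluster drift parameter with a
#' uniform prior), and per-individual admixture proportions Q with a
#' single Dirichlet parameter alpha updated by a Metropolis step
#' (proposal SD 0.025).  Missing alleles contribute nothing to the
#' likelihood.  Returns posterior means of Q and P and the mean data
#' log-likelihood over post-burn-in sweeps.  With the same seed and chain
#' settings the result is bit-identical.
#'
#' @param table a \linkS4class{GenotypeTable}.
#' @param K number of clusters (>= 1).
#' @param burnin burn-in sweeps.
#' @param reps post-burn-in sweeps.
#' @param alphaInit initial admixture Dirichlet parameter.
#' @param lambda Dirichlet parameter of the ancestral-frequency prior.
#' @param seed optional integer seed.
#' @return A \linkS4class{ClusterModel}.
#' @export
fitAdmixture <- function(table, K, burnin = 100000, reps = 1000000,
                         alphaInit = 1.0, lambda = 1.0, seed = NULL) {
  stopifnot(K >= 1, nInd(table) >= 1)
  if (K > nInd(table)) stop("K exceeds the number of individuals")
  if (!is.null(seed)) set.seed(seed)
  reg <- alleleRegistry(table)
  n <- nInd(table); L <- nLoc(table)
  Xa <- Xb <- matrix(0L, n, L)
  for (l in seq_len(L)) {
    Xa[, l] <- match(table@alleleA[, l], reg[[l]], nomatch = 0L)
    Xb[, l] <- match(table@alleleB[, l], reg[[l]], nomatch = 0L)
  }
  res <- .admixtureGibbs(Xa, Xb, vapply(reg, length, integer(1)),
                         as.integer(K), as.integer(burnin),
                         as.integer(reps), alphaInit, 0.025, lambda, 0.05)
  Q <- res$Q
  dimnames(Q) <- list(indNames(table), paste0("cluster", seq_len(K)))
  P <- res$P
  names(P) <- lociNames(table)
  for (l in seq_len(L))
    dimnames(P[[l]]) <- list(paste0("cluster", seq_len(K)),
                             as.character(reg[[l]]))
  new("ClusterModel", K = as.integer(K), Q = Q, P = P,
      logLik = res$logLik, logLikVar = res$logLikVar,
      settings = list(burnin = burnin, reps = reps, alpha = res$alpha,
                      lambda = lambda, seed = seed))
}

setMethod("show", "ClusterModel", function(object) {
  cat("Admixture model, K =", object@K, "\n")
  cat(sprintf("  mean log-likelihood: %.2f (trace var %.2f)\n",
              object@logLik, object@logLikVar))
  cat("  individuals:", nrow(object@Q), "\n")
})

#' Evanno delta-K model selection over replicate runs
#'
#' Computes, per K, the mean and SD of the data log-likelihood L(K) over
#' replicate runs, the successive differences L'(K) and |L''(K)|, and
#' Delta K = mean(|L(K+1) - 2 L(K) + L(K-1)|) / SD(L(K)).  Delta K is
#' defined only for interior K with a positive between-replicate SD; the
#' best K maximises it.
#'
#' @param runs list of \linkS4class{ClusterModel} objects covering a
#'   contiguous K range with >= 2 replicates per K.
#' @return list: \code{table} (data.frame K, meanL, sdL, dL, absD2L,
#'   deltaK) and \code{bestK}.
#' @export
evannoDeltaK <- function(runs) {
  ks <- vapply(runs, function(m) m@K, integer(1))
  ll <- vapply(runs, function(m) m@logLik, numeric(1))
  uk <- sort(unique(ks))
  if (length(uk) < 3) stop("need at least 3 consecutive K values")
  if (any(diff(uk) != 1)) stop("K values must be consecutive")
  if (any(table(ks) < 2)) stop("need >= 2 replicate runs per K")
  meanL <- tapply(ll, ks, mean)[as.character(uk)]
  sdL <- tapply(ll, ks, stats::sd)[as.character(uk)]
  m <- length(uk)
  dL <- c(NA, diff(meanL))
  absD2L <- deltaK <- rep(NA_real_, m)
  for (i in 2:(m - 1)) {
    absD2L[i] <- abs(meanL[i + 1] - 2 * meanL[i] + meanL[i - 1])
    if (sdL[i] > 0) deltaK[i] <- absD2L[i] / sdL[i]
  }
  interior <- 2:(m - 1)
  if (all(is.na(deltaK[interior])))
    stop("delta K undefined at every interior K ",
         "(zero between-replicate SD)")
  tab <- data.frame(K = uk, meanL = as.numeric(meanL),
                    sdL = as.numeric(sdL), dL = as.numeric(dL),
                    absD2L = absD2L, deltaK = deltaK)
  list(table = tab, bestK = uk[which.max(deltaK)])
}

#' Threshold assignment of individuals to clusters
#'
#' An individual is assigned to cluster k when its admixture proportion
#' Q[i, k] reaches the threshold; otherwise it is labelled
#' \code{"admixed"}.
#'
#' @param model a \linkS4class{ClusterModel} (or a Q matrix).
#' @param threshold assignment threshold in (0.5, 1].
#' @return character vector of labels (\code{"1"}, \code{"2"}, ...,
#'   or \code{"admixed"}), named by individual.
#' @export
assignClusters <- function(model, threshold = 0.9) {
  stopifnot(threshold > 0.5, threshold <= 1)
  Q <- if (is(model, "ClusterModel")) model@Q else model
  lab <- apply(Q, 1, function(q) {
    k <- which(q >= threshold)
    if (length(k) == 1) as.character(k) else "admixed"
  })
  stats::setNames(as.character(lab), rownames(Q))
}

# greedy maximum-correlation matching of the columns of Q2 onto Q1
matchColumns <- function(Q1, Q2) {
  K <- ncol(Q1)
  cors <- matrix(-Inf, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    v <- suppressWarnings(stats::cor(Q1[, i], Q2[, j]))
    cors[i, j] <- ifelse(is.na(v), 0, v)
  }
  perm <- integer(K)   # perm[i] = column of Q2 matched to column i of Q1
  used <- rep(FALSE, K)
  for (step in seq_len(K)) {
    best <- c(NA_integer_, NA_integer_); bv <- -Inf
    for (i in seq_len(K)) for (j in seq_len(K)) {
      if (perm[i] == 0 && !used[j] && cors[i, j] > bv) {
        bv <- cors[i, j]; best <- c(i, j)
      }
    }
    perm[best[1]] <- best[2]
    used[best[2]] <- TRUE
  }
  perm
}

#' Align replicate admixture runs (label-switching repair)
#'
#' Cluster labels are arbitrary across replicate runs at the same K; this
#' permutes each run's clusters to maximise column correlation with the
#' first run (greedy matching), and returns the aligned models with their
#' averaged Q matrix.
#'
#' @param models list of \linkS4class{ClusterModel} objects with the same
#'   K and individual order.
#' @return list: \code{models} (aligned), \code{meanQ}.
#' @export
alignReplicates <- function(models) {
  K <- models[[1]]@K
  stopifnot(all(vapply(models, function(m) m@K, integer(1)) == K))
  ref <- models[[1]]@Q
  out <- models
  for (m in seq_along(models)[-1]) {
    perm <- matchColumns(ref, models[[m]]@Q)
    Q <- models[[m]]@Q[, perm, drop = FALSE]
    colnames(Q) <- colnames(ref)
    P <- lapply(models[[m]]@P, function(pl) {
      pl2 <- pl[perm, , drop = FALSE]
      rownames(pl2) <- rownames(pl)
      pl2
    })
    out[[m]]@Q <- Q
    out[[m]]@P <- P
  }
  meanQ <- Reduce(`+`, lapply(out, function(m) m@Q)) / length(out)
  meanQ <- meanQ / rowSums(meanQ)
  list(models = out, meanQ = meanQ)
}
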