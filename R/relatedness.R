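# ---- shared helpers ---------------------------------------------------------

# frequency lookup for one locus: named numeric -> function of allele size
freqOf <- function(fl) {
  function(al) {
    i <- match(as.character(al), names(fl))
    ifelse(is.na(i), 0, unname(fl[i]))
  }
}

# probabilities of an unordered genotype pair under the nine condensed
# identity (Jacquard) states; gx = c(a, b), gy = c(c, d), p = freq lookup
jacquardCellProbs <- function(gx, gy, p) {
  a <- gx[1]; b <- gx[2]; c <- gy[1]; d <- gy[2]
  pa <- p(a); pb <- p(b); pc <- p(c); pd <- p(d)
  hwx <- if (a == b) pa^2 else 2 * pa * pb
  hwy <- if (c == d) pc^2 else 2 * pc * pd
  P <- numeric(9)
  xh <- a == b; yh <- c == d
  if (xh && yh && a == c) {                     # (aa, aa)
    P <- c(pa, pa^2, pa^2, pa^3, pa^2, pa^3, pa^2, pa^3, pa^4)
  } else if (xh && yh) {                        # (aa, cc), a != c
    P[2] <- pa * pc; P[4] <- pa * pc^2; P[6] <- pa^2 * pc
    P[9] <- pa^2 * pc^2
  } else if (xh && !yh && (c == a || d == a)) { # (aa, ab)
    po <- if (c == a) pd else pc
    P[3] <- pa * po; P[4] <- 2 * pa^2 * po
    P[8] <- pa^2 * po; P[9] <- 2 * pa^3 * po
  } else if (xh && !yh) {                       # (aa, cd), none shared
    P[4] <- 2 * pa * pc * pd; P[9] <- 2 * pa^2 * pc * pd
  } else if (!xh && yh && (a == c || b == c)) { # (ab, aa)
    po <- if (a == c) pb else pa
    P[5] <- pc * po; P[6] <- 2 * pc^2 * po
    P[8] <- pc^2 * po; P[9] <- 2 * pc^3 * po
  } else if (!xh && yh) {                       # (ab, cc), none shared
    P[6] <- 2 * pc * pa * pb; P[9] <- 2 * pc^2 * pa * pb
  } else {                                      # both heterozygous
    sx <- sort(c(a, b)); sy <- sort(c(c, d))
    if (all(sx == sy)) {                        # (ab, ab)
      P[7] <- 2 * pa * pb
      P[8] <- pa * pb * (pa + pb)
      P[9] <- 4 * pa^2 * pb^2
    } else {
      shared <- intersect(c(a, b), c(c, d))
      if (length(shared) == 1) {                # (ab, ac)
        s <- shared
        ox <- setdiff(c(a, b), s); oy <- setdiff(c(c, d), s)
        P[8] <- p(s) * p(ox) * p(oy)
        P[9] <- 4 * p(s)^2 * p(ox) * p(oy)
      } else {                                  # (ab, cd)
        P[9] <- hwx * hwy
      }
    }
  }
  P
}

# per-pair 9 x L state-probability matrix
jacquardProbMatrix <- function(ax, bx, ay, by, freqs) {
  L <- length(freqs)
  M <- matrix(NA_real_, 9, L)
  for (l in seq_len(L)) {
    if (is.na(ax[l]) || is.na(ay[l])) next
    M[, l] <- jacquardCellProbs(c(ax[l], bx[l]), c(ay[l], by[l]),
                                freqOf(freqs[[l]]$freq))
  }
  M[, !is.na(M[1, ]), drop = FALSE]
}

# EM on the identity-state simplex (9 states, or 3 when inbred states are
# excluded); multi-start
dyadMLFit <- function(M, nStarts = 5, tol = 1e-8, maxIter = 2000) {
  ns <- nrow(M)
  if (!ncol(M)) return(list(delta = rep(NA_real_, ns), converged = FALSE))
  M <- pmax(M, 1e-300)
  best <- NULL
  starts <- c(list(rep(1 / ns, ns)),
              lapply(seq_len(nStarts - 1), function(s) {
                d <- stats::rgamma(ns, 1); d / sum(d)
              }))
  for (d0 in starts) {
    d <- d0; llOld <- -Inf; conv <- FALSE
    for (it in seq_len(maxIter)) {
      W <- M * d                      # 9 x L
      cs <- colSums(W)
      ll <- sum(log(cs))
      post <- sweep(W, 2, cs, "/")
      d <- rowMeans(post)
      if (abs(ll - llOld) < tol) { conv <- TRUE; break }
      llOld <- ll
    }
    if (is.null(best) || ll > best$ll) best <- list(delta = d, ll = ll,
                                                    converged = conv)
  }
  best
}

deltaToTheta <- function(d) d[1] + 0.5 * (d[3] + d[5] + d[7]) + 0.25 * d[8]
deltaToFx <- function(d) sum(d[1:4])
deltaToFy <- function(d) d[1] + d[2] + d[5] + d[6]
# Wright's correlation form: reduces to 2*theta for non-inbred dyads and
# keeps duplicated (fully identical) genotypes at r = 1
deltaToR <- function(d) {
  2 * deltaToTheta(d) / sqrt((1 + deltaToFx(d)) * (1 + deltaToFy(d)))
}

# ---- pairwise estimators ----------------------------------------------------

# Queller-Goodnight, ratio of sums over loci, symmetrized
qgPair <- function(ax, bx, ay, by, freqs) {
  half <- function(a1, a2, c1, c2) {
    num <- den <- 0
    for (l in seq_along(freqs)) {
      if (is.na(a1[l]) || is.na(c1[l])) next
      p <- freqOf(freqs[[l]]$freq)
      pa <- p(a1[l]); pb <- p(a2[l])
      s <- 0.5 * ((a1[l] == c1[l]) + (a1[l] == c2[l]) +
                  (a2[l] == c1[l]) + (a2[l] == c2[l]))
      num <- num + s - pa - pb
      den <- den + 1 + (a1[l] == a2[l]) - pa - pb
    }
    if (den == 0) return(NA_real_)
    num / den
  }
  mean(c(half(ax, bx, ay, by), half(ay, by, ax, bx)), na.rm = TRUE)
}

# Lynch-Ritland, locus-weighted, symmetrized
lrPair <- function(ax, bx, ay, by, freqs) {
  half <- function(a1, a2, c1, c2) {
    num <- den <- 0
    for (l in seq_along(freqs)) {
      if (is.na(a1[l]) || is.na(c1[l])) next
      p <- freqOf(freqs[[l]]$freq)
      pa <- p(a1[l]); pb <- p(a2[l])
      dab <- as.numeric(a1[l] == a2[l])
      W <- ((1 + dab) * (pa + pb) - 4 * pa * pb)
      if (W <= 0) next
      rl <- (pa * ((a2[l] == c1[l]) + (a2[l] == c2[l])) +
             pb * ((a1[l] == c1[l]) + (a1[l] == c2[l])) - 4 * pa * pb) / W
      w <- W / (2 * pa * pb)
      num <- num + w * rl
      den <- den + w
    }
    if (den == 0) return(NA_real_)
    num / den
  }
  mean(c(half(ax, bx, ay, by), half(ay, by, ax, bx)), na.rm = TRUE)
}

# cross-allele IBS similarity moment estimator: E[s] = theta + (1-theta) a2
simPair <- function(ax, bx, ay, by, freqs) {
  num <- den <- 0
  for (l in seq_along(freqs)) {
    if (is.na(ax[l]) || is.na(ay[l])) next
    a2 <- sum(freqs[[l]]$freq^2)
    s <- 0.25 * ((ax[l] == ay[l]) + (ax[l] == by[l]) +
                 (bx[l] == ay[l]) + (bx[l] == by[l]))
    num <- num + s - a2
    den <- den + 1 - a2
  }
  if (den == 0) return(NA_real_)
  2 * num / den
}

mlPair <- function(ax, bx, ay, by, freqs, nStarts = 5, inbreeding = TRUE) {
  M <- jacquardProbMatrix(ax, bx, ay, by, freqs)
  if (!inbreeding) {
    fit <- dyadMLFit(M[7:9, , drop = FALSE], nStarts = nStarts)
    d <- c(rep(0, 6), fit$delta)
  } else {
    fit <- dyadMLFit(M, nStarts = nStarts)
    d <- fit$delta
  }
  list(r = deltaToR(d), fx = deltaToFx(d), fy = deltaToFy(d),
       converged = fit$converged)
}

pairEstimate <- function(ax, bx, ay, by, freqs, method, nStarts = 5,
                         inbreeding = NULL) {
  switch(method,
    queller_goodnight = list(r = qgPair(ax, bx, ay, by, freqs),
                             converged = TRUE),
    lynch_ritland = list(r = lrPair(ax, bx, ay, by, freqs), converged = TRUE),
    similarity = list(r = simPair(ax, bx, ay, by, freqs), converged = TRUE),
    dyad_ml = mlPair(ax, bx, ay, by, freqs, nStarts,
                     inbreeding = isTRUE(inbreeding)),
    trio_ml = mlPair(ax, bx, ay, by, freqs, nStarts,
                     inbreeding = !isFALSE(inbreeding)),
    stop("unknown relatedness method: ", method)
  )
}

#' Pairwise relatedness estimation
#'
#' Estimates relatedness r for every pair of individuals with one of five
#' estimators: the Queller-Goodnight and Lynch-Ritland moment estimators
#' (reference-frequency based, averaged over the two orderings of the
#' pair), a cross-allele IBS similarity moment estimator, and two
#' maximum-likelihood estimators (\code{dyad_ml}, \code{trio_ml}) that
#' maximise the product over loci of the genotype-pair probability over
#' the condensed identity-state coefficients by multi-start EM.
#' \code{trio_ml} uses all nine states (inbred dyads allowed) and reports
#' relatedness in Wright's correlation form
#' r = 2 theta / sqrt((1 + fx)(1 + fy)), which equals 2 theta for
#' non-inbred dyads and 1 for duplicated genotypes; \code{dyad_ml}
#' defaults to the non-inbred three-state likelihood (less small-sample
#' bias when dyads are outbred); both honour an explicit
#' \code{inbreeding} override.  Moment estimates can fall outside [0, 1];
#' likelihood estimates respect the simplex.
#'
#' Allele frequencies default to the full sample, focal pair included.
#'
#' @param table a \linkS4class{GenotypeTable}.
#' @param method one of \code{"queller_goodnight"}, \code{"lynch_ritland"},
#'   \code{"similarity"}, \code{"dyad_ml"}, \code{"trio_ml"}.
#' @param freqs optional allele frequencies (defaults to
#'   \code{alleleFreqs(table)}).
#' @param nStarts EM multi-starts for likelihood methods.
#' @param inbreeding NULL for the per-method default, or TRUE/FALSE to
#'   force the nine-state or three-state likelihood.
#' @param seed optional seed (EM starting points).
#' @return A \linkS4class{RelatednessResult}.
#' @export
estimateRelatedness <- function(table, method = "trio_ml", freqs = NULL,
                                nStarts = 5, inbreeding = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(freqs)) freqs <- alleleFreqs(table)
  n <- nInd(table)
  A <- table@alleleA; B <- table@alleleB
  r <- matrix(NA_real_, n, n, dimnames = list(indNames(table),
                                              indNames(table)))
  cv <- matrix(TRUE, n, n, dimnames = dimnames(r))
  diag(r) <- if (method %in% c("dyad_ml", "trio_ml")) 1 else NA_real_
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    est <- pairEstimate(A[i, ], B[i, ], A[j, ], B[j, ], freqs, method,
                        nStarts, inbreeding)
    r[i, j] <- r[j, i] <- est$r
    cv[i, j] <- cv[j, i] <- isTRUE(est$converged)
    if (!isTRUE(est$converged))
      warning(sprintf("EM not fully converged for pair (%s, %s)",
                      indNames(table)[i], indNames(table)[j]))
  }
  f <- rep(NA_real_, n)
  if (method %in% c("dyad_ml", "trio_ml"))
    f <- inbreedingML(table, freqs)
  names(f) <- indNames(table)
  new("RelatednessResult", estimator = method, r = r, f = f, converged = cv)
}

# per-individual inbreeding by 1-D maximum likelihood:
# P(aa|f) = f p + (1-f) p^2,  P(ab|f) = (1-f) 2 p q
inbreedingML <- function(table, freqs = NULL) {
  if (is.null(freqs)) freqs <- alleleFreqs(table)
  A <- table@alleleA; B <- table@alleleB
  vapply(seq_len(nInd(table)), function(i) {
    ll <- function(f) {
      s <- 0
      for (l in seq_along(freqs)) {
        if (is.na(A[i, l])) next
        p <- freqOf(freqs[[l]]$freq)
        pa <- p(A[i, l])
        if (A[i, l] == B[i, l])
          s <- s + log(max(f * pa + (1 - f) * pa^2, 1e-300))
        else
          s <- s + log(max((1 - f) * 2 * pa * p(B[i, l]), 1e-300))
      }
      s
    }
    stats::optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-8)$maximum
  }, numeric(1))
}

#' Per-individual inbreeding coefficients with class labels
#'
#' Maximum-likelihood inbreeding coefficient per individual (f in [0, 1]),
#' classified with the conventional thresholds: high when f >= 0.25,
#' moderate when 0.125 <= f < 0.25, low otherwise.
#'
#' @param table a \linkS4class{GenotypeTable}.
#' @param method likelihood machinery to use (\code{"trio_ml"} or
#'   \code{"dyad_ml"}; both share the per-individual likelihood).
#' @param freqs optional allele frequencies.
#' @return data.frame: individual, f, class; mean f in attribute
#'   \code{meanF}.
#' @export
estimateInbreeding <- function(table, method = "trio_ml", freqs = NULL) {
  stopifnot(method %in% c("trio_ml", "dyad_ml"))
  f <- inbreedingML(table, freqs)
  cls <- ifelse(f >= 0.25, "high", ifelse(f >= 0.125, "moderate", "low"))
  out <- data.frame(individual = indNames(table), f = f, class = cls,
                    row.names = NULL)
  attr(out, "meanF") <- mean(f)
  out
}

# ---- dyad simulation and estimator selection --------------------------------

relationshipK <- list(
  full_sib  = c(0.25, 0.5, 0.25),
  half_sib  = c(0.5, 0.5, 0),
  cousin    = c(0.75, 0.25, 0),
  unrelated = c(1, 0, 0)
)

relationshipR <- c(full_sib = 0.5, half_sib = 0.25, cousin = 0.125,
                   unrelated = 0)

#' Simulate genotype dyads of known relationship
#'
#' For each dyad and locus the identity-by-descent pattern is drawn from
#' the relationship's k-coefficients (full sibs (0.25, 0.5, 0.25), half
#' sibs (0.5, 0.5, 0), first cousins (0.75, 0.25, 0), unrelated
#' (1, 0, 0)); non-IBD alleles are filled i.i.d. from the supplied
#' frequencies.
#'
#' @param freqs per-locus allele frequencies (observed or synthetic).
#' @param classes relationship classes to simulate.
#' @param nPerClass dyads per class.
#' @param seed optional integer seed.
#' @return list: \code{class}, \code{trueR}, allele matrices \code{ax},
#'   \code{bx}, \code{ay}, \code{by} (dyads x loci), and the realised
#'   per-locus IBD counts \code{ibdCount}.
#' @export
simulateDyads <- function(freqs, classes = names(relationshipK),
                          nPerClass = 2000, seed = NULL) {
  bad <- setdiff(classes, names(relationshipK))
  if (length(bad)) stop("unknown relationship class: ",
                        paste(bad, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  L <- length(freqs)
  nTot <- nPerClass * length(classes)
  ax <- bx <- ay <- by <- matrix(NA_integer_, nTot, L,
                                 dimnames = list(NULL, names(freqs)))
  ibdCount <- matrix(NA_integer_, nTot, L)
  cls <- rep(classes, each = nPerClass)
  draw <- function(l, n) {
    sizes <- as.integer(names(freqs[[l]]$freq))
    sizes[sample.int(length(sizes), n, replace = TRUE,
                     prob = freqs[[l]]$freq)]
  }
  for (l in seq_len(L)) {
    for (ci in seq_along(classes)) {
      k <- relationshipK[[classes[ci]]]
      rows <- (ci - 1) * nPerClass + seq_len(nPerClass)
      ibd <- sample(0:2, nPerClass, replace = TRUE, prob = k)
      a1 <- draw(l, nPerClass); a2 <- draw(l, nPerClass)
      c1 <- draw(l, nPerClass); c2 <- draw(l, nPerClass)
      # ibd = 1: y's first allele copies x's first; ibd = 2: both copied
      c1[ibd >= 1] <- a1[ibd >= 1]
      c2[ibd == 2] <- a2[ibd == 2]
      ax[rows, l] <- pmin(a1, a2); bx[rows, l] <- pmax(a1, a2)
      ay[rows, l] <- pmin(c1, c2); by[rows, l] <- pmax(c1, c2)
      ibdCount[rows, l] <- ibd
    }
  }
  list(class = cls, trueR = unname(relationshipR[cls]),
       ax = ax, bx = bx, ay = ay, by = by, ibdCount = ibdCount)
}

#' Evaluate estimators on simulated dyads and select one
#'
#' Runs each estimator on the same simulated dyads and reports, per
#' estimator and relationship class, the mean estimate, bias, variance and
#' mean squared error against the true relatedness; the selected estimator
#' minimises the MSE pooled over classes (the operational reading of
#' "minimum variation from the true value").
#'
#' @param dyads output of \code{\link{simulateDyads}}.
#' @param freqs the frequencies the dyads were simulated from.
#' @param methods estimators to compare.
#' @param nStarts EM multi-starts for likelihood methods.
#' @return list: \code{report} (data.frame estimator x class), \code{pooled}
#'   (data.frame estimator / pooled MSE), \code{selected}.
#' @export
selectEstimator <- function(dyads, freqs,
                            methods = c("queller_goodnight",
                                        "lynch_ritland", "similarity"),
                            nStarts = 5) {
  stopifnot(length(methods) >= 2)
  n <- length(dyads$class)
  rows <- list(); pooled <- list()
  for (m in methods) {
    est <- vapply(seq_len(n), function(i)
      pairEstimate(dyads$ax[i, ], dyads$bx[i, ], dyads$ay[i, ],
                   dyads$by[i, ], freqs, m, nStarts)$r, numeric(1))
    for (cl in unique(dyads$class)) {
      sel <- dyads$class == cl
      err <- est[sel] - dyads$trueR[sel]
      rows[[paste(m, cl)]] <- data.frame(
        estimator = m, class = cl, trueR = dyads$trueR[sel][1],
        mean = mean(est[sel], na.rm = TRUE),
        bias = mean(err, na.rm = TRUE),
        variance = stats::var(est[sel], na.rm = TRUE),
        mse = mean(err^2, na.rm = TRUE))
    }
    pooled[[m]] <- data.frame(estimator = m,
                              mse = mean((est - dyads$trueR)^2,
                                         na.rm = TRUE))
  }
  report <- do.call(rbind, rows); rownames(report) <- NULL
  pooled <- do.call(rbind, pooled); rownames(pooled) <- NULL
  list(report = report, pooled = pooled,
       selected = pooled$estimator[which.min(pooled$mse)])
}

setMethod("show", "RelatednessResult", function(object) {
  n <- nrow(object@r)
  up <- object@r[upper.tri(object@r)]
  cat("Pairwise relatedness (", object@estimator, "), ", n,
      " individuals\n", sep = "")
  if (length(up))
    cat(sprintf("  mean r = %.3f, max r = %.3f\n",
                mean(up, na.rm = TRUE), max(up, na.rm = TRUE)))
  if (!all(is.na(object@f)))
    cat(sprintf("  mean inbreeding f = %.4f\n", mean(object@f, na.rm = TRUE)))
})
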