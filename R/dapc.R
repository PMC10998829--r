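# individuals x (locus:allele) 0/1/2 dosage matrix; missing -> column mean
alleleDosage <- function(table) {
  reg <- alleleRegistry(table)
  A <- table@alleleA; B <- table@alleleB
  cols <- list()
  for (l in seq_len(nLoc(table))) {
    for (s in reg[[l]]) {
      v <- (A[, l] == s) + (B[, l] == s)
      cols[[paste0(lociNames(table)[l], ".", s)]] <- v
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- indNames(table)
  for (j in seq_len(ncol(X))) {
    m <- is.na(X[, j])
    if (any(m)) X[m, j] <- mean(X[, j], na.rm = TRUE)
  }
  X
}

ldaFit <- function(scores, grp, ridge = FALSE) {
  if (ridge) {
    # nudge within-group covariance when singular
    scores <- scores + matrix(stats::rnorm(length(scores), sd = 1e-6),
                              nrow(scores))
  }
  MASS::lda(scores, grouping = grp)
}

#' Cross-validated choice of retained principal components for DAPC
#'
#' For each candidate number of retained PCs: repeated stratified hold-out
#' (default 90/10, 30 replicates) of PCA followed by linear discriminant
#' analysis, recording the assignment success of held-out individuals.
#' The best count has the highest mean success; ties break by the lowest
#' mean squared error (mean of (1 - success)^2 over replicates).
#'
#' @param table a \linkS4class{GenotypeTable}.
#' @param groups factor (or coercible) of group labels per individual.
#' @param candidatePcs candidate retained-PC counts.
#' @param trainFrac training fraction per replicate.
#' @param reps hold-out replicates per candidate.
#' @param seed optional integer seed.
#' @return list: \code{bestPcs}, and \code{table} (data.frame nPcs /
#'   meanSuccess / mse / note).
#' @export
dapcCrossval <- function(table, groups, candidatePcs = NULL,
                         trainFrac = 0.9, reps = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grp <- factor(groups)
  stopifnot(nlevels(grp) >= 2, all(table(grp) >= 2))
  X <- alleleDosage(table)
  n <- nrow(X)
  if (is.null(candidatePcs))
    candidatePcs <- seq(2, min(20, n - 2), by = 1)
  res <- lapply(candidatePcs, function(np) {
    succ <- numeric(reps); usable <- TRUE
    for (r in seq_len(reps)) {
      tr <- unlist(lapply(levels(grp), function(g) {
        idx <- which(grp == g)
        ntr <- max(1, floor(length(idx) * trainFrac))
        sample(idx, ntr)
      }))
      te <- setdiff(seq_len(n), tr)
      if (!length(te)) te <- sample(tr, max(1, round(n * (1 - trainFrac))))
      if (np >= length(tr) || np > min(dim(X)) ) { usable <- FALSE; break }
      pc <- stats::prcomp(X[tr, , drop = FALSE], center = TRUE)
      np2 <- min(np, ncol(pc$x))
      sTr <- pc$x[, seq_len(np2), drop = FALSE]
      sTe <- scale(X[te, , drop = FALSE], center = pc$center,
                   scale = FALSE) %*% pc$rotation[, seq_len(np2), drop = FALSE]
      fit <- tryCatch(MASS::lda(sTr, grouping = grp[tr]),
                      error = function(e) NULL)
      if (is.null(fit)) { succ[r] <- NA; next }
      pred <- stats::predict(fit, sTe)$class
      succ[r] <- mean(pred == grp[te])
    }
    if (!usable)
      return(data.frame(nPcs = np, meanSuccess = NA_real_, mse = NA_real_,
                        note = "skipped: >= training sample size"))
    data.frame(nPcs = np, meanSuccess = mean(succ, na.rm = TRUE),
               mse = mean((1 - succ)^2, na.rm = TRUE), note = "")
  })
  tab <- do.call(rbind, res)
  ok <- which(!is.na(tab$meanSuccess))
  if (!length(ok)) stop("no usable candidate PC count")
  best <- ok[order(-tab$meanSuccess[ok], tab$mse[ok], tab$nPcs[ok])][1]
  list(bestPcs = tab$nPcs[best], table = tab)
}

#' Discriminant analysis of principal components
#'
#' PCA dimension reduction followed by linear discriminant analysis
#' between predefined groups; returns individual coordinates on the
#' discriminant axes and group centroids for scatterplots.  A singular
#' within-group covariance triggers a tiny ridge perturbation with a
#' warning.
#'
#' @param table a \linkS4class{GenotypeTable}.
#' @param groups factor of group labels.
#' @param nPca retained principal components (e.g. from
#'   \code{\link{dapcCrossval}}).
#' @param nDa discriminant axes (at most groups - 1).
#' @return list of class \code{"DAPCModel"}: \code{scores} (individuals x
#'   nDa), \code{centroids}, \code{groups}, \code{nPca}, \code{nDa},
#'   \code{assignments} (re-assigned group per individual), \code{propCorrect}.
#' @export
dapcFit <- function(table, groups, nPca, nDa = NULL) {
  grp <- factor(groups)
  if (is.null(nDa)) nDa <- nlevels(grp) - 1L
  stopifnot(nDa <= nlevels(grp) - 1L)
  X <- alleleDosage(table)
  stopifnot(nPca <= nrow(X) - 1)
  pc <- stats::prcomp(X, center = TRUE)
  nPca <- min(nPca, ncol(pc$x))
  S <- pc$x[, seq_len(nPca), drop = FALSE]
  fit <- tryCatch(MASS::lda(S, grouping = grp), error = function(e) {
    warning("singular within-group covariance; applying ridge fallback")
    ldaFit(S, grp, ridge = TRUE)
  })
  sc <- stats::predict(fit, S)
  scores <- sc$x[, seq_len(min(nDa, ncol(sc$x))), drop = FALSE]
  centroids <- apply(scores, 2, function(v) tapply(v, grp, mean))
  structure(list(scores = scores, centroids = centroids, groups = grp,
                 nPca = nPca, nDa = ncol(scores),
                 assignments = sc$class,
                 propCorrect = mean(sc$class == grp), lda = fit),
            class = "DAPCModel")
}

#' @export
print.DAPCModel <- function(x, ...) {
  cat("DAPC model:", x$nPca, "PCs,", x$nDa, "discriminant axes,",
      nlevels(x$groups), "groups\n")
  cat(sprintf("  training reassignment success: %.1f%%\n",
              100 * x$propCorrect))
  invisible(x)
}
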