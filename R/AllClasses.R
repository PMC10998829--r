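#' @import methods
NULL

#' Diploid microsatellite genotypes for a set of individuals
#'
#' The central container of the package: an individuals x loci table of
#' unordered diploid allele-size pairs (fragment sizes in base pairs), with
#' explicit missing cells and per-individual metadata (population label,
#' source sample ids).  Allele pairs are stored sorted so that
#' \code{alleleA <= alleleB}; a missing genotype has \code{NA} in both
#' matrices.
#'
#' @slot alleleA integer matrix (individuals x loci), smaller allele of each
#'   pair, \code{NA} when the cell is untyped.
#' @slot alleleB integer matrix, larger allele; missing exactly where
#'   \code{alleleA} is.
#' @slot pop character vector of population labels, one per individual
#'   (\code{NA} allowed).
#' @slot metadata list of free-form per-table metadata (e.g. the source
#'   sample ids behind each consolidated individual).
#'
#' @export
setClass("GenotypeTable",
  representation(
    alleleA = "matrix",
    alleleB = "matrix",
    pop = "character",
    metadata = "list"
  )
)

setValidity("GenotypeTable", function(object) {
  a <- object@alleleA; b <- object@alleleB
  msg <- character()
  if (!all(dim(a) == dim(b)))
    msg <- c(msg, "alleleA and alleleB dimensions differ")
  if ((nrow(a) > 0 && is.null(rownames(a))) ||
      (ncol(a) > 0 && is.null(colnames(a))))
    msg <- c(msg, "allele matrices must carry individual and locus names")
  if (anyDuplicated(rownames(a)))
    msg <- c(msg, "individual names must be unique")
  if (anyDuplicated(colnames(a)))
    msg <- c(msg, "locus names must be unique")
  if (length(object@pop) != nrow(a))
    msg <- c(msg, "pop must have one entry per individual")
  if (!all(is.na(a) == is.na(b)))
    msg <- c(msg, "half-missing genotypes are not allowed")
  ok <- !is.na(a)
  if (any(a[ok] <= 0 | b[ok] <= 0))
    msg <- c(msg, "allele sizes must be positive integers")
  if (any(a[ok] > b[ok]))
    msg <- c(msg, "allele pairs must be stored sorted (alleleA <= alleleB)")
  if (length(msg)) msg else TRUE
})

#' Replicate PCR allele calls prior to consensus
#'
#' Raw per-replicate genotype calls, one row per (sample, locus, replicate).
#' A failed amplification is recorded with \code{NA} alleles; it is a
#' replicate that produced no call, not a homozygote.
#'
#' @slot calls data.frame with columns \code{sample}, \code{locus},
#'   \code{replicate}, \code{allele1}, \code{allele2}.
#'
#' @export
setClass("ReplicateCalls", representation(calls = "data.frame"))

setValidity("ReplicateCalls", function(object) {
  d <- object@calls
  need <- c("sample", "locus", "replicate", "allele1", "allele2")
  if (!all(need %in% names(d)))
    return(paste("calls must have columns:", paste(need, collapse = ", ")))
  key <- paste(d$sample, d$locus, d$replicate)
  if (anyDuplicated(key))
    return("duplicate (sample, locus, replicate) rows")
  if (!all(is.na(d$allele1) == is.na(d$allele2)))
    return("half-called replicates are not allowed")
  TRUE
})

#' Fitted Bayesian admixture model for one K
#'
#' Posterior summaries from the Gibbs sampler: admixture proportions Q,
#' per-cluster allele frequencies P, and the data log-likelihood trace.
#'
#' @slot K integer, number of clusters.
#' @slot Q numeric matrix (individuals x K) of posterior-mean admixture
#'   proportions; rows sum to 1.
#' @slot P list over loci; each element a K x (alleles at locus) matrix of
#'   posterior-mean cluster allele frequencies, columns named by allele size.
#' @slot logLik numeric, mean data log-likelihood over post-burn-in sweeps.
#' @slot logLikVar numeric, variance of the post-burn-in log-likelihood
#'   trace (STRUCTURE's deviance correction uses mean - var/2).
#' @slot settings list: burnin, reps, alpha posterior mean, seed, thin.
#'
#' @export
setClass("ClusterModel",
  representation(
    K = "integer",
    Q = "matrix",
    P = "list",
    logLik = "numeric",
    logLikVar = "numeric",
    settings = "list"
  )
)

setValidity("ClusterModel", function(object) {
  msg <- character()
  if (ncol(object@Q) != object@K)
    msg <- c(msg, "Q must have K columns")
  if (any(abs(rowSums(object@Q) - 1) > 1e-9))
    msg <- c(msg, "Q rows must sum to 1")
  if (!is.finite(object@logLik))
    msg <- c(msg, "log-likelihood must be finite")
  if (length(msg)) msg else TRUE
})

#' Linkage-disequilibrium effective population size estimate
#'
#' @slot r2 weighted mean Burrows composite r-squared across comparisons.
#' @slot expR2 expected sampling r-squared E[r2|S] for the harmonic mean
#'   sample size.
#' @slot S harmonic mean sample size over locus-pair comparisons.
#' @slot nComparisons number of allele-pair comparisons used.
#' @slot ne point estimate of effective size (\code{Inf} when the observed
#'   r2 does not exceed its sampling expectation).
#' @slot ciParam parametric (chi-square) 95 percent confidence interval.
#' @slot ciJack jackknife-over-loci 95 percent confidence interval.
#' @slot pcrit minimum allele frequency admitted to the calculation.
#'
#' @export
setClass("NeEstimate",
  representation(
    r2 = "numeric", expR2 = "numeric", S = "numeric",
    nComparisons = "numeric", ne = "numeric",
    ciParam = "numeric", ciJack = "numeric", pcrit = "numeric"
  )
)

#' Pairwise relatedness / inbreeding estimates
#'
#' @slot estimator estimator name.
#' @slot r symmetric matrix of pairwise relatedness estimates.
#' @slot f per-individual inbreeding coefficients (likelihood estimators
#'   only; NA vector for moment estimators).
#' @slot converged logical matrix of optimizer convergence flags (likelihood
#'   estimators; all TRUE for moment estimators).
#'
#' @export
setClass("RelatednessResult",
  representation(
    estimator = "character",
    r = "matrix",
    f = "numeric",
    converged = "matrix"
  )
)

setValidity("RelatednessResult", function(object) {
  r <- object@r
  if (nrow(r) != ncol(r)) return("r must be square")
  if (max(abs(r - t(r)), na.rm = TRUE) > 1e-8) return("r must be symmetric")
  TRUE
})

#' Configuration of the individual-based viability simulation
#'
#' Demographic rates, genetic-load parameters and run settings for
#' \code{\link{runPVA}}.  The shipped defaults are a documented placeholder
#' parameterisation for a large solitary felid (see the methods vignette);
#' supply empirically derived rates for real forecasts.
#'
#' @slot initialSize founding population size.
#' @slot initialComposition data.frame(sex, age) for the founders; empty
#'   means a stable-age, even-sex composition is constructed.
#' @slot ageFirstRepro age (years) of first reproduction, per sex
#'   (named c(F=,M=)).
#' @slot maxBreedAge maximum breeding age (both sexes).
#' @slot maxLifespan maximum lifespan; individuals die on reaching it.
#' @slot pctFemalesBreeding probability an eligible adult female breeds in a
#'   given year.
#' @slot litterSizeProbs probabilities of litter sizes 1..n given breeding.
#' @slot sexRatioMale probability a newborn is male.
#' @slot mortality named numeric: firstYear, subadult, adult annual
#'   mortality probabilities.
#' @slot K carrying capacity (individuals); \code{Inf} disables truncation.
#' @slot LE lethal equivalents per diploid genome.
#' @slot pLethal fraction of LE due to recessive lethal alleles (the rest
#'   acts on first-year survival as exp(-(1-pLethal)*LE*F)).
#' @slot F0 founder inbreeding coefficient.
#' @slot k0 founder pairwise kinship.
#' @slot horizon years simulated.
#' @slot iterations replicate trajectories.
#' @slot evSD named numeric: optional environmental SD on breeding
#'   probability and mortality rates (0 = off).
#'
#' @export
setClass("PVAConfig",
  representation(
    initialSize = "integer",
    initialComposition = "data.frame",
    ageFirstRepro = "numeric",
    maxBreedAge = "integer",
    maxLifespan = "integer",
    pctFemalesBreeding = "numeric",
    litterSizeProbs = "numeric",
    sexRatioMale = "numeric",
    mortality = "numeric",
    K = "numeric",
    LE = "numeric",
    pLethal = "numeric",
    F0 = "numeric",
    k0 = "numeric",
    horizon = "integer",
    iterations = "integer",
    evSD = "numeric"
  )
)

setValidity("PVAConfig", function(object) {
  msg <- character()
  pr <- c(object@pctFemalesBreeding, object@sexRatioMale, object@mortality,
          object@pLethal, object@F0, object@k0)
  if (any(pr < 0 | pr > 1)) msg <- c(msg, "probabilities must lie in [0, 1]")
  if (object@LE < 0) msg <- c(msg, "LE must be >= 0")
  if (object@K < 0) msg <- c(msg, "K must be >= 0")
  if (object@horizon < 1L || object@iterations < 1L)
    msg <- c(msg, "horizon and iterations must be >= 1")
  if (abs(sum(object@litterSizeProbs) - 1) > 1e-9)
    msg <- c(msg, "litterSizeProbs must sum to 1")
  if (!all(c("firstYear", "subadult", "adult") %in% names(object@mortality)))
    msg <- c(msg, "mortality needs firstYear, subadult, adult entries")
  if (length(msg)) msg else TRUE
})

#' Result of a viability simulation
#'
#' @slot years data.frame per simulated year: \code{year}, \code{meanN},
#'   \code{sdN}, \code{lo95}, \code{hi95} (2.5/97.5 percentiles over
#'   iterations) and \code{survival} (proportion of iterations extant).
#' @slot pExtinct probability of extinction by the horizon.
#' @slot meanFinalExtant mean final size among extant iterations (NA when
#'   none survive).
#' @slot medianTimeToExtinction median extinction year among extinct
#'   iterations (NA when none go extinct).
#' @slot finalSizes final population size of each iteration.
#' @slot seed integer seed the run used.
#'
#' @export
setClass("PVAResult",
  representation(
    years = "data.frame",
    pExtinct = "numeric",
    meanFinalExtant = "numeric",
    medianTimeToExtinction = "numeric",
    finalSizes = "numeric",
    seed = "integer"
  )
)

setValidity("PVAResult", function(object) {
  s <- object@years$survival
  if (any(diff(s) > 1e-12))
    return("survival probability must be non-increasing in year")
  if (any(object@years$meanN < 0)) return("population sizes must be >= 0")
  TRUE
})
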