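#' Carrying capacity from habitat density and area
#'
#' K = density x area / 100, rounded to the nearest integer (half up),
#' for densities quoted per 100 km2.
#'
#' @param density individuals per 100 km2.
#' @param area habitat area in km2.
#' @return integer carrying capacity.
#' @export
computeK <- function(density, area) {
  stopifnot(density > 0, area > 0)
  as.integer(floor(density * area / 100 + 0.5))
}

#' Build a viability-simulation configuration
#'
#' All arguments have defaults forming a documented placeholder
#' parameterisation for a large solitary felid (see the methods vignette);
#' forecasts for a real population require empirically derived rates.
#' Litter sizes are 1..length(litterSizeProbs) cubs with the given
#' probabilities, conditional on a female breeding that year.
#'
#' @param initialSize founding population size.
#' @param initialComposition optional data.frame(sex, age); when omitted,
#'   founders are adults spread evenly over the breeding ages with
#'   alternating sex.
#' @param ageFirstRepro named c(F=, M=) ages of first reproduction.
#' @param maxBreedAge maximum breeding age.
#' @param maxLifespan maximum lifespan (death on reaching it).
#' @param pctFemalesBreeding probability an eligible female breeds per year.
#' @param litterSizeProbs litter-size distribution given breeding.
#' @param sexRatioMale probability a newborn is male.
#' @param mortality named c(firstYear=, subadult=, adult=) annual
#'   mortality probabilities.
#' @param K carrying capacity (Inf disables ceiling truncation).
#' @param LE lethal equivalents per diploid genome.
#' @param pLethal fraction of LE due to recessive lethal alleles.
#' @param F0 founder inbreeding coefficient.
#' @param k0 founder pairwise kinship.
#' @param horizon years simulated.
#' @param iterations replicate trajectories.
#' @param evSD named c(breeding=, mortality=): SD of annual normal
#'   perturbations of the breeding probability and mortality rates
#'   (0 = environmental variation off).
#' @return A \linkS4class{PVAConfig}.
#' @export
pvaConfig <- function(initialSize = 30,
                      initialComposition = NULL,
                      ageFirstRepro = c(F = 3, M = 4),
                      maxBreedAge = 15,
                      maxLifespan = 17,
                      pctFemalesBreeding = 0.5,
                      litterSizeProbs = c(0.2, 0.4, 0.3, 0.1),
                      sexRatioMale = 0.5,
                      mortality = c(firstYear = 0.4, subadult = 0.15,
                                    adult = 0.1),
                      K = 164,
                      LE = 6.26,
                      pLethal = 0.5,
                      F0 = 0.0868,
                      k0 = 0.0868,
                      horizon = 100,
                      iterations = 1000,
                      evSD = c(breeding = 0, mortality = 0)) {
  if (is.null(initialComposition))
    initialComposition <- data.frame(sex = character(0), age = integer(0))
  new("PVAConfig",
      initialSize = as.integer(initialSize),
      initialComposition = initialComposition,
      ageFirstRepro = ageFirstRepro,
      maxBreedAge = as.integer(maxBreedAge),
      maxLifespan = as.integer(maxLifespan),
      pctFemalesBreeding = pctFemalesBreeding,
      litterSizeProbs = litterSizeProbs / sum(litterSizeProbs),
      sexRatioMale = sexRatioMale,
      mortality = mortality,
      K = as.numeric(K),
      LE = LE,
      pLethal = pLethal,
      F0 = F0, k0 = k0,
      horizon = as.integer(horizon),
      iterations = as.integer(iterations),
      evSD = evSD)
}

#' Seed founders with recessive lethal alleles
#'
#' Infinite-loci model: each founder receives a Poisson(pLethal x LE)
#' count of globally unique recessive lethal allele ids, so the mean
#' lethal-equivalents-from-lethals per founder genome equals
#' pLethal x LE; an offspring inheriting two copies of one id dies in its
#' first year.
#'
#' @param nFounders number of founders.
#' @param LE lethal equivalents per diploid genome.
#' @param pLethal fraction of LE that is recessive lethal.
#' @param seed optional integer seed.
#' @return list of integer vectors (lethal allele ids per founder).
#' @export
assignFounderLethals <- function(nFounders, LE, pLethal, seed = NULL) {
  stopifnot(LE >= 0, pLethal >= 0, pLethal <= 1)
  if (!is.null(seed)) set.seed(seed)
  counts <- stats::rpois(nFounders, pLethal * LE)
  ids <- if (sum(counts)) seq_len(sum(counts)) else integer(0)
  split(ids, rep.int(seq_len(nFounders), counts))[
    as.character(seq_len(nFounders))] |>
    lapply(function(v) if (is.null(v)) integer(0) else as.integer(v))
}

#' Append an offspring to a kinship matrix
#'
#' k(new, z) = (k(dam, z) + k(sire, z)) / 2 for every existing z, and
#' k(new, new) = (1 + k(dam, sire)) / 2; the offspring's inbreeding
#' coefficient is k(dam, sire).
#'
#' @param K kinship matrix of the existing individuals.
#' @param dam,sire row indices of the parents.
#' @return list: \code{K} (augmented matrix), \code{F} (offspring
#'   inbreeding coefficient).
#' @export
kinshipAddOffspring <- function(K, dam, sire) {
  n <- nrow(K)
  newRow <- 0.5 * (K[dam, ] + K[sire, ])
  Fo <- K[dam, sire]
  K2 <- rbind(cbind(K, newRow), c(newRow, 0.5 * (1 + Fo)))
  rownames(K2) <- colnames(K2) <- NULL
  list(K = K2, F = Fo)
}

# age-class mortality lookup (age 0 = first year)
mortalityOf <- function(age, cfg, perturb = 0) {
  m <- ifelse(age == 0, cfg@mortality["firstYear"],
              ifelse(age < min(cfg@ageFirstRepro), cfg@mortality["subadult"],
                     cfg@mortality["adult"]))
  pmin(pmax(m + perturb, 0), 1)
}

# one replicate trajectory; uses the current RNG stream
simulateOnce <- function(cfg) {
  n0 <- cfg@initialSize
  if (nrow(cfg@initialComposition)) {
    sex <- as.character(cfg@initialComposition$sex)
    age <- as.integer(cfg@initialComposition$age)
    n0 <- length(sex)
  } else {
    sex <- rep(c("F", "M"), length.out = n0)
    ages <- seq(min(cfg@ageFirstRepro), cfg@maxBreedAge)
    age <- rep(ages, length.out = n0)
  }
  Fv <- rep(cfg@F0, n0)
  Kin <- matrix(cfg@k0, n0, n0)
  diag(Kin) <- 0.5 * (1 + cfg@F0)
  lethals <- assignFounderLethals(n0, cfg@LE, cfg@pLethal)
  nextLethal <- if (length(unlist(lethals))) max(unlist(lethals)) + 1L else 1L

  Ntraj <- integer(cfg@horizon)
  extinctYear <- NA_integer_
  for (yr in seq_len(cfg@horizon)) {
    n <- length(sex)
    if (n == 0 || !any(sex == "F") || !any(sex == "M")) {
      if (is.na(extinctYear)) extinctYear <- yr
    }
    # --- breeding
    newSex <- character(0); newAge <- integer(0); newF <- numeric(0)
    newLeth <- list(); newDam <- integer(0); newSire <- integer(0)
    if (is.na(extinctYear)) {
      pb <- cfg@pctFemalesBreeding
      if (cfg@evSD["breeding"] > 0)
        pb <- min(max(stats::rnorm(1, pb, cfg@evSD["breeding"]), 0), 1)
      females <- which(sex == "F" & age >= cfg@ageFirstRepro["F"] &
                         age <= cfg@maxBreedAge)
      males <- which(sex == "M" & age >= cfg@ageFirstRepro["M"] &
                       age <= cfg@maxBreedAge)
      if (length(females) && length(males)) {
        for (d in females) {
          if (stats::runif(1) >= pb) next
          s <- males[sample.int(length(males), 1)]
          litter <- sample.int(length(cfg@litterSizeProbs), 1,
                               prob = cfg@litterSizeProbs)
          for (cub in seq_len(litter)) {
            newSex <- c(newSex,
                        if (stats::runif(1) < cfg@sexRatioMale) "M" else "F")
            newAge <- c(newAge, 0L)
            newF <- c(newF, Kin[d, s])
            inh <- c(lethals[[d]][stats::runif(length(lethals[[d]])) < 0.5],
                     lethals[[s]][stats::runif(length(lethals[[s]])) < 0.5])
            newLeth[[length(newLeth) + 1L]] <- inh
            newDam <- c(newDam, d); newSire <- c(newSire, s)
          }
        }
      }
    }
    nNew <- length(newSex)
    if (nNew) {
      Kin2 <- matrix(0, n + nNew, n + nNew)
      Kin2[seq_len(n), seq_len(n)] <- Kin
      for (j in seq_len(nNew)) {
        d <- newDam[j]; s <- newSire[j]
        idx <- n + j
        prev <- seq_len(idx - 1)
        row <- 0.5 * (Kin2[d, prev] + Kin2[s, prev])
        Kin2[idx, prev] <- row
        Kin2[prev, idx] <- row
        Kin2[idx, idx] <- 0.5 * (1 + Kin2[d, s])
      }
      Kin <- Kin2
      sex <- c(sex, newSex); age <- c(age, newAge); Fv <- c(Fv, newF)
      lethals <- c(lethals, newLeth)
      n <- n + nNew
    }
    # --- mortality
    if (n) {
      perturb <- if (cfg@evSD["mortality"] > 0)
        stats::rnorm(1, 0, cfg@evSD["mortality"]) else 0
      mort <- mortalityOf(age, cfg, perturb)
      firstYear <- age == 0
      surv <- 1 - mort
      surv[firstYear] <- surv[firstYear] *
        exp(-(1 - cfg@pLethal) * cfg@LE * Fv[firstYear])
      homoLethal <- vapply(lethals, anyDuplicated, integer(1)) > 0
      surv[firstYear & homoLethal] <- 0
      alive <- stats::runif(n) < surv
      # --- aging and senescence
      age <- age + 1L
      alive <- alive & age < cfg@maxLifespan
      # --- carrying capacity truncation
      nAlive <- sum(alive)
      if (is.finite(cfg@K) && nAlive > cfg@K) {
        excess <- (nAlive - cfg@K) / nAlive
        alive[alive] <- stats::runif(nAlive) >= excess
      }
      keep <- which(alive)
      sex <- sex[keep]; age <- age[keep]; Fv <- Fv[keep]
      lethals <- lethals[keep]
      Kin <- Kin[keep, keep, drop = FALSE]
    }
    if (length(sex) == 0 || !any(sex == "F") || !any(sex == "M")) {
      if (is.na(extinctYear)) extinctYear <- yr
    }
    Ntraj[yr] <- length(sex)
  }
  list(N = Ntraj, extinctYear = extinctYear)
}

#' Run the individual-based viability simulation
#'
#' Simulates replicate population trajectories under the annual cycle
#' breeding -> mortality -> aging -> carrying-capacity truncation, with
#' pedigree-tracked kinship, inbreeding depression of first-year survival
#' (exp(-(1 - pLethal) x LE x F) heterosis component) and unique recessive
#' lethal alleles (homozygotes die).  Extinction is the absence of either
#' sex.  A fixed seed gives a bit-identical result.
#'
#' @param config a \linkS4class{PVAConfig}.
#' @param seed optional integer seed.
#' @return A \linkS4class{PVAResult}.
#' @export
runPVA <- function(config, seed = NULL) {
  validObject(config)
  if (!is.null(seed)) set.seed(seed)
  iters <- config@iterations
  Nmat <- matrix(0L, iters, config@horizon)
  extY <- rep(NA_integer_, iters)
  for (it in seq_len(iters)) {
    r <- simulateOnce(config)
    Nmat[it, ] <- r$N
    extY[it] <- r$extinctYear
  }
  extinctBy <- outer(ifelse(is.na(extY), Inf, extY), seq_len(config@horizon),
                     "<=")
  years <- data.frame(
    year = seq_len(config@horizon),
    meanN = colMeans(Nmat),
    sdN = apply(Nmat, 2, stats::sd),
    lo95 = apply(Nmat, 2, stats::quantile, probs = 0.025),
    hi95 = apply(Nmat, 2, stats::quantile, probs = 0.975),
    survival = 1 - colMeans(extinctBy))
  extant <- is.na(extY)
  new("PVAResult",
      years = years,
      pExtinct = mean(!extant),
      meanFinalExtant = if (any(extant))
        mean(Nmat[extant, config@horizon]) else NA_real_,
      medianTimeToExtinction = if (any(!extant))
        stats::median(extY[!extant]) else NA_real_,
      finalSizes = Nmat[, config@horizon],
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

setMethod("show", "PVAResult", function(object) {
  h <- nrow(object@years)
  cat("Viability simulation over", h, "years\n")
  cat(sprintf("  P(extinct by year %d) = %.3f\n", h, object@pExtinct))
  cat(sprintf("  survival probability at year %d = %.3f\n", h,
              object@years$survival[h]))
  if (!is.na(object@meanFinalExtant))
    cat(sprintf("  mean final size among extant runs = %.1f\n",
                object@meanFinalExtant))
  if (!is.na(object@medianTimeToExtinction))
    cat(sprintf("  median time to extinction = %d years\n",
                as.integer(object@medianTimeToExtinction)))
})

#' One-factor-at-a-time rescue-scenario sweep
#'
#' Runs the viability simulation per grid value, varying one factor at a
#' time from the base configuration: lethal equivalents, the proportion of
#' breeding females, and the recessive-lethal fraction of the load.
#'
#' @param base a \linkS4class{PVAConfig}.
#' @param LEvalues lethal-equivalent grid.
#' @param femaleRatios breeding-female proportion grid.
#' @param pLethalValues recessive-lethal fraction grid.
#' @param seed optional integer seed (one stream per scenario, derived).
#' @return Long-format data.frame: factor, value, year, survival, meanN,
#'   lo95, hi95.
#' @export
scenarioSweep <- function(base,
                          LEvalues = c(0, 3.14, 6.26, 12.26),
                          femaleRatios = c(0.25, 0.5, 0.75),
                          pLethalValues = c(0.25, 0.5, 0.75),
                          seed = NULL) {
  if (is.null(seed)) seed <- 1L
  grids <- list(LE = LEvalues, femaleRatio = femaleRatios,
                pLethal = pLethalValues)
  out <- list(); sc <- 0L
  for (fac in names(grids)) for (v in grids[[fac]]) {
    sc <- sc + 1L
    cfg <- base
    if (fac == "LE") cfg@LE <- v
    if (fac == "femaleRatio") cfg@pctFemalesBreeding <- v
    if (fac == "pLethal") cfg@pLethal <- v
    res <- runPVA(cfg, seed = seed + 1000L * sc)
    out[[sc]] <- cbind(data.frame(factor = fac, value = v), res@years)
  }
  do.call(rbind, out)
}
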