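# msatpva

Genetic-status assessment and population viability forecasting for small,
isolated wildlife populations typed at microsatellite loci.

Small populations cut off from a larger range — the motivating case is a
cross-border Amur tiger population of a few dozen animals typed
noninvasively from feces — face a twin threat: genetic erosion (low
diversity, tiny effective size, rising inbreeding) and the demographic
consequences of inbreeding depression. Quantifying both requires a long
pipeline, traditionally spread across half a dozen Windows tools. This
package implements that pipeline end to end in R, with seeded synthetic
generators so every stage is testable without any external data:

* **Consensus genotyping** from replicate PCRs (`callConsensus`: homozygote
  accepted at ≥3 occurrences, heterozygote at ≥2), individual
  identification from recaptured samples by the ≤1-allele-mismatch rule
  (`matchIndividuals`), and locus filtering (`filterLoci`).
* **Diversity and exact tests** (`diversitySummary`: Na, Ho, unbiased
  He = (2n/(2n−1))(1 − Σp²), PIC; `fisWC`: Weir–Cockerham f;
  `hweExactTest`: Guo–Thompson-style Monte-Carlo exact Hardy–Weinberg
  probability test; `genotypicLDTest`/`ldAllPairs`: exact genotypic
  disequilibrium).
* **Bayesian admixture clustering** with correlated allele frequencies
  (`fitAdmixture`, Gibbs sampler in C++), Evanno ΔK model selection
  (`evannoDeltaK`), label-switching repair (`alignReplicates`) and
  threshold assignment (`assignClusters`, Q ≥ 0.9).
* **Distances and ordination**: stepwise-weighted Dsw distances
  (`dswMatrix`), neighbor-joining trees (`njTree`, Newick IO), and DAPC
  with cross-validated PC retention (`dapcCrossval`, `dapcFit`).
* **Effective population size** by the single-sample linkage-
  disequilibrium method with Pcrit allele screening, Burrows composite
  disequilibrium, the E[r²|S] sampling correction and parametric plus
  jackknife confidence intervals (`ldNe`, `neRatio`).
* **Relatedness and inbreeding**: Queller–Goodnight, Lynch–Ritland and
  IBS-similarity moment estimators plus dyadic and nine-state
  maximum-likelihood estimators (`estimateRelatedness`), simulation-based
  estimator selection over full-sib/half-sib/cousin/unrelated dyads
  (`simulateDyads`, `selectEstimator`), and per-individual inbreeding with
  the conventional f ≥ 0.25 / 0.125 class thresholds
  (`estimateInbreeding`).
* **Population viability analysis**: an individual-based annual-cycle
  simulation with exact pedigree kinship, inbreeding depression of
  first-year survival split into heterosis and recessive-lethal
  (infinite-loci) components, carrying-capacity truncation, and
  one-factor-at-a-time rescue sweeps over lethal equivalents
  {0, 3.14, 6.26, 12.26}, breeding-female ratios {25, 50, 75}% and
  recessive-lethal fractions (`pvaConfig`, `runPVA`, `scenarioSweep`,
  `computeK`).
* **Formats**: GenePop read/write (3-digit codes, missing = `000000`),
  replicate-call TSV, Newick.

## Worked example

Simulate a noninvasively sampled cohort — 12 true individuals, 4 of them
recaptured (16 samples), four replicate PCRs with 20% allelic dropout —
then run the genetic-status stages:

```r
library(msatpva)

fr    <- genAlleleFreqs(14, 4, seed = 7)          # 14 loci, 4 alleles each
truth <- sampleHWGenotypes(fr, 12, seed = 8)
sel   <- c(1:12, 1:4)                             # 4 recaptures
a <- truth@alleleA[sel, ]; b <- truth@alleleB[sel, ]
rownames(a) <- rownames(b) <- sprintf("S%02d", seq_along(sel))

rc   <- addReplicateNoise(genotypeTable(a, b), dropout = 0.2,
                          falseAllele = 0.01, failRate = 0.05, seed = 9)
cons <- callConsensus(rc)                         # 3x hom / 2x het rule
ids  <- matchIndividuals(cons)                    # collapse recaptures
ids$table
#> GenotypeTable: 12 individuals x 14 loci
#>   missing cells: 8.3%
```

The 16 samples collapse back to the 12 true individuals. Diversity,
effective size and inbreeding:

```r
round(diversitySummary(ids$table)$means, 3)
#>    Na    Ho    He   PIC
#> 3.643 0.623 0.673 0.581

ldNe(ids$table)
#> LD effective population size (Pcrit = 0.02 )
#>   mean r2 = 0.144484 (E[r2|S] = 0.136020, S = 10.0, 1156 comparisons)
#>   Ne = 34.6
#>   95% CI (parametric): 12.7 - Inf

round(attr(estimateInbreeding(ids$table), "meanF"), 3)
#> [1] 0.049
```

Mean allele count ≈ 3.6 and He ≈ 0.67 reflect the simulated panel; the Ne
estimate is wide and upward-drifting because these 12 individuals are an
unstructured Hardy–Weinberg draw (no drift signal) — on drifted
Wright–Fisher cohorts the estimator recovers the true size (see the
methods vignette). The mean inbreeding estimate on this outbred cohort,
0.049, illustrates the small upward fold-bias of a [0,1]-constrained
estimator at 14 loci.

A viability forecast under inbreeding depression, and its rescue lever:

```r
base <- pvaConfig(horizon = 100, iterations = 1000)   # LE = 6.26 default
runPVA(base, seed = 1)                                # placeholder demography
sw <- scenarioSweep(base, seed = 1)                   # LE / female / lethal grids
```

`pvaConfig()` ships a documented placeholder demography for a large
solitary felid; survival probabilities are comparable across scenarios,
not to published forecasts, until empirical rates are supplied.

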