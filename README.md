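# occmap

One-class SVM analysis of case-control regional brain morphometry, with
RBF-preimage discriminative maps and matched-pair permutation inference.

## What problem this solves, and for whom

Binary classifiers trained to separate patients from controls conflate two
questions: *are the classes separable?* and *which class carries the common
structure?* In heterogeneous conditions - e.g. neurodevelopmental cohorts
where controls span a wide cognitive range - a one-class classifier (OCC)
answers the second question directly: it learns a boundary around a single
*target* class and tests whether the other class falls outside it. Comparing
case-trained and control-trained descriptions shows which group is the
coherent one.

`occmap` is for researchers with per-subject regional morphometry tables
(the tab-separated exports of cortical-surface pipelines: Area, Volume,
Thickness, Thickness SD and Mean Curvature for the 62 DKT cortical regions,
plus per-hemisphere totals - 314 features) and case/control metadata (sex,
age in months, non-verbal IQ). A synthetic cohort generator with the same
file dialect makes the entire pipeline testable without clinical data.

## The method

* **ν-one-class SVM** (dual: minimize ½ αᵀKα with 0 ≤ αᵢ ≤ 1/(νN),
  Σαᵢ = 1; RBF kernel k(x,x′) = exp(−γ‖x−x′‖²)), solved by a compiled
  SMO solver; the equivalent SVDD (minimal enclosing hypersphere,
  C = 1/(νN)) is also provided. ν bounds the training outlier fraction
  above and the support-vector fraction below.
* **Leave-pair-out cross-validation** over age/NVIQ-matched case-control
  units (optimal assignment matching; 21/20 strata give 19 pairs + one
  triplet), with optional nested (γ, ν) grid optimization
  (γ ∈ 2⁻¹⁵…2³; ν coarse in [0.01, 0.5], fine in [0.01, 0.3]), AUC via the
  exact Mann-Whitney statistic, overall and within NVIQ strata.
* **Preimage maps**: the boundary's weight vector is pulled back to input
  space by multi-start fixed-point iteration; each component of the
  preimage z corresponds to one (hemisphere, region, measure) feature.
* **Matched-pair permutation inference**: within-unit label swaps give the
  null for both the cross-validated AUC and each |z| component; features
  with p < 0.05 are reported region-by-measure with case-vs-control
  sign-trend arrows.

See `vignette("occ-morphometry-maps")` for the model, the design decisions
and the generator's scope.

## Worked example

```r
library(occmap)

sc <- cohortScenario("effectRecovery", seed = 1)   # 40 cases vs 40 controls,
cohort <- simulateCohort(sc$config, sc$effects)    # 10 planted features
partition <- matchPairs(subjectTable(cohort), "pooled")
partition
#> MatchedPartition (stratum: pooled)
#>   M = 40 units: 40 pairs, 0 triplet(s); 80 subjects

cv <- runOneClassCV(cohort, partition, targetClass = "case")  # nu=0.1, heuristic gamma
cvAuc(cv)
#> [1] 1

map <- preimageSignificance(cohort, partition, nPermutations = 500, seed = 2)
map
#> SignificanceMap: 314 features, 20 significant at alpha = 0.05
#>   permutations: 500 valid of 500 (nu = 0.1, gamma = 0.003185, target = case)
head(makeRegionReport(map), 3)[, 1:4]
#>   hemisphere                  region Area Volume
#> 1         lh caudalanteriorcingulate    ↑
#> 2         lh     caudalmiddlefrontal    ↑
#> 3         lh                  cuneus    ↑
```

The AUC is the probability that a random case scores more case-like than a
random control under leave-pair-out CV (0.5 = chance). The significance map
retains the features whose preimage component exceeds its matched-pair
permutation null; arrows mark whether the feature trends up or down in
cases. On this synthetic cohort the planted Area effects (6 up, 4 down in
left-hemisphere regions) dominate the report.

A full run - validation, matching, CV, AUC permutation test, map, report,
manifest - from one configuration:

```r
res <- runFullAnalysis(runConfig(synthetic = sc$config, effects = sc$effects,
                                 nPermutations = 500, seed = 1,
                                 outDir = "occmap_run"))
```

A thin command-line wrapper ships in `inst/scripts/occmap.R`
(`Rscript occmap.R run --config run.yaml`).

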