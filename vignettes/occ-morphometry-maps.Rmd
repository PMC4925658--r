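---
title: "One-class SVM analysis of regional brain morphometry: model, inference and design notes"
author: "occmap maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-class SVM analysis of regional brain morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occmap)
```

## The problem

Case-control neuroimaging studies usually train a *binary* classifier to
separate patients from controls. When one of the two classes is intrinsically
heterogeneous - as is common when controls span a wide cognitive range, or
when the patient group mixes etiologies - the binary decision boundary is
driven by whichever class happens to be messier. One-class classification
(OCC, also called data description or novelty detection) asks a different
question: *can a single class be described by a compact boundary, such that
members of the other class fall outside it?* Trained on class A and tested on
both classes, an OCC model measures the internal coherence of A relative to
B; comparing the A-trained and B-trained directions reveals which class
carries the common structure.

`occmap` implements this analysis for regional brain-morphometry feature
tables: per-subject vectors of cortical Area (mm²), Volume (mm³), Thickness
(mm), Thickness SD (mm) and integrated rectified Mean Curvature (mm⁻¹) over
the 62 cortical regions of the DKT parcellation (31 per hemisphere), plus
per-hemisphere total white-surface area and mean thickness - 314 features in
the full layout. Subjects carry group, sex, age (months) and non-verbal IQ
(NVIQ) metadata; NVIQ < 70 defines the developmental-delay (DD) subgroup.

## The model

### ν-one-class SVM

Given N target-class examples $x_i$ mapped by a kernel feature map $\phi$,
the single-class SVM places a hyperplane separating the data from the origin
with maximal margin:

$$\min_{w,\xi,\rho} \; \tfrac12\|w\|^2 + \tfrac{1}{\nu N}\sum_i \xi_i - \rho
\quad \text{s.t.} \quad w\cdot\phi(x_i) \ge \rho - \xi_i,\; \xi_i \ge 0 .$$

Its dual is the quadratic program
$\min_\alpha \tfrac12 \sum_{ij}\alpha_i\alpha_j k(x_i,x_j)$ subject to
$0 \le \alpha_i \le 1/(\nu N)$ and $\sum_i \alpha_i = 1$, solved here by
SMO-style maximal-violating-pair coordinate updates (compiled; tolerance
$10^{-6}$ on the KKT gap, at most $10^5$ iterations). The decision value of
a point is $\sum_i \alpha_i k(x_i, x) - \rho$, positive for target-like
points. $\rho$ is the mean of $\sum_j \alpha_j k(x_j, x_s)$ over margin
support vectors; when every $\alpha$ sits at a bound, the midpoint of the
interval bracketed by the bound groups is used. $\nu \in (0,1]$ upper-bounds
the fraction of training points left outside the boundary and lower-bounds
the support-vector fraction (verified as a property test).

With the RBF kernel $k(x,x') = \exp(-\gamma\|x-x'\|^2)$ this is equivalent
to the support vector data description (the minimal enclosing hypersphere)
at $C = 1/(\nu N)$: the linear term of the SVDD dual is constant on the
simplex, so the two argmins coincide exactly - `fitSVDD()` exists both as a
user-facing model and as a structural cross-check.

### Standardization

Feature units span nine orders of magnitude (white-surface area ~8·10⁴ mm²
vs mean curvature ~0.14 mm⁻¹), so unscaled RBF distances would be dominated
by area/volume features. Every model therefore z-scores features. *Which*
statistics are used depends on the stage:

* **Cross-validation**: each fold standardizes with the training
  *target-class* statistics and applies them unchanged to the held-out unit,
  so no test information leaks into training (verified by a test that
  mutates held-out rows and observes only their own scores change).
* **Preimage maps**: the observed and all permutation maps are standardized
  with the pooled statistics of *all* subjects. These are invariant under
  matched-unit relabeling, which puts every map on one common scale. A
  per-target-set standardizer would center each map near zero and make
  |z|-comparisons across permutations meaningless for mean-shift effects.

### Matched units, LPO-CV and nested optimization

Cases and controls are paired by minimum-cost assignment on standardized
(age, NVIQ) Euclidean distance (Jonker-Volgenant; deterministic). If cases
outnumber controls by one, the surplus case joins the pair whose control is
nearest, giving one triplet - e.g. a 21/20 stratum yields 19 pairs plus one
triplet, M = 20 units. Leave-pair-out cross-validation (LPO-CV) holds out
one unit per fold, trains the OCC on the target-class members of the rest,
and scores both subjects of the held-out unit; each subject is scored
exactly once. Performance is the AUC of the out-of-fold scores (exactly the
Mann-Whitney statistic, ties counted ½; an exact brute-force oracle backs
this in the tests).

Kernel parameters are either fixed (ν = 0.1 with the heuristic
γ = 1/#features) or tuned per outer fold by two sequential inner LPO-CV
sweeps over the training units only: γ over 19 powers of two from $2^{-15}$
to $2^{3}$, refined by 9 points spanning ±1 in log₂ at step 0.25 around the
coarse optimum (the refinement rule is this package's choice; a bounded,
deterministic bracket); then ν over 10 values in [0.01, 0.5] and 20 in
[0.01, 0.3]. Ties break toward the smaller parameter for reproducibility.
The inner loops re-standardize per inner fold, keeping the leakage policy
identical at both levels. The two-class reference SVM (via `e1071`/libsvm)
follows the same contract with a cost grid $2^{-5}..2^{15}$ - that grid is
this package's own choice of a standard span, not a reproduction of any
published grid.

### RBF preimage maps

Under a non-linear kernel the weight vector $w = \sum_i \alpha_i\phi(x_i)$
lives in feature space; to read per-feature contributions it is pulled back
to input space by the classical fixed-point iteration

$$z \leftarrow \frac{\sum_i \alpha_i e^{-\gamma\|z-x_i\|^2} x_i}
                    {\sum_i \alpha_i e^{-\gamma\|z-x_i\|^2}},$$

whose iterates are convex combinations of the support vectors (so every
component of $z$ stays inside the componentwise SV hull - a tested
invariant). The iteration map has multiple basins, so it is multi-started:
from the α-weighted SV mean and, by default, 5 additional starts at support
vectors sampled proportionally to α (the toolbox this procedure originates
from does not document its policy; multi-start is this package's decision,
with tolerance $10^{-8}$ on the step norm and at most $10^4$ iterations,
both far below the map's resolution and cheap relative to the permutation
cost). A step that decreases the objective $\sum_i \alpha_i k(x_i, z)$ or
underflows the denominator aborts that start; the best start by final
objective wins. Each component of $z$ corresponds to one named feature, so
$z$ is reported as a map over (hemisphere, region, measure), both
standardized and back-transformed to native units.

### Matched-pair permutation inference

The exchangeable null swaps case/control labels independently within each
matched unit with probability ½ (in a triplet the control exchanges with one
of the two cases chosen uniformly), giving $2^M$ equiprobable relabelings
that preserve group sizes and the matching structure. The published
procedure this follows says only that "randomly chosen" cases are exchanged
with their matched controls; the independent-Bernoulli-per-unit rule is the
standard paired-permutation null and the unique exchangeable choice.

* **AUC significance**: each permutation re-runs the complete LPO-CV
  (including nested optimization when the observed run used it) on the
  permuted labels; $p = \#(\mathrm{AUC}_{null} > \mathrm{AUC}_{obs})/B$,
  the raw counting convention, with the add-one corrected value
  $(\#+1)/(B+1)$ reported alongside for statistical hygiene.
* **Map significance**: the observed map comes from a model trained on the
  full target class at fixed ν = 0.1 and heuristic γ; each permutation
  refits and recomputes the preimage on its artificial target set at the
  same fixed parameters (this asymmetry - nested optimization for the AUC
  null, fixed parameters for the map null - mirrors the two published
  procedures being emulated). Feature k gets
  $p_k = \#(|z_k^{null}| > |z_k^{obs}|)/B$; features with $p_k < \alpha$
  (default 0.05) are retained and annotated with the sign of the
  case-control mean difference (mean difference is the implemented default;
  the sign-trend source statistic was not specified in the emulated
  procedure). No multiple-testing correction is applied to the primary
  report, matching the emulated retention rule; a Benjamini-Hochberg column
  is emitted for users who want it. Permutations whose preimage fails to
  converge are resampled once and otherwise dropped with a denominator
  adjustment (warning above 1%). Every permutation's random stream derives
  from (seed, permutation index), so results are independent of batching.

## The synthetic cohort generator

No clinical data ship with the package; `simulateCohort()` generates
cohorts with the statistical structure the analysis assumes, and the writers
emit exactly the TSV dialect the readers parse (an exact round trip):

* **Covariates**: age ~ 49 ± 13 months and NVIQ a two-component mixture
  (DD ~ 53 ± 10, no-DD ~ 91 ± 14, weight 0.5), truncated to the configured
  ranges ([22, 72] months, [31, 123] NVIQ by default; 41 cases / 40 controls
  by default). Controls copy their matched case's covariates plus a small
  jitter (age SD 2 months, NVIQ SD 3), so the designed pairing is
  recoverable by `matchPairs()` and group marginals match by construction.
  DD status is NVIQ < 70, by definition and not configurable.
* **Features**: multivariate Gaussian with block covariance - the 5
  measures of one region share correlation 0.5 (they describe one
  structure), regions independent; this keeps the generator simple and
  analytically invertible for tests. Case rows receive the planted
  standardized mean shifts and a within-class covariance scale; control
  rows are a DD/no-DD mixture with configurable between-subpopulation
  separation; age/NVIQ can couple linearly into every feature. Values are
  mapped to realistic native units per measure.

What the generator does **not** emulate: spatial smoothness beyond the
region block, scanner/site effects, non-Gaussian tails, longitudinal growth,
and any real anatomical covariance structure. Passing tests therefore show
the *procedure* is correct and calibrated under its own assumptions - not
that any particular clinical effect exists.

### Frozen scenarios

`cohortScenario()` exposes the three study conditions used by the validation
suite (null / effectRecovery / asymmetry; see its help page). Two choices
deserve explanation:

* The **asymmetry** scenario's control heterogeneity (1.75 SD on 60
  features) was calibrated once, over a small design-time grid, so that a
  control-trained description performs at chance (AUC 0.50 ± 0.03 across
  seeds) while the case-trained one discriminates (AUC ≈ 0.89) - the
  qualitative asymmetry the analysis is designed to expose. 200 subjects
  per arm keep the sampling SD of a chance-level AUC near 0.03.
* The **effectRecovery** scenario plants ±2.5 SD shifts on 10 features. A
  design-time power analysis showed the permutation null of a map component
  scales with the planted offset itself (artificial target sets are bimodal
  on affected features), so the map test's detectable-effect threshold at
  40 + 40 subjects is roughly 2 SD; 1.5 SD effects hover at the detection
  boundary. ±2.5 SD demonstrates recovery (AUC > 0.95, ≥ 8/10 features
  flagged, all recovered signs correct) at a magnitude the test can actually
  resolve. Users studying weaker effects should expect the map stage - like
  the procedure it emulates - to be conservative.

## Numerical choices and degenerate inputs

* SMO tolerance $10^{-6}$ (KKT gap), max $10^5$ iterations; dual verified
  against an independent accelerated projected-gradient + KKT-polish oracle
  and an interior-point solver to $10^{-6}$.
* N = 1 target examples are legal: α = [1], ρ = 1, the training point sits
  exactly on the boundary.
* Zero-variance features get unit scale in every standardizer (so constant
  columns are inert, a tested invariant).
* Margin errors are counted at score < −10⁻⁵, matching the solver tolerance.
* Matching ties and SV selection ties resolve by row order; all stochastic
  stages consume seeds derived from (seed, index), making every result
  reproducible bit-for-bit.
* Problem sizes in the validation suite (cohorts of 40-81 subjects at 44
  features for calibration loops, full 314 features for recovery runs, 200
  permutations for calibration and 500 for recovery) were chosen as the
  smallest sizes at which the checked properties are statistically
  meaningful.

## Known limitations

* The preimage is a local fixed point; multi-start mitigates but does not
  guarantee the global optimum (the 2-D grid-search tests bound the gap on
  small instances).
* The map test has limited power for mean shifts below ~2 SD at M = 40
  units, and its null distribution is effect-dependent (see above).
* Raw-count p-values can be exactly 0; the add-one column is the
  statistically safer summary.
* `matchPairs()` supports equal arms or a one-case surplus (pair/triplet
  designs only).
* Only linear and RBF kernels are provided, and no probability calibration
  or feature selection is implemented.

## A minimal run

```{r, eval = FALSE}
sc <- cohortScenario("effectRecovery", seed = 1)
cohort <- simulateCohort(sc$config, sc$effects)
partition <- matchPairs(subjectTable(cohort), "pooled")
cv <- runOneClassCV(cohort, partition, targetClass = "case")
cvAuc(cv)
map <- preimageSignificance(cohort, partition, nPermutations = 500, seed = 2)
makeRegionReport(map)
```

Or end to end from one config: `runFullAnalysis(runConfig(synthetic =
sc$config, effects = sc$effects, nPermutations = 500, seed = 1))`, which
writes the partition, scores, AUC table, null distributions, significance
map, region report and a JSON manifest from which the run is reproducible.
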