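#' Configuration of a synthetic case-control morphometry cohort
#'
#' Describes the composition of a simulated cohort: group sizes, the regional
#' feature layout (number of DKT regions and surface measures, optional global
#' features), the covariate ranges used for age (months) and non-verbal IQ
#' (NVIQ), the male fraction, the fraction of controls belonging to the
#' developmentally-delayed (DD, NVIQ < 70) subpopulation, and the seed.
#' Defaults emulate a preschool case-control study: 41 cases vs 40 controls,
#' ages in [22, 72] months, NVIQ in [31, 123], and a 50/50 DD / no-DD control
#' mixture.
#'
#' @slot nCases,nControls group sizes (>= 1).
#' @slot nRegions total number of cortical regions across both hemispheres
#'   (even, <= 62); region names are taken from the DKT label set.
#' @slot measures surface measures per region, a subset of
#'   `c("Area", "Volume", "Thickness", "ThicknessStd", "MeanCurv")`.
#' @slot includeGlobal add the 4 global features (per-hemisphere white-surface
#'   area and mean thickness).
#' @slot sexRatio fraction of male subjects.
#' @slot ageRangeMonths,nviqRange sampling intervals for age and NVIQ.
#' @slot controlMixtureWeight fraction of subjects drawn from the DD (low
#'   NVIQ) mixture component.
#' @slot seed integer seed; the cohort is a pure function of config + seed.
#' @seealso [cohortConfig()], [simulateCohort()]
#' @export
setClass("CohortConfig",
    representation(
        nCases = "integer", nControls = "integer", nRegions = "integer",
        measures = "character", includeGlobal = "logical",
        sexRatio = "numeric", ageRangeMonths = "numeric",
        nviqRange = "numeric", controlMixtureWeight = "numeric",
        seed = "integer"))

setValidity("CohortConfig", function(object) {
    msg <- character()
    if (object@nCases < 1L) msg <- c(msg, "nCases must be >= 1")
    if (object@nControls < 1L) msg <- c(msg, "nControls must be >= 1")
    if (object@nRegions < 2L || object@nRegions %% 2L != 0L)
        msg <- c(msg, "nRegions must be an even count >= 2")
    if (object@nRegions > 62L)
        msg <- c(msg, "nRegions cannot exceed the 62 DKT regions")
    if (length(object@measures) < 1L ||
        !all(object@measures %in% surfaceMeasures()))
        msg <- c(msg, sprintf("measures must be a nonempty subset of {%s}",
                              paste(surfaceMeasures(), collapse = ", ")))
    if (anyDuplicated(object@measures))
        msg <- c(msg, "measures must be unique")
    for (nm in c("ageRangeMonths", "nviqRange")) {
        r <- slot(object, nm)
        if (length(r) != 2L || any(!is.finite(r)) || r[1L] > r[2L])
            msg <- c(msg, sprintf("%s must be a finite interval [lo, hi]", nm))
    }
    if (object@sexRatio < 0 || object@sexRatio > 1)
        msg <- c(msg, "sexRatio must be in [0, 1]")
    if (object@controlMixtureWeight < 0 || object@controlMixtureWeight > 1)
        msg <- c(msg, "controlMixtureWeight must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Planted effect structure for synthetic cohorts
#'
#' Describes how the case and control feature distributions differ: which
#' features carry a case-vs-control mean shift (in within-group SD units),
#' how tight the case class is relative to the controls, how far apart the
#' two control subpopulations (DD vs no-DD) are, and how strongly age and
#' NVIQ couple linearly into every feature. The all-defaults object is the
#' null cohort: cases and controls identical in law.
#'
#' @slot affectedFeatures integer indices (canonical feature order) of the
#'   features carrying a case mean shift.
#' @slot effectSizes signed shifts, SD units, one per affected feature.
#' @slot caseWithinCovScale multiplier (> 0) on the case within-class
#'   covariance; < 1 makes the case class the more homogeneous one.
#' @slot controlHeterogeneity per-feature standardized separation between the
#'   DD and no-DD control subpopulation means, applied on
#'   `heterogeneityFeatures`.
#' @slot heterogeneityFeatures integer indices of the features on which the
#'   two control subpopulations differ.
#' @slot covariateCoupling length-2 numeric: linear coefficients of
#'   standardized age and NVIQ added to every feature.
#' @seealso [effectSpec()], [generateFeatures()]
#' @export
setClass("EffectSpec",
    representation(
        affectedFeatures = "integer", effectSizes = "numeric",
        caseWithinCovScale = "numeric", controlHeterogeneity = "numeric",
        heterogeneityFeatures = "integer", covariateCoupling = "numeric"))

setValidity("EffectSpec", function(object) {
    msg <- character()
    if (length(object@affectedFeatures) != length(object@effectSizes))
        msg <- c(msg, "affectedFeatures and effectSizes lengths differ")
    if (length(object@effectSizes) && any(!is.finite(object@effectSizes)))
        msg <- c(msg, "effectSizes must be finite")
    if (length(object@caseWithinCovScale) != 1L ||
        !is.finite(object@caseWithinCovScale) || object@caseWithinCovScale <= 0)
        msg <- c(msg, "caseWithinCovScale must be a positive scalar")
    if (length(object@controlHeterogeneity) != 1L ||
        !is.finite(object@controlHeterogeneity) ||
        object@controlHeterogeneity < 0)
        msg <- c(msg, "controlHeterogeneity must be a nonnegative scalar")
    if (length(object@covariateCoupling) != 2L ||
        any(!is.finite(object@covariateCoupling)))
        msg <- c(msg, "covariateCoupling must be two finite numbers")
    if (anyDuplicated(object@affectedFeatures))
        msg <- c(msg, "affectedFeatures must be unique")
    if (length(msg)) msg else TRUE
})

#' Virtual parent of the kernel data-description models
#'
#' Common slots of the nu-one-class SVM and the SVDD: the (standardized)
#' support vectors with their dual coefficients, the kernel specification,
#' the per-feature standardizer learned on the training target class, and
#' solver diagnostics.
#'
#' @slot supportVectors standardized training rows with positive dual
#'   coefficient.
#' @slot alpha dual coefficients of the support vectors (sum to 1).
#' @slot svIndex indices of the support vectors in the training matrix.
#' @slot kernel `"rbf"` or `"linear"`.
#' @slot gamma RBF width (NA for linear kernel).
#' @slot nTrain number of training target examples N.
#' @slot center,scale per-feature standardizer (length 0 when disabled).
#' @slot featureNames training feature names.
#' @slot trainingScores decision values of all N training examples.
#' @slot diagnostics solver iteration count, convergence flag, dual objective.
#' @export
setClass("SupportVectorDescription",
    representation(
        "VIRTUAL",
        supportVectors = "matrix", alpha = "numeric", svIndex = "integer",
        kernel = "character", gamma = "numeric", nTrain = "integer",
        center = "numeric", scale = "numeric", featureNames = "character",
        trainingScores = "numeric", diagnostics = "list"))

#' Fitted nu-one-class SVM
#'
#' Dual solution of the single-class SVM: minimize
#' \eqn{\tfrac12 \sum_{ij} \alpha_i \alpha_j k(x_i, x_j)} subject to
#' \eqn{0 \le \alpha_i \le 1/(\nu N)}, \eqn{\sum_i \alpha_i = 1}, with offset
#' \eqn{\rho} estimated on the margin support vectors. The decision value of
#' a point x is \eqn{\sum_i \alpha_i k(x_i, x) - \rho}: positive means
#' target-like, negative means outlier.
#'
#' @slot nu upper bound on the training margin-error fraction and lower bound
#'   on the support-vector fraction.
#' @slot rho decision offset.
#' @seealso [fitOneClass()], [decisionValues()]
#' @export
setClass("OneClassModel",
    contains = "SupportVectorDescription",
    representation(nu = "numeric", rho = "numeric"))

setValidity("OneClassModel", function(object) {
    msg <- character()
    if (object@nu <= 0 || object@nu > 1) msg <- c(msg, "nu must be in (0, 1]")
    if (!is.finite(object@rho)) msg <- c(msg, "rho must be finite")
    C <- 1 / (object@nu * object@nTrain)
    if (length(object@alpha)) {
        if (any(object@alpha < -1e-8) || any(object@alpha > C + 1e-8))
            msg <- c(msg, "alpha outside [0, 1/(nu N)]")
        if (abs(sum(object@alpha) - 1) > 1e-6)
            msg <- c(msg, "alpha must sum to 1")
    }
    if (nrow(object@supportVectors) != length(object@alpha))
        msg <- c(msg, "supportVectors/alpha mismatch")
    if (length(msg)) msg else TRUE
})

#' Fitted support vector data description (SVDD)
#'
#' Dual solution of the minimal enclosing hypersphere with slack bound C:
#' maximize \eqn{\sum_i \alpha_i k(x_i,x_i) - \sum_{ij} \alpha_i\alpha_j
#' k(x_i,x_j)} subject to \eqn{0 \le \alpha_i \le C}, \eqn{\sum \alpha_i = 1}.
#' The decision value of x is \eqn{R^2 - \|\phi(x) - c\|^2} (positive inside
#' the sphere). With an RBF kernel and \eqn{C = 1/(\nu N)} the solution
#' coincides with the nu-one-class SVM.
#'
#' @slot cost the slack trade-off parameter C (>= 1/N).
#' @slot radius2 squared radius of the description sphere.
#' @slot alphaKalpha the quadratic form \eqn{\alpha' K \alpha} cached for
#'   scoring.
#' @seealso [fitSVDD()]
#' @export
setClass("SVDDModel",
    contains = "SupportVectorDescription",
    representation(cost = "numeric", radius2 = "numeric",
                   alphaKalpha = "numeric"))

setValidity("SVDDModel", function(object) {
    msg <- character()
    if (length(object@alpha)) {
        if (any(object@alpha < -1e-8) ||
            any(object@alpha > object@cost + 1e-8))
            msg <- c(msg, "alpha outside [0, C]")
        if (abs(sum(object@alpha) - 1) > 1e-6)
            msg <- c(msg, "alpha must sum to 1")
    }
    if (length(msg)) msg else TRUE
})

#' Approximate RBF preimage of a one-class boundary
#'
#' Result of the fixed-point iteration approximating the preimage z of the
#' weight vector \eqn{w = \sum_i \alpha_i \phi(x_i)}: each component of z
#' corresponds to one input feature, so z can be read as a per-feature map
#' of the learned description.
#'
#' @slot z preimage on the standardized feature scale.
#' @slot zRaw preimage back-transformed to native units (equals `z` when the
#'   model has no standardizer).
#' @slot converged,nIterations,residual,restartsUsed iteration diagnostics.
#' @slot objective final feature-space objective
#'   \eqn{\sum_i \alpha_i k(x_i, z)}.
#' @slot featureNames canonical feature names aligned with `z`.
#' @seealso [computePreimage()]
#' @export
setClass("PreimageResult",
    representation(
        z = "numeric", zRaw = "numeric", converged = "logical",
        nIterations = "integer", residual = "numeric",
        restartsUsed = "integer", objective = "numeric",
        featureNames = "character"))

setValidity("PreimageResult", function(object) {
    msg <- character()
    if (any(!is.finite(object@z))) msg <- c(msg, "z must be finite")
    if (length(object@residual) == 1L && is.finite(object@residual) &&
        object@residual < 0)
        msg <- c(msg, "residual must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Matched case-control partition
#'
#' The M matched units used both as leave-pair-out cross-validation folds and
#' as label-swap units in permutation inference. Each unit is a pair (one
#' case, one control) or a triplet (two cases, one control).
#'
#' @slot units list; each element is `list(cases = <ids>, controls = <ids>)`.
#' @slot stratum cohort stratum label (`"pooled"`, `"male"`, `"female"`).
#' @slot subjectIds all subject ids, in unit order.
#' @seealso [matchPairs()], [lpoSplits()]
#' @export
setClass("MatchedPartition",
    representation(units = "list", stratum = "character",
                   subjectIds = "character"))

setValidity("MatchedPartition", function(object) {
    msg <- character()
    ids <- unlist(lapply(object@units, unlist), use.names = FALSE)
    if (anyDuplicated(ids))
        msg <- c(msg, "a subject appears in more than one unit")
    ok <- vapply(object@units, function(u) {
        length(u$cases) >= 1L && length(u$controls) >= 1L
    }, logical(1))
    if (!all(ok)) msg <- c(msg, "every unit needs >= 1 case and >= 1 control")
    if (!setequal(ids, object@subjectIds))
        msg <- c(msg, "subjectIds inconsistent with units")
    if (length(msg)) msg else TRUE
})

#' Leave-pair-out cross-validation result
#'
#' Out-of-fold decision scores for every subject of a matched partition,
#' together with the kernel parameters chosen in each fold.
#'
#' @slot scores `DataFrame` with columns subject, group, unit, fold, score.
#'   Scores are target-likeness decision values of the fold's model.
#' @slot foldParams `DataFrame` with columns fold, gamma, nu (or cost for the
#'   two-class reference).
#' @slot targetClass `"case"`, `"control"`, or `"both"` (two-class reference).
#' @slot stratum stratum label inherited from the partition.
#' @slot optimized whether nested parameter optimization was run.
#' @seealso [runOneClassCV()], [cvAuc()]
#' @export
setClass("OneClassCV",
    representation(scores = "DataFrame", foldParams = "DataFrame",
                   targetClass = "character", stratum = "character",
                   optimized = "logical"))

setValidity("OneClassCV", function(object) {
    msg <- character()
    need <- c("subject", "group", "unit", "fold", "score")
    if (!all(need %in% colnames(object@scores)))
        msg <- c(msg, sprintf("scores needs columns {%s}",
                              paste(need, collapse = ", ")))
    else if (anyDuplicated(object@scores$subject))
        msg <- c(msg, "exactly one score per subject required")
    if (length(msg)) msg else TRUE
})

#' Per-feature preimage significance map
#'
#' A `DataFrame` (one row per feature, canonical order) holding the observed
#' preimage component, its matched-pair permutation p-value (raw count /
#' number of permutations, plus the add-one corrected version and a
#' Benjamini-Hochberg column), the significance flag at level alpha, and the
#' case-vs-control sign trend. Permutation settings live in `metadata()`.
#'
#' @seealso [preimageSignificance()], [makeRegionReport()]
#' @export
setClass("SignificanceMap", contains = "DFrame")

setValidity("SignificanceMap", function(object) {
    msg <- character()
    need <- c("featureName", "hemisphere", "region", "measure", "z", "p",
              "pAddOne", "pBH", "significant", "signTrend")
    if (!all(need %in% colnames(object)))
        msg <- c(msg, sprintf("missing columns: %s",
                              paste(setdiff(need, colnames(object)),
                                    collapse = ", ")))
    else {
        if (any(object$p < 0 | object$p > 1))
            msg <- c(msg, "p-values must lie in [0, 1]")
        a <- metadata(object)$alpha
        if (is.numeric(a) && length(a) == 1L &&
            !identical(as.logical(object$p < a), as.logical(object$significant)))
            msg <- c(msg, "significant flag must equal p < alpha")
        if (!all(object$signTrend %in% c("up", "down", "none")))
            msg <- c(msg, "signTrend must be up/down/none")
    }
    if (length(msg)) msg else TRUE
})
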