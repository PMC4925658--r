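#' Decision values of a fitted data-description model
#'
#' For a [OneClassModel-class], the score of x is
#' \eqn{\sum_i \alpha_i k(x_i, x) - \rho}; for a [SVDDModel-class] it is
#' \eqn{R^2 - \|\phi(x) - c\|^2}. Positive scores are target-like, negative
#' scores are outliers. `newdata` is given in native units; the model's
#' standardizer (if any) is applied internally.
#'
#' @param model a fitted [OneClassModel-class] or [SVDDModel-class].
#' @param newdata numeric matrix, subjects x features, native units.
#' @param ... passed to methods.
#' @return numeric vector, one score per row of `newdata`.
#' @export
setGeneric("decisionValues", function(model, newdata, ...)
    standardGeneric("decisionValues"))

#' Accessors for fitted description models
#'
#' `supportVectors` returns the standardized support-vector matrix,
#' `dualCoefs` their dual coefficients (summing to 1), and `kernelGamma`
#' the RBF width.
#'
#' @param object a [OneClassModel-class] or [SVDDModel-class].
#' @return matrix, numeric vector, or scalar respectively.
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
setGeneric("supportVectors", function(object) standardGeneric("supportVectors"))

#' @rdname model-accessors
#' @export
setGeneric("dualCoefs", function(object) standardGeneric("dualCoefs"))

#' @rdname model-accessors
#' @export
setGeneric("kernelGamma", function(object) standardGeneric("kernelGamma"))

#' Accessors for matched partitions
#'
#' `nUnits` returns the number of matched units M; `partitionUnits` the list
#' of units (each `list(cases, controls)` of subject ids).
#'
#' @param object a [MatchedPartition-class].
#' @name partition-accessors
NULL

#' @rdname partition-accessors
#' @export
setGeneric("nUnits", function(object) standardGeneric("nUnits"))

#' @rdname partition-accessors
#' @export
setGeneric("partitionUnits", function(object) standardGeneric("partitionUnits"))

#' Accessors for cross-validation results
#'
#' `cvScores` returns the out-of-fold score table (one row per subject);
#' `cvParams` the per-fold chosen kernel parameters.
#'
#' @param object a [OneClassCV-class].
#' @name cv-accessors
NULL

#' @rdname cv-accessors
#' @export
setGeneric("cvScores", function(object) standardGeneric("cvScores"))

#' @rdname cv-accessors
#' @export
setGeneric("cvParams", function(object) standardGeneric("cvParams"))

#' Approximate preimage of the learned one-class boundary
#'
#' @param model a fitted RBF [OneClassModel-class].
#' @param ... method arguments (tolerance, restarts, seed).
#' @return a [PreimageResult-class].
#' @export
setGeneric("computePreimage", function(model, ...)
    standardGeneric("computePreimage"))
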