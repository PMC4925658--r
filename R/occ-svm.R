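#' RBF kernel Gram matrix
#'
#' \eqn{k(x, x') = \exp(-\gamma \|x - x'\|^2)}: entries lie in (0, 1], the
#' matrix is symmetric with unit diagonal when `x2 = x`. The width gamma
#' controls boundary smoothness; the heuristic default used throughout the
#' package is `1 / ncol(x)` (the inverse of the number of features).
#'
#' @param x,x2 numeric matrices with equal column counts (`x2` defaults to
#'   `x`).
#' @param gamma positive kernel width.
#' @return `nrow(x)` x `nrow(x2)` Gram matrix.
#' @examples
#' rbfKernelMatrix(diag(2), gamma = 0.5)
#' @export
rbfKernelMatrix <- function(x, x2 = x, gamma) {
    x <- as.matrix(x); x2 <- as.matrix(x2)
    if (ncol(x) != ncol(x2))
        stop("dimension mismatch: ", ncol(x), " vs ", ncol(x2), " columns")
    if (!is.finite(gamma) || gamma <= 0) stop("gamma must be > 0")
    cpp_rbf_gram(x, x2, gamma)
}

## Kernel matrix for either supported family.
kernelMatrix2 <- function(x, x2, kernel, gamma) {
    if (kernel == "rbf") cpp_rbf_gram(x, x2, gamma)
    else tcrossprod(x, x2)
}

## Resolve the standardize argument into a standardizer (or NULL).
resolveStandardizer <- function(standardize, x) {
    if (isTRUE(standardize)) fitStandardizer(x)
    else if (is.list(standardize)) {
        stopifnot(all(c("center", "scale") %in% names(standardize)))
        standardize
    } else NULL
}

#' Fit a nu-one-class SVM
#'
#' Solves the dual of the single-class SVM on the target-class examples:
#' minimize \eqn{\tfrac12 \sum_{ij}\alpha_i\alpha_j k(x_i,x_j)} subject to
#' \eqn{0 \le \alpha_i \le 1/(\nu N)}, \eqn{\sum_i\alpha_i = 1}, by SMO-style
#' coordinate-pair optimization (maximal violating pair, tolerance `tol`,
#' at most `maxIter` iterations). The offset \eqn{\rho} is the mean of
#' \eqn{\sum_j \alpha_j k(x_j, x_s)} over margin support vectors
#' (\eqn{0 < \alpha_s < 1/(\nu N)}); if none exist, the midpoint of the
#' admissible interval defined by the bound support vectors. nu is an upper
#' bound on the fraction of training points left outside the boundary and a
#' lower bound on the support-vector fraction.
#'
#' @param x numeric matrix of target-class examples (subjects x features),
#'   native units.
#' @param nu regularization parameter in (0, 1].
#' @param gamma RBF width; `NULL` requests the heuristic `1/ncol(x)`.
#' @param kernel `"rbf"` or `"linear"`.
#' @param standardize `TRUE` to z-score each feature with target-class
#'   training statistics (the default; RBF distances across mm^2 / mm^3 /
#'   mm^-1 units would otherwise be dominated by volume-scale features), a
#'   precomputed `list(center, scale)`, or `FALSE`.
#' @param tol,maxIter SMO stopping tolerance and iteration cap.
#' @return a [OneClassModel-class].
#' @examples
#' x <- matrix(rnorm(60), 20, 3)
#' m <- fitOneClass(x, nu = 0.2)
#' mean(decisionValues(m, x) < 0) <= 0.2  # nu-property
#' @export
fitOneClass <- function(x, nu = 0.1, gamma = NULL,
                        kernel = c("rbf", "linear"), standardize = TRUE,
                        tol = 1e-6, maxIter = 1e5) {
    kernel <- match.arg(kernel)
    x <- as.matrix(x)
    if (!nrow(x)) stop("at least one target example required")
    if (!is.numeric(nu) || length(nu) != 1L || nu <= 0 || nu > 1)
        stop("nu must be in (0, 1]")
    st <- resolveStandardizer(standardize, x)
    xs <- applyStandardizer(x, st)
    if (is.null(gamma)) gamma <- 1 / ncol(x)
    if (kernel == "rbf" && (!is.finite(gamma) || gamma <= 0))
        stop("gamma must be > 0")
    N <- nrow(xs)
    K <- kernelMatrix2(xs, xs, kernel, gamma)
    C <- 1 / (nu * N)
    sol <- cpp_smo_solve(K, numeric(N), C, tol, as.integer(maxIter))
    if (!sol$converged)
        stop("SMO did not converge within ", maxIter, " iterations ",
             "(final iteration count ", sol$iterations, "); ",
             "consider increasing maxIter or tol")
    alpha <- sol$alpha
    Kalpha <- sol$grad   # p = 0, so gradient equals K alpha
    svSel <- alpha > C * 1e-8
    rho <- occRho(Kalpha, alpha, C)
    new("OneClassModel",
        supportVectors = xs[svSel, , drop = FALSE],
        alpha = alpha[svSel], svIndex = which(svSel),
        kernel = kernel, gamma = if (kernel == "rbf") gamma else NA_real_,
        nTrain = N,
        center = if (is.null(st)) numeric(0) else st$center,
        scale = if (is.null(st)) numeric(0) else st$scale,
        featureNames = colnames(x) %||% character(0),
        trainingScores = Kalpha - rho,
        nu = nu, rho = rho,
        diagnostics = list(iterations = sol$iterations,
                           converged = sol$converged,
                           objective = sol$objective))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## rho from the (K alpha) vector: mean over free SVs, else midpoint of the
## admissible interval between the bound groups.
occRho <- function(Kalpha, alpha, C) {
    eps <- C * 1e-7
    free <- alpha > eps & alpha < C - eps
    if (any(free)) return(mean(Kalpha[free]))
    atC <- alpha >= C - eps
    at0 <- alpha <= eps
    lo <- if (any(atC)) max(Kalpha[atC]) else NA_real_
    hi <- if (any(at0)) min(Kalpha[at0]) else NA_real_
    if (is.na(lo)) hi else if (is.na(hi)) lo else (lo + hi) / 2
}

modelStandardizer <- function(model) {
    if (length(model@center))
        list(center = model@center, scale = model@scale)
    else NULL
}

#' @rdname decisionValues
#' @export
setMethod("decisionValues", "OneClassModel", function(model, newdata, ...) {
    newdata <- as.matrix(newdata)
    if (ncol(newdata) != ncol(model@supportVectors))
        stop("newdata has ", ncol(newdata), " features; model expects ",
             ncol(model@supportVectors))
    zs <- applyStandardizer(newdata, modelStandardizer(model))
    K <- kernelMatrix2(zs, model@supportVectors, model@kernel, model@gamma)
    as.vector(K %*% model@alpha) - model@rho
})

#' Fit a support vector data description (SVDD)
#'
#' Minimal enclosing hypersphere around the target class with slack bound C:
#' the dual maximizes \eqn{\sum_i \alpha_i k(x_i,x_i) -
#' \sum_{ij}\alpha_i\alpha_j k(x_i,x_j)} over the same simplex-with-box
#' constraint set, solved with the same SMO core. With an RBF kernel and
#' \eqn{C = 1/(\nu N)} the solution coincides with [fitOneClass()] (identical
#' support vectors; decision values are a monotone transform of each other).
#'
#' @inheritParams fitOneClass
#' @param C slack trade-off; must satisfy `C >= 1/N`.
#' @return a [SVDDModel-class].
#' @export
fitSVDD <- function(x, C, gamma = NULL, kernel = c("rbf", "linear"),
                    standardize = TRUE, tol = 1e-6, maxIter = 1e5) {
    kernel <- match.arg(kernel)
    x <- as.matrix(x)
    N <- nrow(x)
    if (!N) stop("at least one target example required")
    if (!is.numeric(C) || length(C) != 1L || C * N < 1 - 1e-12)
        stop("infeasible slack bound: C must be >= 1/N")
    st <- resolveStandardizer(standardize, x)
    xs <- applyStandardizer(x, st)
    if (is.null(gamma)) gamma <- 1 / ncol(x)
    K <- kernelMatrix2(xs, xs, kernel, gamma)
    sol <- cpp_smo_solve(2 * K, -diag(K), C, tol, as.integer(maxIter))
    if (!sol$converged) stop("SMO did not converge within ", maxIter,
                             " iterations")
    alpha <- sol$alpha
    Kalpha <- as.vector(K %*% alpha)
    aKa <- sum(alpha * Kalpha)
    ## squared distance of training points to the center
    d2 <- diag(K) - 2 * Kalpha + aKa
    eps <- C * 1e-7
    free <- alpha > eps & alpha < C - eps
    radius2 <- if (any(free)) mean(d2[free]) else {
        atC <- alpha >= C - eps; at0 <- alpha <= eps
        lo <- if (any(at0)) max(d2[at0]) else NA_real_  # inside: d2 <= R2
        hi <- if (any(atC)) min(d2[atC]) else NA_real_  # outside: d2 >= R2
        if (is.na(lo)) hi else if (is.na(hi)) lo else (lo + hi) / 2
    }
    svSel <- alpha > C * 1e-8
    new("SVDDModel",
        supportVectors = xs[svSel, , drop = FALSE],
        alpha = alpha[svSel], svIndex = which(svSel),
        kernel = kernel, gamma = if (kernel == "rbf") gamma else NA_real_,
        nTrain = as.integer(N),
        center = if (is.null(st)) numeric(0) else st$center,
        scale = if (is.null(st)) numeric(0) else st$scale,
        featureNames = colnames(x) %||% character(0),
        trainingScores = radius2 - d2,
        cost = C, radius2 = radius2, alphaKalpha = aKa,
        diagnostics = list(iterations = sol$iterations,
                           converged = sol$converged,
                           objective = sol$objective))
}

#' @rdname decisionValues
#' @export
setMethod("decisionValues", "SVDDModel", function(model, newdata, ...) {
    newdata <- as.matrix(newdata)
    zs <- applyStandardizer(newdata, modelStandardizer(model))
    K <- kernelMatrix2(zs, model@supportVectors, model@kernel, model@gamma)
    kxx <- if (model@kernel == "rbf") rep(1, nrow(zs)) else rowSums(zs * zs)
    d2 <- kxx - 2 * as.vector(K %*% model@alpha) + model@alphaKalpha
    model@radius2 - d2
})

#' @rdname model-accessors
#' @export
setMethod("supportVectors", "SupportVectorDescription",
          function(object) object@supportVectors)

#' @rdname model-accessors
#' @export
setMethod("dualCoefs", "SupportVectorDescription",
          function(object) object@alpha)

#' @rdname model-accessors
#' @export
setMethod("kernelGamma", "SupportVectorDescription",
          function(object) object@gamma)

setMethod("show", "OneClassModel", function(object) {
    cat("OneClassModel (nu-one-class SVM)\n",
        "  kernel: ", object@kernel,
        if (object@kernel == "rbf") sprintf(" (gamma = %.4g)", object@gamma),
        "\n  nu: ", object@nu, "   N: ", object@nTrain,
        "   support vectors: ", length(object@alpha),
        "\n  rho: ", format(object@rho, digits = 4),
        "   standardized: ", length(object@center) > 0, "\n", sep = "")
})

setMethod("show", "SVDDModel", function(object) {
    cat("SVDDModel (support vector data description)\n",
        "  kernel: ", object@kernel,
        if (object@kernel == "rbf") sprintf(" (gamma = %.4g)", object@gamma),
        "\n  C: ", format(object@cost, digits = 4), "   N: ", object@nTrain,
        "   support vectors: ", length(object@alpha),
        "\n  squared radius: ", format(object@radius2, digits = 4), "\n",
        sep = "")
})

#' Serialize a fitted model to a JSON text form
#'
#' Writes the dual coefficients, offset, kernel parameters, support vectors
#' and standardizer so the model can be reloaded with [readOneClassModel()].
#'
#' @param model a [OneClassModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeOneClassModel <- function(model, path) {
    obj <- list(class = "OneClassModel", nu = model@nu, rho = model@rho,
                kernel = model@kernel, gamma = model@gamma,
                nTrain = model@nTrain, alpha = model@alpha,
                svIndex = model@svIndex,
                supportVectors = model@supportVectors,
                center = model@center, scale = model@scale,
                featureNames = model@featureNames)
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeOneClassModel
#' @export
readOneClassModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    sv <- matrix(as.numeric(obj$supportVectors), nrow = length(obj$alpha))
    new("OneClassModel", supportVectors = sv,
        alpha = as.numeric(obj$alpha), svIndex = as.integer(obj$svIndex),
        kernel = obj$kernel, gamma = as.numeric(obj$gamma),
        nTrain = as.integer(obj$nTrain),
        center = as.numeric(obj$center), scale = as.numeric(obj$scale),
        featureNames = as.character(obj$featureNames),
        trainingScores = numeric(0), nu = obj$nu, rho = obj$rho,
        diagnostics = list())
}
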