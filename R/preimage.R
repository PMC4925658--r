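## Approximate preimage of the one-class weight vector w = sum_i a_i phi(x_i)
## under the RBF map, by fixed-point iteration:
##   z <- sum_i a_i exp(-g ||z - x_i||^2) x_i / sum_i a_i exp(-g ||z-x_i||^2)
## Because all a_i >= 0, every iterate is a convex combination of the
## support vectors, so z stays inside their componentwise hull. The map has
## multiple basins, so the iteration is multi-started: once from the
## alpha-weighted support-vector mean and `nRestarts` times from individual
## support vectors sampled proportionally to alpha. Among starts, the iterate
## maximizing the feature-space objective sum_i a_i k(x_i, z) is returned.

#' One fixed-point step of the RBF preimage iteration
#'
#' Exposed mainly for inspection and testing; [computePreimage()] runs the
#' full multi-start iteration.
#'
#' @param z current iterate (standardized feature scale).
#' @param model a fitted RBF [OneClassModel-class].
#' @return the next iterate, a convex combination of the support vectors.
#' @export
fixedPointStep <- function(z, model) {
    if (model@kernel != "rbf") stop("preimage iteration requires RBF kernel")
    sv <- model@supportVectors
    if (length(z) != ncol(sv)) stop("z dimension mismatch")
    d2 <- colSums((t(sv) - z)^2)
    w <- model@alpha * exp(-model@gamma * d2)
    if (sum(w) < 1e-300)
        stop("fixed-point denominator underflow: z escaped the data support")
    as.vector(crossprod(sv, w)) / sum(w)
}

#' @rdname computePreimage
#' @details The multi-start fixed-point preimage applies to RBF models; for
#'   a linear kernel the primal weight vector is exact and no iteration is
#'   needed (deliberately unsupported here).
#' @param tol convergence tolerance on the step norm.
#' @param maxIter iteration cap per start.
#' @param nRestarts additional starts from support vectors sampled by alpha
#'   weight (the first start is always the alpha-weighted SV mean).
#' @param seed integer seed controlling restart sampling; fixed seed gives an
#'   identical [PreimageResult-class].
#' @export
setMethod("computePreimage", "OneClassModel",
    function(model, tol = 1e-8, maxIter = 1e4, nRestarts = 5, seed = 1L, ...) {
    if (model@kernel != "rbf") stop("preimage iteration requires RBF kernel")
    sv <- model@supportVectors
    nsv <- nrow(sv)
    starts <- matrix(as.vector(crossprod(sv, model@alpha)) / sum(model@alpha),
                     1L, ncol(sv), byrow = TRUE)
    nRestarts <- min(nRestarts, nsv)
    if (nRestarts > 0) {
        set.seed(as.integer(seed))
        pick <- sample.int(nsv, nRestarts, replace = FALSE,
                           prob = model@alpha)
        starts <- rbind(starts, sv[pick, , drop = FALSE])
    }
    res <- cpp_preimage(sv, model@alpha, model@gamma, starts,
                        tol, as.integer(maxIter))
    if (!res$converged && !any(res$start_converged))
        warning("preimage iteration reached maxIter on every start; ",
                "returning the best iterate (residual ",
                format(res$residual, digits = 3), ")")
    z <- as.numeric(res$z)
    names(z) <- if (length(model@featureNames)) model@featureNames else NULL
    zRaw <- if (length(model@center)) z * model@scale + model@center else z
    new("PreimageResult", z = z, zRaw = zRaw,
        converged = isTRUE(res$converged),
        nIterations = as.integer(res$n_iterations),
        residual = as.numeric(res$residual),
        restartsUsed = as.integer(nrow(starts) - 1L),
        objective = as.numeric(res$objective),
        featureNames = model@featureNames)
})

setMethod("show", "PreimageResult", function(object) {
    cat("PreimageResult\n",
        "  features: ", length(object@z),
        "   converged: ", object@converged,
        " (", object@nIterations, " iterations, residual ",
        format(object@residual, digits = 3), ")\n",
        "  objective sum_i alpha_i k(x_i, z): ",
        format(object@objective, digits = 6), "\n", sep = "")
})
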