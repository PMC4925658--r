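## Matched-pair permutation inference. The exchangeable null swaps case and
## control labels independently within each matched unit (probability 1/2
## per unit; in a triplet the control is exchanged with one of the two cases
## chosen uniformly), giving 2^M equiprobable relabelings that preserve
## group sizes and the matching structure. Each permutation's random stream
## derives from (seed, permutation index), so results do not depend on how
## permutations are batched.

#' Permute group labels within matched units
#'
#' @param partition a [MatchedPartition-class].
#' @param seed integer seed for this draw.
#' @return named character vector: permuted group per subject id.
#' @export
permuteUnitLabels <- function(partition, seed = 1L) {
    set.seed(as.integer(seed))
    units <- partition@units
    M <- length(units)
    doSwap <- runif(M) < 0.5
    pickCase <- runif(M)   # which case enters a swapped triplet
    pickCtrl <- runif(M)
    out <- vector("list", M)
    for (k in seq_len(M)) {
        cases <- units[[k]]$cases; ctrls <- units[[k]]$controls
        lab <- c(rep("case", length(cases)), rep("control", length(ctrls)))
        names(lab) <- c(cases, ctrls)
        if (doSwap[k]) {
            i <- 1L + floor(pickCase[k] * length(cases))
            j <- 1L + floor(pickCtrl[k] * length(ctrls))
            lab[cases[i]] <- "control"
            lab[ctrls[j]] <- "case"
        }
        out[[k]] <- lab
    }
    lab <- unlist(out)
    lab[partition@subjectIds]
}

#' Permutation significance of the cross-validated AUC
#'
#' Builds the null distribution of the LPO-CV AUC by relabeling matched
#' units [nPermutations] times and re-running the complete one-class
#' cross-validation (including nested parameter optimization when the
#' observed analysis used it) on each artificial target class. The p-value
#' is the raw exceedance count divided by the number of permutations (the
#' add-one corrected version is reported alongside).
#'
#' @inheritParams runOneClassCV
#' @param nPermutations number of unit-label permutations.
#' @param seed base seed; permutation b uses a stream derived from
#'   (seed, b).
#' @param observed optionally, a precomputed [OneClassCV-class] with the
#'   identical configuration (it is recomputed when `NULL`).
#' @return `list(pValue, pValueAddOne, observedAuc, nullAuc)`.
#' @export
aucPermutationTest <- function(cohort, partition, targetClass = "case",
                               nPermutations = 10000, seed = 1L, nu = 0.1,
                               gamma = NULL, optimize = FALSE,
                               grid = optGrid(), observed = NULL,
                               tol = 1e-6, maxIter = 1e5) {
    if (nPermutations < 1L) stop("nPermutations must be >= 1")
    if (is.null(observed))
        observed <- runOneClassCV(cohort, partition, targetClass, nu = nu,
                                  gamma = gamma, optimize = optimize,
                                  grid = grid, tol = tol, maxIter = maxIter)
    obsAuc <- cvAuc(observed)
    inp <- cvInputs(cohort, partition)
    nullAuc <- vapply(seq_len(nPermutations), function(b) {
        lab <- permuteUnitLabels(partition, seed = deriveSeed(seed, b))
        lab <- lab[inp$subjects$id]
        core <- occCvCore(inp$X, inp$unit, lab, targetClass, nu, gamma,
                          optimize, grid, tol, maxIter)
        aucOnly(orientScores(core$scores, targetClass), lab)
    }, numeric(1))
    list(pValue = sum(nullAuc > obsAuc) / nPermutations,
         pValueAddOne = (1 + sum(nullAuc > obsAuc)) / (nPermutations + 1),
         observedAuc = obsAuc, nullAuc = nullAuc)
}

## Fit the map-stage one-class model (fixed nu, heuristic gamma, shared
## standardizer) and return the preimage, retrying once on non-convergence.
mapPreimage <- function(X, rows, nu, gamma, st, restartSeed,
                        nRestarts, tol, maxIter) {
    m <- fitOneClass(X[rows, , drop = FALSE], nu = nu, gamma = gamma,
                     standardize = st)
    pre <- suppressWarnings(
        computePreimage(m, tol = tol, maxIter = maxIter,
                        nRestarts = nRestarts, seed = restartSeed))
    if (!pre@converged)
        pre <- suppressWarnings(
            computePreimage(m, tol = tol, maxIter = maxIter,
                            nRestarts = nRestarts,
                            seed = deriveSeed(restartSeed, 104729L)))
    pre
}

#' Per-feature preimage significance map
#'
#' Trains a one-class SVM on the full target class (fixed nu, heuristic or
#' supplied gamma), computes the RBF preimage z of its boundary, and builds
#' a per-feature null by repeating the fit + preimage on
#' matched-unit-permuted target sets. Feature k's p-value is the fraction of
#' permutations whose |z_k| exceeds the observed |z_k|; features with
#' p < alpha are flagged significant and annotated with the sign trend of
#' the case-control mean difference.
#'
#' All maps are computed on a common standardized scale (features z-scored
#' with the pooled statistics of all partition subjects, which are invariant
#' under unit relabeling), so observed and null components are directly
#' comparable.
#'
#' @inheritParams aucPermutationTest
#' @param alpha significance level for the retention flag.
#' @param nRestarts,preTol,preMaxIter multi-start preimage controls (see
#'   [computePreimage()]). Permutations whose preimage fails to converge are
#'   resampled once and otherwise dropped with a denominator adjustment (a
#'   warning reports the count when > 1% fail).
#' @return a [SignificanceMap-class]; permutation settings in `metadata()`.
#' @export
preimageSignificance <- function(cohort, partition, targetClass = "case",
                                 nu = 0.1, gamma = NULL,
                                 nPermutations = 10000, alpha = 0.05,
                                 seed = 1L, nRestarts = 5, preTol = 1e-8,
                                 preMaxIter = 1e4) {
    if (nPermutations < 1L) stop("nPermutations must be >= 1")
    inp <- cvInputs(cohort, partition)
    X <- inp$X
    st <- fitStandardizer(X)          # pooled, permutation-invariant
    if (is.null(gamma)) gamma <- 1 / ncol(X)
    obsRows <- which(inp$subjects$group == targetClass)
    if (!length(obsRows))
        stop("target class '", targetClass, "' absent from the partition")
    obs <- mapPreimage(X, obsRows, nu, gamma, st, deriveSeed(seed, 0L),
                       nRestarts, preTol, preMaxIter)
    zObs <- obs@z
    exceed <- numeric(ncol(X))
    nValid <- 0L
    nFailed <- 0L
    for (b in seq_len(nPermutations)) {
        lab <- permuteUnitLabels(partition, seed = deriveSeed(seed, b))
        rows <- which(lab[inp$subjects$id] == targetClass)
        pre <- mapPreimage(X, rows, nu, gamma, st, deriveSeed(seed, -b),
                           nRestarts, preTol, preMaxIter)
        if (!pre@converged) { nFailed <- nFailed + 1L; next }
        exceed <- exceed + (abs(pre@z) > abs(zObs))
        nValid <- nValid + 1L
    }
    if (nFailed > 0.01 * nPermutations)
        warning(nFailed, " of ", nPermutations,
                " permutation preimages failed to converge and were dropped")
    if (nValid == 0L) stop("no valid permutation preimages")
    p <- exceed / nValid
    idx <- as.data.frame(rowData(cohort))
    idx <- idx[match(colnames(X), idx$featureName), , drop = FALSE]
    df <- DataFrame(featureName = colnames(X),
                    hemisphere = idx$hemisphere, region = idx$region,
                    measure = idx$measure,
                    z = unname(zObs), zRaw = unname(obs@zRaw),
                    p = p, pAddOne = (exceed + 1) / (nValid + 1),
                    pBH = p.adjust(p, "BH"),
                    significant = p < alpha,
                    signTrend = signTrends(X, inp$subjects$group),
                    row.names = colnames(X))
    metadata(df) <- list(alpha = alpha, nPermutations = nPermutations,
                         nValid = nValid, nFailed = nFailed, nu = nu,
                         gamma = gamma, targetClass = targetClass,
                         stratum = partition@stratum, seed = seed)
    new("SignificanceMap", df)
}

#' Case-vs-control sign trend per feature
#'
#' The sign of the case-control difference of feature means; differences
#' below 1e-12 pooled SDs are reported as `"none"`.
#'
#' @param features subjects x features matrix.
#' @param labels group labels per row.
#' @return character vector in `{"up", "down", "none"}`.
#' @export
signTrends <- function(features, labels) {
    isCase <- labels == "case"
    if (!any(isCase) || !all(isCase | labels == "control") || all(isCase))
        stop("both groups must be nonempty")
    mc <- colMeans(features[isCase, , drop = FALSE])
    mk <- colMeans(features[!isCase, , drop = FALSE])
    s <- apply(features, 2L, sd)
    s[!is.finite(s) | s < 1e-12] <- 1
    d <- (mc - mk) / s
    ifelse(abs(d) < 1e-12, "none", ifelse(d > 0, "up", "down"))
}

#' Region-by-measure report of significant features
#'
#' Tabulates the significant features of a [SignificanceMap-class] as one
#' row per (hemisphere, region) with one column per measure carrying an
#' up/down arrow for the case-vs-control trend, sorted by hemisphere then
#' region.
#'
#' @param map a [SignificanceMap-class].
#' @param alpha significance level (defaults to the map's own).
#' @return `data.frame`; zero rows when nothing is significant.
#' @export
makeRegionReport <- function(map, alpha = NULL) {
    if (is.null(alpha)) alpha <- metadata(map)$alpha
    sig <- as.data.frame(map[map$p < alpha, , drop = FALSE])
    measures <- c(surfaceMeasures(), globalMeasures())
    measures <- measures[measures %in% unique(map$measure)]
    if (!nrow(sig)) {
        out <- data.frame(hemisphere = character(0), region = character(0))
        for (m in measures) out[[m]] <- character(0)
        return(out)
    }
    sig$arrow <- ifelse(sig$signTrend == "up", "↑",
                        ifelse(sig$signTrend == "down", "↓", "·"))
    keys <- unique(sig[, c("hemisphere", "region")])
    keys <- keys[order(keys$hemisphere, keys$region), , drop = FALSE]
    out <- data.frame(hemisphere = keys$hemisphere, region = keys$region,
                      stringsAsFactors = FALSE)
    for (m in measures) out[[m]] <- ""
    for (i in seq_len(nrow(sig))) {
        r <- which(out$hemisphere == sig$hemisphere[i] &
                   out$region == sig$region[i])
        out[r, sig$measure[i]] <- sig$arrow[i]
    }
    rownames(out) <- NULL
    out
}

#' Write a significance map and its region report
#'
#' Emits the full per-feature map, the null-exceedance summary and the
#' region-by-measure arrow table as UTF-8 TSV plus a human-readable text
#' rendering.
#'
#' @param map a [SignificanceMap-class].
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
writeSignificanceMap <- function(map, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    mapPath <- file.path(dir, "significance_map.tsv")
    write.table(as.data.frame(map), mapPath, sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
    rep <- makeRegionReport(map)
    repPath <- file.path(dir, "region_report.tsv")
    write.table(rep, repPath, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    txtPath <- file.path(dir, "region_report.txt")
    writeLines(c(sprintf("Significant features at p < %.3g (%d of %d)",
                         metadata(map)$alpha, sum(map$significant),
                         nrow(map)),
                 "", utils::capture.output(print(rep))),
               txtPath, useBytes = FALSE)
    invisible(c(mapPath, repPath, txtPath))
}

setMethod("show", "SignificanceMap", function(object) {
    md <- metadata(object)
    cat("SignificanceMap: ", nrow(object), " features, ",
        sum(object$significant), " significant at alpha = ", md$alpha,
        "\n  permutations: ", md$nValid, " valid of ", md$nPermutations,
        " (nu = ", md$nu, ", gamma = ", format(md$gamma, digits = 4),
        ", target = ", md$targetClass, ")\n", sep = "")
    callNextMethod()
})
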