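## Leave-pair-out cross-validation of one-class and reference two-class
## SVMs over a matched partition, with nested kernel-parameter optimization
## and ROC/AUC evaluation (overall and within covariate-defined subgroups).

#' Kernel-parameter optimization grids
#'
#' The gamma coarse grid has 19 steps from 2^-15 to 2^3 by powers of 2,
#' refined around the coarse optimum with 9 points spanning +-1 in log2 at
#' step 0.25. nu is searched with 10 linearly spaced values in [0.01, 0.5]
#' (coarse) and 20 in [0.01, 0.3] (fine), starting from nu = 0.1. The cost
#' grid for the two-class reference spans 2^-5..2^15 by powers of 2.
#'
#' @param gammaCoarse,nuCoarse,nuFine,costGrid optional overrides (ascending).
#' @param nuInit nu held fixed during the gamma search.
#' @param gammaFineSpan,gammaFineStep log2 half-width and step of the gamma
#'   refinement.
#' @return list of grids used by [nestedOptimize()].
#' @export
optGrid <- function(gammaCoarse = 2^seq(-15, 3, by = 1),
                    nuCoarse = seq(0.01, 0.5, length.out = 10),
                    nuFine = seq(0.01, 0.3, length.out = 20),
                    nuInit = 0.1,
                    gammaFineSpan = 1, gammaFineStep = 0.25,
                    costGrid = 2^seq(-5, 15, by = 1)) {
    stopifnot(!is.unsorted(gammaCoarse), !is.unsorted(nuCoarse),
              !is.unsorted(nuFine), !is.unsorted(costGrid),
              all(gammaCoarse > 0), all(nuCoarse > 0 & nuCoarse <= 1),
              all(nuFine > 0 & nuFine <= 1), nuInit > 0, nuInit <= 1)
    list(gammaCoarse = gammaCoarse, nuCoarse = nuCoarse, nuFine = nuFine,
         nuInit = nuInit, gammaFineSpan = gammaFineSpan,
         gammaFineStep = gammaFineStep, costGrid = costGrid)
}

#' ROC curve and AUC
#'
#' The AUC equals the Mann-Whitney probability that a randomly chosen case
#' scores above a randomly chosen control, ties counted 1/2 (computed
#' exactly via midranks). The ROC is returned as the full step curve over
#' all thresholds.
#'
#' @param scores numeric case-likeness scores.
#' @param labels group labels aligned with `scores`.
#' @param positive label of the positive (case) class.
#' @return `list(auc, roc)`; `roc` is a data.frame with columns threshold,
#'   fpr, tpr.
#' @examples
#' rocAuc(c(3, 2, 1, 2), c("case", "case", "control", "control"))$auc # 0.875
#' @export
rocAuc <- function(scores, labels, positive = "case") {
    keep <- !is.na(scores) & !is.na(labels)
    scores <- scores[keep]; labels <- labels[keep]
    pos <- labels == positive
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L)
        stop("AUC undefined: need both classes, got ", n1, " positive and ",
             n0, " negative")
    r <- rank(scores)                      # midranks handle ties as 1/2
    auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    thr <- sort(unique(scores), decreasing = TRUE)
    tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
    fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
    roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
    list(auc = auc, roc = roc)
}

## ---- internal CV plumbing ------------------------------------------------

## Align a cohort with a partition: features, subjects, unit index.
cvInputs <- function(cohort, partition) {
    X <- featureMatrix(cohort)
    subjects <- subjectTable(cohort)
    miss <- setdiff(partition@subjectIds, rownames(X))
    if (length(miss))
        stop("features missing for partition subject(s): ",
             paste(utils::head(miss, 5L), collapse = ", "))
    ids <- partition@subjectIds
    list(X = X[ids, , drop = FALSE],
         subjects = subjects[ids, , drop = FALSE],
         unit = unitIndexOf(partition, ids))
}

## Case-likeness orientation of raw target-likeness scores.
orientScores <- function(scores, targetClass) {
    if (identical(targetClass, "control")) -scores else scores
}

## Rank-based AUC without the ROC curve, for hot loops (identical value to
## rocAuc()$auc).
aucOnly <- function(scores, labels, positive = "case") {
    pos <- labels == positive
    n1 <- sum(pos); n0 <- length(pos) - n1
    if (n1 == 0L || n0 == 0L) stop("AUC undefined: need both classes")
    (sum(rank(scores)[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

occInnerAuc <- function(X, unit, group, targetClass, nu, gamma,
                        tol = 1e-6, maxIter = 1e5) {
    s <- cpp_occ_cv_scores(X, unit, group == targetClass, nu,
                           if (is.null(gamma)) -1 else gamma,
                           tol, as.integer(maxIter))
    aucOnly(orientScores(s, targetClass), group)
}

#' Nested kernel-parameter optimization by inner leave-pair-out CV
#'
#' Two sequential searches over the training units only: (1) with nu fixed
#' at `grid$nuInit`, gamma is swept over the coarse grid and then a log2
#' refinement around the coarse optimum, keeping the value maximizing the
#' inner-CV AUC; (2) with gamma fixed at that optimum, nu is swept over the
#' coarse then fine grids. Ties break toward the smaller gamma, then the
#' smaller nu.
#'
#' @param X subjects x features matrix (training subjects only).
#' @param unit matched-unit index per row of `X`.
#' @param group group label per row of `X`.
#' @param targetClass `"case"` or `"control"`.
#' @param grid an [optGrid()].
#' @return `list(gamma, nu, trace)`; `trace` records every (parameter, AUC)
#'   pair evaluated.
#' @export
nestedOptimize <- function(X, unit, group, targetClass = "case",
                           grid = optGrid()) {
    if (length(unique(unit[!is.na(unit)])) < 2L)
        stop("nested optimization needs at least 2 training units")
    evalGamma <- function(g) occInnerAuc(X, unit, group, targetClass,
                                         grid$nuInit, g)
    g1 <- vapply(grid$gammaCoarse, evalGamma, numeric(1))
    gBest <- grid$gammaCoarse[which.max(g1)]
    gFine <- 2^(log2(gBest) + seq(-grid$gammaFineSpan, grid$gammaFineSpan,
                                  by = grid$gammaFineStep))
    g2 <- vapply(gFine, evalGamma, numeric(1))
    gAll <- c(grid$gammaCoarse, gFine)
    aAll <- c(g1, g2)
    o <- order(gAll)
    gammaOpt <- gAll[o][which.max(aAll[o])]

    evalNu <- function(nu) occInnerAuc(X, unit, group, targetClass, nu,
                                       gammaOpt)
    nuAll <- c(grid$nuCoarse, grid$nuFine)
    nAll <- vapply(nuAll, evalNu, numeric(1))
    o <- order(nuAll)
    nuOpt <- nuAll[o][which.max(nAll[o])]
    list(gamma = gammaOpt, nu = nuOpt,
         trace = list(gamma = data.frame(gamma = gAll, auc = aAll),
                      nu = data.frame(nu = nuAll, auc = nAll)))
}

#' Leave-pair-out cross-validation of the one-class SVM
#'
#' For each matched unit j, a nu-one-class SVM is trained on the
#' target-class members of all other units (features z-scored with the
#' training target statistics, so no test information enters the fold) and
#' scores the held-out unit's subjects of both classes. With
#' `optimize = TRUE`, (gamma, nu) are tuned per fold by [nestedOptimize()]
#' on the training units only; otherwise the fixed `nu` and heuristic (or
#' supplied) `gamma` are used.
#'
#' @param cohort cohort `SummarizedExperiment`.
#' @param partition a [MatchedPartition-class].
#' @param targetClass class the description is trained on (`"case"` or
#'   `"control"`).
#' @param nu fixed nu (default 0.1) when not optimizing.
#' @param gamma fixed RBF width; `NULL` = heuristic 1/n_features.
#' @param optimize run nested parameter optimization per fold.
#' @param grid an [optGrid()].
#' @param tol,maxIter SMO controls.
#' @return a [OneClassCV-class] with one out-of-fold score per subject.
#' @export
runOneClassCV <- function(cohort, partition, targetClass = c("case",
                          "control"), nu = 0.1, gamma = NULL,
                          optimize = FALSE, grid = optGrid(),
                          tol = 1e-6, maxIter = 1e5) {
    targetClass <- match.arg(targetClass)
    inp <- cvInputs(cohort, partition)
    if (!any(inp$subjects$group == targetClass))
        stop("target class '", targetClass, "' absent from the partition")
    core <- occCvCore(inp$X, inp$unit, inp$subjects$group, targetClass,
                      nu, gamma, optimize, grid, tol, maxIter)
    new("OneClassCV",
        scores = DataFrame(subject = inp$subjects$id,
                           group = inp$subjects$group,
                           unit = inp$unit, fold = inp$unit,
                           score = core$scores),
        foldParams = DataFrame(core$foldParams),
        targetClass = targetClass,
        stratum = partition@stratum, optimized = optimize)
}

## Shared one-class LPO-CV engine; `group` may be a permuted relabeling.
occCvCore <- function(X, unit, group, targetClass, nu, gamma, optimize,
                      grid, tol = 1e-6, maxIter = 1e5) {
    M <- length(unique(unit[!is.na(unit)]))
    heuristic <- 1 / ncol(X)
    if (!optimize) {
        s <- cpp_occ_cv_scores(X, unit, group == targetClass, nu,
                               if (is.null(gamma)) -1 else gamma,
                               tol, as.integer(maxIter))
        fp <- list(fold = seq_len(M),
                   gamma = rep(gamma %||% heuristic, M),
                   nu = rep(nu, M))
    } else {
        s <- rep(NA_real_, nrow(X))
        fp <- list(fold = seq_len(M), gamma = rep(NA_real_, M),
                   nu = rep(NA_real_, M))
        for (j in sort(unique(unit))) {
            tr <- which(unit != j)
            te <- which(unit == j)
            opt <- nestedOptimize(X[tr, , drop = FALSE], unit[tr],
                                  group[tr], targetClass, grid)
            tgt <- tr[group[tr] == targetClass]
            m <- fitOneClass(X[tgt, , drop = FALSE], nu = opt$nu,
                             gamma = opt$gamma, tol = tol, maxIter = maxIter)
            s[te] <- decisionValues(m, X[te, , drop = FALSE])
            fp$gamma[j] <- opt$gamma
            fp$nu[j] <- opt$nu
        }
    }
    list(scores = s, foldParams = fp)
}

#' Leave-pair-out cross-validation of the reference two-class SVM
#'
#' Standard soft-margin binary SVM (linear or RBF kernel) under the same
#' matched-unit LPO-CV contract, providing the baseline against which the
#' one-class results are compared. Features are z-scored per fold with the
#' statistics of all training subjects. With `optimize = TRUE` the cost (and
#' gamma, for RBF) are tuned per fold by an inner LPO-CV over
#' `grid$costGrid` (x `grid$gammaCoarse` for RBF).
#'
#' @inheritParams runOneClassCV
#' @param kernel `"linear"` or `"rbf"`.
#' @param cost fixed soft-margin cost when not optimizing.
#' @return a [OneClassCV-class] with `targetClass = "both"`; scores are
#'   case-likeness decision values.
#' @export
runTwoClassCV <- function(cohort, partition, kernel = c("linear", "rbf"),
                          cost = 1, gamma = NULL, optimize = FALSE,
                          grid = optGrid()) {
    kernel <- match.arg(kernel)
    inp <- cvInputs(cohort, partition)
    X <- inp$X; subjects <- inp$subjects; unit <- inp$unit
    M <- length(partition@units)
    heuristic <- 1 / ncol(X)
    s <- rep(NA_real_, nrow(X))
    fp <- DataFrame(fold = seq_len(M), cost = NA_real_, gamma = NA_real_)
    innerAuc <- function(rows, co, ga) {
        sc <- rep(NA_real_, length(rows))
        for (u in unique(unit[rows])) {
            tr <- rows[unit[rows] != u]
            te <- rows[unit[rows] == u]
            sc[match(te, rows)] <- twoClassScores(X, tr, te,
                                                  subjects$group, kernel,
                                                  co, ga)
        }
        rocAuc(sc, subjects$group[rows])$auc
    }
    for (j in seq_len(M)) {
        tr <- which(unit != j)
        te <- which(unit == j)
        co <- cost; ga <- gamma %||% heuristic
        if (optimize) {
            cand <- if (kernel == "linear")
                data.frame(cost = grid$costGrid, gamma = heuristic)
            else expand.grid(cost = grid$costGrid, gamma = grid$gammaCoarse)
            aucs <- mapply(function(c0, g0) innerAuc(tr, c0, g0),
                           cand$cost, cand$gamma)
            best <- which.max(aucs)
            co <- cand$cost[best]; ga <- cand$gamma[best]
        }
        s[te] <- twoClassScores(X, tr, te, subjects$group, kernel, co, ga)
        fp$cost[j] <- co
        fp$gamma[j] <- if (kernel == "rbf") ga else NA_real_
    }
    new("OneClassCV",
        scores = DataFrame(subject = subjects$id, group = subjects$group,
                           unit = unit, fold = unit, score = s),
        foldParams = fp, targetClass = "both",
        stratum = partition@stratum, optimized = optimize)
}

## Fit e1071::svm on training rows and return case-oriented decision values
## for the test rows.
twoClassScores <- function(X, tr, te, group, kernel, cost, gamma) {
    st <- fitStandardizer(X[tr, , drop = FALSE])
    zs <- applyStandardizer(X[tr, , drop = FALSE], st)
    y <- factor(group[tr], levels = c("case", "control"))
    m <- e1071::svm(zs, y, scale = FALSE, cost = cost,
                    kernel = if (kernel == "rbf") "radial" else "linear",
                    gamma = gamma)
    zt <- applyStandardizer(X[te, , drop = FALSE], st)
    pr <- attr(stats::predict(m, zt, decision.values = TRUE),
               "decision.values")
    dv <- as.numeric(pr[, 1L])
    if (startsWith(colnames(pr)[1L], "control")) dv <- -dv
    dv
}

#' Overall and subgroup AUC of a cross-validation result
#'
#' `cvAuc` computes the case-vs-control AUC from the out-of-fold scores
#' (orienting them so that larger means more case-like, regardless of the
#' trained target class); `subgroupAuc` restricts to the subjects satisfying
#' a predicate - typically an NVIQ stratum - without any refitting.
#'
#' @param cv a [OneClassCV-class].
#' @param subjects subject table covering the CV subjects (needed when
#'   `predicate` is a function of the subject table).
#' @param predicate logical vector aligned with the CV subjects, or a
#'   function of the subject table returning one (e.g.
#'   `function(s) s$nviq >= 70`).
#' @return the AUC (numeric scalar).
#' @export
cvAuc <- function(cv) {
    sc <- cv@scores
    rocAuc(orientScores(sc$score, cv@targetClass), sc$group)$auc
}

#' @rdname cvAuc
#' @export
subgroupAuc <- function(cv, subjects, predicate) {
    sc <- cv@scores
    sub <- subjects[match(sc$subject, subjects$id), , drop = FALSE]
    keep <- if (is.function(predicate)) predicate(sub) else as.logical(predicate)
    if (length(keep) != nrow(sc))
        stop("predicate length does not match the CV subjects")
    if (!any(keep & sc$group == "case") || !any(keep & sc$group == "control"))
        stop("AUC undefined: subgroup must contain both classes")
    rocAuc(orientScores(sc$score[keep], cv@targetClass), sc$group[keep])$auc
}

#' @rdname cv-accessors
#' @export
setMethod("cvScores", "OneClassCV", function(object) object@scores)

#' @rdname cv-accessors
#' @export
setMethod("cvParams", "OneClassCV", function(object) object@foldParams)

setMethod("show", "OneClassCV", function(object) {
    cat("OneClassCV (stratum: ", object@stratum, ", target: ",
        object@targetClass, ", ",
        if (object@optimized) "nested-optimized" else "fixed parameters",
        ")\n  ", nrow(object@scores), " out-of-fold scores over ",
        nrow(object@foldParams), " folds; AUC = ",
        format(cvAuc(object), digits = 3), "\n", sep = "")
})
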