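test_that("rocAuc equals the Mann-Whitney probability with half ties", {
    r <- rocAuc(c(3, 2, 1, 2), c("case", "case", "control", "control"))
    expect_equal(r$auc, 0.875)   # (1 + 1 + 1 + 0.5) / 4
    expect_equal(rocAuc(c(5, 4, 1, 2), rep(c("case", "control"), each = 2))$auc, 1)
    expect_equal(rocAuc(rep(1, 6), rep(c("case", "control"), 3))$auc, 0.5)
    expect_error(rocAuc(1:3, rep("case", 3)), "undefined")
    ## ROC endpoints
    expect_equal(r$roc$fpr[1], 0)
    expect_equal(r$roc$tpr[nrow(r$roc)], 1)
})

test_that("rocAuc matches brute-force pairwise counting on random vectors", {
    set.seed(91)
    for (r in 1:100) {
        n1 <- sample(2:10, 1)
        n0 <- sample(2:10, 1)
        sc <- sample(1:6, n1 + n0, replace = TRUE)  # ties guaranteed
        lab <- c(rep("case", n1), rep("control", n0))
        expect_identical(rocAuc(sc, lab)$auc, bruteAuc(sc, lab))
    }
})

test_that("grids reproduce the published search design", {
    g <- optGrid()
    expect_length(g$gammaCoarse, 19L)
    expect_equal(g$gammaCoarse[1], 2^-15)
    expect_equal(g$gammaCoarse[19], 2^3)
    expect_equal(diff(log2(g$gammaCoarse)), rep(1, 18))
    expect_length(g$nuCoarse, 10L)
    expect_equal(range(g$nuCoarse), c(0.01, 0.5))
    expect_length(g$nuFine, 20L)
    expect_equal(range(g$nuFine), c(0.01, 0.3))
    expect_equal(g$nuInit, 0.1)
})

test_that("out-of-fold scores come from models that never saw the unit", {
    se <- smallNullCohort(seed = 95)
    part <- matchPairs(subjectTable(se), "pooled")
    cv <- runOneClassCV(se, part, "case", nu = 0.1)
    X <- featureMatrix(se)
    subj <- subjectTable(se)
    sc <- cvScores(cv)
    for (j in c(1L, 5L)) {
        u <- partitionUnits(part)[[j]]
        ids <- unlist(u)
        trainIds <- setdiff(subj$id[subj$group == "case"], ids)
        m <- fitOneClass(X[trainIds, , drop = FALSE], nu = 0.1)
        manual <- decisionValues(m, X[ids, , drop = FALSE])
        expect_equal(sc$score[match(ids, sc$subject)], manual,
                     tolerance = 1e-12)
    }
    ## mutating a held-out control row changes only that subject's score
    ctrlId <- partitionUnits(part)[[2]]$controls[1]
    se2 <- se
    SummarizedExperiment::assay(se2)[, ctrlId] <-
        SummarizedExperiment::assay(se2)[, ctrlId] + 1000
    cv2 <- runOneClassCV(se2, part, "case", nu = 0.1)
    changed <- cvScores(cv2)$score != sc$score
    expect_identical(which(changed), match(ctrlId, sc$subject))
})

test_that("CV results are deterministic and correctly oriented", {
    se <- smallNullCohort(seed = 97)
    part <- matchPairs(subjectTable(se), "pooled")
    a <- runOneClassCV(se, part, "case")
    b <- runOneClassCV(se, part, "case")
    expect_identical(cvScores(a)$score, cvScores(b)$score)
    ## control-trained results orient case-likeness as minus the score
    cvc <- runOneClassCV(se, part, "control")
    sc <- cvScores(cvc)
    expect_equal(cvAuc(cvc),
                 rocAuc(-sc$score, sc$group)$auc)
})

test_that("subgroup AUC restricts the out-of-fold scores without refits", {
    se <- smallNullCohort(seed = 99)
    subj <- subjectTable(se)
    part <- matchPairs(subj, "pooled")
    cv <- runOneClassCV(se, part, "case")
    expect_equal(subgroupAuc(cv, subj, function(s) rep(TRUE, nrow(s))),
                 cvAuc(cv))
    hi <- subgroupAuc(cv, subj, function(s) s$nviq >= 70)
    lo <- subgroupAuc(cv, subj, function(s) s$nviq < 70)
    expect_true(is.finite(hi) && is.finite(lo))
    expect_error(subgroupAuc(cv, subj, function(s) s$group == "case"),
                 "both classes")
})

test_that("a stratified planted effect raises the affected stratum's AUC", {
    cfg <- cohortConfig(nCases = 60, nControls = 60, nRegions = 8,
                        seed = 103)
    subj <- sampleCovariates(cfg)
    ## inject a case shift only for high-NVIQ subjects
    se <- generateFeatures(subj, cfg, effectSpec(), seed = 104)
    X <- SummarizedExperiment::assay(se)
    shift <- ifelse(subj$group == "case" & subj$nviq >= 70, 3, 0)
    rowSds <- apply(X[1:10, ], 1, sd)
    X[1:10, ] <- X[1:10, ] + outer(rowSds, shift)
    SummarizedExperiment::assay(se) <- X
    part <- matchPairs(subj, "pooled")
    cv <- runOneClassCV(se, part, "case")
    expect_gt(subgroupAuc(cv, subj, function(s) s$nviq >= 70),
              subgroupAuc(cv, subj, function(s) s$nviq < 70))
})

test_that("nested optimization is an exhaustive argmax over its grids", {
    g <- optGrid(gammaCoarse = 2^c(-6, -5, -4), nuCoarse = c(0.1, 0.2, 0.3),
                 nuFine = c(0.1, 0.15), gammaFineSpan = 0.5,
                 gammaFineStep = 0.5)
    cfg <- cohortConfig(nCases = 12, nControls = 12, nRegions = 8,
                        seed = 107)
    se <- simulateCohort(cfg, effectSpec(affectedFeatures = 1:10,
                                         effectSizes = 2))
    subj <- subjectTable(se)
    part <- matchPairs(subj, "pooled")
    X <- featureMatrix(se)
    u <- occmap:::unitIndexOf(part, subj$id)
    opt <- nestedOptimize(X, u, subj$group, "case", g)
    tg <- opt$trace$gamma
    tn <- opt$trace$nu
    expect_equal(max(tg$auc), tg$auc[tg$gamma == opt$gamma][1])
    expect_equal(max(tn$auc), tn$auc[tn$nu == opt$nu][1])
    ## ties break toward the smaller parameter
    expect_equal(opt$gamma, min(tg$gamma[tg$auc == max(tg$auc)]))
    expect_equal(opt$nu, min(tn$nu[tn$auc == max(tn$auc)]))
})

test_that("the two-class reference behaves on null and separable cohorts", {
    seNull <- smallNullCohort(seed = 109)
    part <- matchPairs(subjectTable(seNull), "pooled")
    aucNull <- cvAuc(runTwoClassCV(seNull, part, "linear"))
    expect_gt(aucNull, 0.2)
    expect_lt(aucNull, 0.8)

    sc <- cohortScenario("effectRecovery", seed = 113)
    seEff <- simulateCohort(sc$config, sc$effects)
    p2 <- matchPairs(subjectTable(seEff), "pooled")
    auc2 <- cvAuc(runTwoClassCV(seEff, p2, "linear"))
    auc1 <- cvAuc(runOneClassCV(seEff, p2, "case"))
    ## the binary reference uses both classes, so it should match or beat
    ## the one-class result up to fold-level noise
    expect_gte(auc2, auc1 - 0.02)
    expect_gt(auc2, 0.9)
})

test_that("a single shifted feature drives the linear reference's sign", {
    cfg <- cohortConfig(nCases = 25, nControls = 25, nRegions = 2,
                        measures = "Thickness", includeGlobal = FALSE,
                        seed = 127)
    se <- simulateCohort(cfg, effectSpec(affectedFeatures = 1L,
                                         effectSizes = 4))
    part <- matchPairs(subjectTable(se), "pooled")
    cv <- runTwoClassCV(se, part, "linear")
    sc <- cvScores(cv)
    x1 <- featureMatrix(se)[sc$subject, 1]
    expect_gt(cor(sc$score, x1), 0.5)
})
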