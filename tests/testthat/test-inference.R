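test_that("unit-label permutation preserves sizes and swaps fairly", {
    s <- sampleCovariates(cohortConfig(nCases = 21, nControls = 20,
                                       sexRatio = 1, seed = 131))
    part <- matchPairs(s, "male")
    for (b in 1:20) {
        lab <- permuteUnitLabels(part, seed = b)
        expect_equal(sum(lab == "case"), 21L)
        expect_equal(sum(lab == "control"), 20L)
        ## each unit keeps its label multiset
        for (u in partitionUnits(part)) {
            ids <- unlist(u)
            expect_equal(sum(lab[ids] == "case"), length(u$cases))
        }
    }
    ## swap frequency of one pair over many draws: 50% +- 1.5%
    pair <- partitionUnits(part)[[1]]
    swapped <- vapply(1:10000, function(b)
        permuteUnitLabels(part, seed = b)[pair$cases[1]] == "control",
        logical(1))
    expect_lt(abs(mean(swapped) - 0.5), 0.015)
})

test_that("no-swap and all-swap outcomes reproduce and invert the labels", {
    s <- sampleCovariates(cohortConfig(nCases = 3, nControls = 3, seed = 137))
    part <- matchPairs(s, "pooled")
    orig <- setNames(s$group, s$id)[part@subjectIds]
    labs <- lapply(1:200, function(b) permuteUnitLabels(part, b))
    none <- which(vapply(labs, function(l) all(l == orig), logical(1)))[1]
    all_ <- which(vapply(labs, function(l) all(l != orig), logical(1)))[1]
    expect_false(is.na(none))   # identity relabeling occurs
    expect_false(is.na(all_))   # full inversion occurs
    expect_identical(labs[[all_]][part@subjectIds],
                     setNames(ifelse(orig == "case", "control", "case"),
                              names(orig)))
})

test_that("AUC permutation p-values follow the raw counting convention", {
    se <- smallNullCohort(seed = 139)
    part <- matchPairs(subjectTable(se), "pooled")
    at <- aucPermutationTest(se, part, nPermutations = 40, seed = 5)
    expect_equal(at$pValue, sum(at$nullAuc > at$observedAuc) / 40)
    expect_equal(at$pValueAddOne,
                 (1 + sum(at$nullAuc > at$observedAuc)) / 41)
    expect_gte(at$pValue, 0)
    expect_lte(at$pValue, 1)
    ## p-value monotonicity in the observed statistic
    pAt <- function(obs) sum(at$nullAuc > obs) / 40
    obsGrid <- seq(0, 1, by = 0.05)
    expect_false(is.unsorted(rev(vapply(obsGrid, pAt, numeric(1)))))
})

test_that("a strong planted effect is detected as significant", {
    sc <- cohortScenario("effectRecovery", seed = 149)
    se <- simulateCohort(sc$config, sc$effects)
    part <- matchPairs(subjectTable(se), "pooled")
    at <- aucPermutationTest(se, part, nPermutations = 100, seed = 7)
    expect_gt(at$observedAuc, 0.9)
    expect_equal(at$pValue, 0)   # observed above every null AUC
})

test_that("sign trends report the case-control mean difference", {
    X <- matrix(rnorm(200), 20, 10)
    lab <- rep(c("case", "control"), each = 10)
    X2 <- X
    X2[1:10, 1] <- X2[1:10, 1] + 5
    X2[, 2] <- 0   # identical -> none
    X2[1:10, 3] <- X2[1:10, 3] - 5
    tr <- signTrends(X2, lab)
    expect_equal(unname(tr[1:3]), c("up", "none", "down"))
    expect_error(signTrends(X, rep("case", 20)), "both groups")
})

test_that("sign trends match the generating effect specification", {
    cfg <- cohortConfig(nCases = 200, nControls = 200, nRegions = 8,
                        seed = 151)
    eff <- effectSpec(affectedFeatures = c(2L, 6L, 9L),
                      effectSizes = c(2, -2, 1.5))
    se <- simulateCohort(cfg, eff)
    tr <- signTrends(featureMatrix(se), subjectTable(se)$group)
    expect_equal(unname(tr[c(2, 6, 9)]), c("up", "down", "up"))
})

test_that("significance maps are deterministic and well-formed", {
    se <- smallNullCohort(seed = 157)
    part <- matchPairs(subjectTable(se), "pooled")
    m1 <- preimageSignificance(se, part, nPermutations = 30, seed = 11)
    m2 <- preimageSignificance(se, part, nPermutations = 30, seed = 11)
    expect_identical(m1$p, m2$p)
    expect_identical(m1$z, m2$z)
    expect_true(validObject(m1))
    expect_equal(nrow(m1), 44L)
    expect_identical(m1$significant, m1$p < 0.05)
    expect_true(all(m1$pAddOne >= m1$p))
    expect_true(all(m1$pAddOne[m1$p < 1] > m1$p[m1$p < 1]))
})

test_that("region reports tabulate significant features as arrow cells", {
    se <- smallNullCohort(seed = 163)
    part <- matchPairs(subjectTable(se), "pooled")
    map <- preimageSignificance(se, part, nPermutations = 20, seed = 13)

    ## empty significant set -> header-only table
    none <- as(map, "DFrame")
    none$p <- rep(1, nrow(none))
    none$significant <- none$p < 0.05
    rep0 <- makeRegionReport(none, alpha = 0.05)
    expect_equal(nrow(rep0), 0L)
    expect_true(all(surfaceMeasures() %in% colnames(rep0)))

    ## one significant feature -> one row with a single arrow
    one <- as(map, "DFrame")
    one$p <- rep(1, nrow(one))
    one$p[3] <- 0.001                      # lh region 1, Thickness
    one$significant <- one$p < 0.05
    rep1 <- makeRegionReport(one, alpha = 0.05)
    expect_equal(nrow(rep1), 1L)
    expect_equal(rep1$region, one$region[3])
    arrows <- unlist(rep1[, surfaceMeasures()])
    expect_equal(sum(nzchar(arrows)), 1L)

    d <- withr::local_tempdir()
    paths <- writeSignificanceMap(map, d)
    expect_true(all(file.exists(paths)))
})
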