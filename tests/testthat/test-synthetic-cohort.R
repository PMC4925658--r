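test_that("covariate sampling matches the configured cohort composition", {
    cfg <- cohortConfig(nCases = 41, nControls = 40, seed = 11)
    s <- sampleCovariates(cfg)
    expect_equal(nrow(s), 81L)
    expect_equal(as.vector(table(s$group)[c("case", "control")]),
                 c(41L, 40L))
    expect_true(all(s$age_months >= 22 & s$age_months <= 72))
    expect_true(all(s$nviq >= 31 & s$nviq <= 123))
    expect_identical(s$dd, s$nviq < 70)
    ## matched marginals: group means agree within sampling error
    expect_lt(abs(mean(s$age_months[s$group == "case"]) -
                  mean(s$age_months[s$group == "control"])), 5)
    expect_lt(abs(mean(s$nviq[s$group == "case"]) -
                  mean(s$nviq[s$group == "control"])), 10)

    tiny <- sampleCovariates(cohortConfig(nCases = 1, nControls = 1))
    expect_equal(sort(tiny$group), c("case", "control"))

    noDD <- sampleCovariates(cohortConfig(nviqRange = c(70, 70), seed = 2))
    expect_equal(sum(noDD$dd), 0L)

    expect_error(cohortConfig(ageRangeMonths = c(50, 20)), "interval")
    expect_error(cohortConfig(measures = character(0)), "measures")
    expect_error(cohortConfig(nCases = 0), "nCases")
})

test_that("the default cohort is 81 subjects by 314 features", {
    se <- simulateCohort(cohortConfig(seed = 3))
    expect_equal(dim(featureMatrix(se)), c(81L, 314L))
    expect_equal(rownames(se), dktFeatureIndex()$featureName)
})

test_that("identical seed and config give a bit-identical cohort", {
    cfg <- cohortConfig(nCases = 6, nControls = 6, nRegions = 4, seed = 99)
    a <- simulateCohort(cfg)
    b <- simulateCohort(cfg)
    expect_identical(featureMatrix(a), featureMatrix(b))
    expect_identical(subjectTable(a), subjectTable(b))
    c <- simulateCohort(cohortConfig(nCases = 6, nControls = 6,
                                     nRegions = 4, seed = 100))
    expect_false(identical(featureMatrix(a), featureMatrix(c)))
})

test_that("a null cohort has identical case and control feature law", {
    cfg <- cohortConfig(nCases = 1500, nControls = 1500, nRegions = 2,
                        measures = c("Area", "Thickness"), seed = 7,
                        includeGlobal = FALSE)
    se <- simulateCohort(cfg)
    X <- featureMatrix(se)
    g <- subjectTable(se)$group
    for (j in seq_len(ncol(X)))
        expect_gt(suppressWarnings(
            ks.test(X[g == "case", j], X[g == "control", j])$p.value), 1e-4)
})

test_that("a planted shift reproduces its standardized effect size", {
    cfg <- cohortConfig(nCases = 500, nControls = 500, nRegions = 4,
                        seed = 17)
    eff <- effectSpec(affectedFeatures = 3L, effectSizes = 3)
    se <- simulateCohort(cfg, eff)
    X <- featureMatrix(se)
    g <- subjectTable(se)$group
    pooledSd <- sqrt((var(X[g == "case", 3]) + var(X[g == "control", 3])) / 2)
    d <- (mean(X[g == "case", 3]) - mean(X[g == "control", 3])) / pooledSd
    expect_equal(d, 3, tolerance = 0.1)
    ## unaffected neighbour stays null
    d2 <- (mean(X[g == "case", 4]) - mean(X[g == "control", 4])) /
        sd(X[, 4])
    expect_lt(abs(d2), 0.2)
})

test_that("case covariance scaling and control heterogeneity act as stated", {
    cfg <- cohortConfig(nCases = 800, nControls = 800, nRegions = 4,
                        seed = 23)
    eff <- effectSpec(caseWithinCovScale = 0.5, controlHeterogeneity = 2,
                      heterogeneityFeatures = 1:2)
    se <- simulateCohort(cfg, eff)
    X <- featureMatrix(se)
    s <- subjectTable(se)
    isCase <- s$group == "case"
    ## case variance halved on a non-heterogeneity feature
    expect_equal(var(X[isCase, 5]) / var(X[!isCase, 5]), 0.5,
                 tolerance = 0.15)
    ## DD and no-DD control means separated by ~2 within-subpopulation SDs
    dd <- !isCase & s$dd
    nd <- !isCase & !s$dd
    sep <- (mean(X[dd, 1]) - mean(X[nd, 1])) / sd(X[nd, 1])
    expect_equal(sep, 2, tolerance = 0.25)
})

test_that("age/NVIQ coupling induces the requested feature correlation", {
    cfg <- cohortConfig(nCases = 400, nControls = 400, nRegions = 4,
                        seed = 29)
    se <- simulateCohort(cfg, effectSpec(covariateCoupling = c(1, 0)))
    X <- featureMatrix(se)
    age <- subjectTable(se)$age_months
    expect_gt(cor(X[, 1], age), 0.4)
    se0 <- simulateCohort(cfg)
    expect_lt(abs(cor(featureMatrix(se0)[, 1], age)), 0.15)
})

test_that("written cohorts round-trip exactly through the I/O layer", {
    se <- smallNullCohort(seed = 31, nCases = 5, nControls = 5)
    d <- withr::local_tempdir()
    files <- writeCohort(se, d)
    ## 2 hemispheres x 5 measures + metadata
    expect_length(files, 11L)
    back <- readCohort(d)
    expect_identical(featureMatrix(back), featureMatrix(se))
    expect_equal(subjectTable(back)$nviq, subjectTable(se)$nviq)
})
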