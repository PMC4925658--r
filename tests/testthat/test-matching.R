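test_that("optimal matching attains the brute-force minimum cost", {
    set.seed(61)
    for (r in 1:5) {
        n <- sample(3:6, 1)
        cost <- matrix(runif(n * n), n, n)
        idx <- occmap:::cpp_lap_assign(cost)
        got <- sum(cost[cbind(seq_len(n), idx)])
        expect_equal(got, bruteAssignCost(cost), tolerance = 1e-12)
        expect_false(anyDuplicated(idx) > 0)
    }
    ## rectangular: one row left out optimally
    cost <- matrix(runif(12), 3, 4)
    idx <- occmap:::cpp_lap_assign(cost)
    expect_equal(sum(cost[cbind(1:3, idx)]), bruteAssignCost(cost),
                 tolerance = 1e-12)
})

test_that("a 21-case / 20-control stratum yields 19 pairs and a triplet", {
    cfg <- cohortConfig(nCases = 21, nControls = 20, nRegions = 4,
                        sexRatio = 1, seed = 71)
    s <- sampleCovariates(cfg)
    part <- matchPairs(s, "male")
    expect_equal(nUnits(part), 20L)
    sizes <- vapply(partitionUnits(part), function(u)
        c(length(u$cases), length(u$controls)), integer(2))
    expect_equal(sum(sizes[1, ] == 1 & sizes[2, ] == 1), 19L)
    expect_equal(sum(sizes[1, ] == 2 & sizes[2, ] == 1), 1L)
    expect_setequal(part@subjectIds, s$id)
})

test_that("the pooled 41/40 cohort forms M = 40 matched units", {
    s <- sampleCovariates(cohortConfig(seed = 73))
    part <- matchPairs(s, "pooled")
    expect_equal(nUnits(part), 40L)
    expect_identical(matchPairs(s, "pooled")@units, part@units)
})

test_that("matching recovers the designed synthetic pairing", {
    ## controls are sampled as case + small jitter, so the optimal matching
    ## should mostly recover partner pairs
    s <- sampleCovariates(cohortConfig(nCases = 10, nControls = 10,
                                       seed = 79))
    part <- matchPairs(s, "pooled")
    hit <- vapply(partitionUnits(part), function(u)
        sub("case", "", u$cases[1]) == sub("ctrl", "", u$controls), logical(1))
    expect_gte(mean(hit), 0.8)
})

test_that("matching rejects unsupported compositions", {
    s <- sampleCovariates(cohortConfig(nCases = 5, nControls = 3, seed = 81))
    expect_error(matchPairs(s, "pooled"), "at most one")
    sOnly <- s[s$group == "case", ]
    expect_error(matchPairs(sOnly, "pooled"), "at least one case and one")
})

test_that("leave-pair-out folds partition the subjects", {
    s <- sampleCovariates(cohortConfig(nCases = 8, nControls = 8, seed = 83))
    part <- matchPairs(s, "pooled")
    folds <- lpoSplits(part)
    expect_length(folds, 8L)
    tested <- unlist(lapply(folds, `[[`, "testSubjects"))
    expect_false(anyDuplicated(tested) > 0)
    expect_setequal(tested, s$id)
    for (f in folds)
        expect_length(intersect(f$testSubjects, f$trainSubjects), 0L)
    one <- matchPairs(s[s$id %in% unlist(partitionUnits(part)[[1]]), ],
                      "pooled")
    expect_error(lpoSplits(one), "at least 2")
})
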