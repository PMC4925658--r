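test_that("a single-support-vector model returns its SV exactly", {
    m <- fitOneClass(matrix(c(2, -1, 3), 1, 3), nu = 0.5,
                     standardize = FALSE)
    pre <- computePreimage(m)
    expect_equal(unname(pre@z), c(2, -1, 3))
    expect_true(pre@converged)
    expect_lte(pre@nIterations, 2L)
    ## one fixed-point step from anywhere lands on the SV
    expect_equal(fixedPointStep(c(10, 10, 10), m), c(2, -1, 3))
})

test_that("the symmetric midpoint of two equal-weight SVs is a fixed point", {
    X <- rbind(c(-1, 0), c(1, 0))
    m <- fitOneClass(X, nu = 1, gamma = 0.5, standardize = FALSE)
    expect_equal(dualCoefs(m), c(0.5, 0.5))
    expect_equal(fixedPointStep(c(0, 0), m), c(0, 0))
})

test_that("every preimage lies in the componentwise support-vector hull", {
    set.seed(11)
    for (r in 1:8) {
        X <- matrix(rnorm(16 * 3), 16, 3)
        m <- fitOneClass(X, nu = runif(1, 0.2, 0.9), gamma = runif(1, .2, 2),
                         standardize = FALSE)
        pre <- computePreimage(m, seed = r)
        sv <- supportVectors(m)
        expect_true(all(pre@z >= apply(sv, 2, min) - 1e-9))
        expect_true(all(pre@z <= apply(sv, 2, max) + 1e-9))
        ## single steps also stay in the hull
        z1 <- fixedPointStep(sv[1, ], m)
        expect_true(all(z1 >= apply(sv, 2, min) - 1e-9 &
                        z1 <= apply(sv, 2, max) + 1e-9))
    }
})

test_that("the fixed point matches a dense 2-D grid search", {
    set.seed(21)
    for (r in 1:3) {
        X <- matrix(rnorm(20), 10, 2)
        m <- fitOneClass(X, nu = 0.5, gamma = 0.8, standardize = FALSE)
        ## restart from every SV so the global basin is always visited
        pre <- computePreimage(m, seed = r,
                               nRestarts = length(dualCoefs(m)))
        sv <- supportVectors(m)
        a <- dualCoefs(m)
        gx <- seq(min(sv[, 1]), max(sv[, 1]), length.out = 200)
        gy <- seq(min(sv[, 2]), max(sv[, 2]), length.out = 200)
        obj <- outer(gx, gy, Vectorize(function(x, y)
            sum(a * exp(-0.8 * colSums((t(sv) - c(x, y))^2)))))
        best <- which(obj == max(obj), arr.ind = TRUE)[1, ]
        res <- sqrt(diff(gx[1:2])^2 + diff(gy[1:2])^2)
        expect_lt(sqrt(sum((pre@z - c(gx[best[1]], gy[best[2]]))^2)),
                  2 * res)
        ## and never attains a worse objective than any grid point
        expect_gte(pre@objective, max(obj) - 1e-9)
    }
})

test_that("restarts concentrate in the heavier cluster's basin", {
    set.seed(31)
    A <- matrix(rnorm(16, mean = 0, sd = 0.3), 8, 2)
    B <- matrix(rnorm(4, mean = 6, sd = 0.3), 2, 2)
    m <- fitOneClass(rbind(A, B), nu = 0.95, gamma = 1, standardize = FALSE)
    hits <- vapply(1:10, function(s) {
        z <- computePreimage(m, seed = s)@z
        sqrt(sum((z - colMeans(A))^2)) < sqrt(sum((z - colMeans(B))^2))
    }, logical(1))
    expect_gte(mean(hits), 0.9)
})

test_that("preimages are reproducible and improve on their start", {
    se <- smallNullCohort(seed = 51)
    X <- featureMatrix(se)
    m <- fitOneClass(X[subjectTable(se)$group == "case", ], nu = 0.1)
    p1 <- computePreimage(m, seed = 7)
    p2 <- computePreimage(m, seed = 7)
    expect_identical(p1@z, p2@z)
    expect_identical(p1@nIterations, p2@nIterations)
    sv <- supportVectors(m)
    a <- dualCoefs(m)
    start <- drop(t(sv) %*% a) / sum(a)
    objStart <- sum(a * exp(-kernelGamma(m) *
                                colSums((t(sv) - start)^2)))
    expect_gte(p1@objective, objStart - 1e-12)
    ## back-transform is consistent with the model standardizer
    expect_equal(unname(p1@zRaw), unname(p1@z * m@scale + m@center))
})
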