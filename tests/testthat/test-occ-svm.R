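test_that("the RBF kernel has its closed-form values and shape", {
    x <- matrix(rnorm(12), 4, 3)
    K <- rbfKernelMatrix(x, gamma = 0.7)
    expect_equal(diag(K), rep(1, 4))
    expect_equal(K, t(K))
    expect_true(all(K > 0 & K <= 1))
    ## ||x - x'||^2 = ln(2)/gamma  ->  k = 1/2
    g <- 0.3
    a <- c(0, 0)
    b <- c(sqrt(log(2) / g), 0)
    expect_equal(rbfKernelMatrix(rbind(a), rbind(b), gamma = g)[1, 1], 0.5)
    expect_error(rbfKernelMatrix(x, matrix(0, 2, 2), gamma = 1),
                 "dimension mismatch")
    expect_error(rbfKernelMatrix(x, gamma = -1), "gamma")
})

test_that("a single training point sits exactly on the boundary", {
    m <- fitOneClass(matrix(c(1, 2, 3), 1, 3), nu = 0.5,
                     standardize = FALSE)
    expect_equal(dualCoefs(m), 1)
    expect_equal(m@rho, 1)
    expect_equal(m@trainingScores, 0)
    expect_equal(decisionValues(m, matrix(c(1, 2, 3), 1, 3)), 0)
})

test_that("the dual solution matches an independent QP oracle", {
    set.seed(101)
    for (r in 1:10) {
        N <- sample(5:25, 1)
        d <- sample(2:10, 1)
        nu <- runif(1, 0.05, 0.9)
        X <- matrix(rnorm(N * d), N, d)
        m <- fitOneClass(X, nu = nu, gamma = 1 / d, standardize = FALSE,
                         tol = 1e-8)
        K <- trainGram(X, 1 / d)
        C <- 1 / (nu * N)
        a2 <- qpOracle(K, C)
        a1 <- fullAlpha(m)
        o1 <- 0.5 * drop(t(a1) %*% K %*% a1)
        o2 <- 0.5 * drop(t(a2) %*% K %*% a2)
        expect_lt(abs(o1 - o2), 1e-6)
        expect_lt(max(abs(a1 - a2)), 1e-6)
    }
})

test_that("an interior-point QP solver reaches the same dual objective", {
    set.seed(151)
    for (r in 1:5) {
        N <- sample(8:20, 1)
        nu <- runif(1, 0.2, 0.8)
        X <- matrix(rnorm(N * 3), N, 3)
        K <- trainGram(X, 1 / 3)
        C <- 1 / (nu * N)
        m <- fitOneClass(X, nu = nu, gamma = 1 / 3, standardize = FALSE)
        ip <- kernlab::ipop(c = matrix(0, N, 1), H = K,
                            A = t(rep(1, N)), b = 1, l = matrix(0, N, 1),
                            u = matrix(C, N, 1), r = 0, sigf = 9)
        a3 <- kernlab::primal(ip)
        o1 <- 0.5 * drop(t(fullAlpha(m)) %*% K %*% fullAlpha(m))
        o3 <- 0.5 * drop(t(a3) %*% K %*% a3)
        expect_lt(abs(o1 - o3), 1e-6)
        expect_lte(o1, o3 + 1e-8)   # ours is never the worse minimizer
    }
})

test_that("nu bounds margin errors above and support vectors below", {
    set.seed(202)
    for (r in 1:25) {
        N <- sample(c(20, 40, 80), 1)
        nu <- sample(c(0.05, 0.1, 0.3), 1)
        m <- fitOneClass(matrix(rnorm(N * 5), N, 5), nu = nu)
        marginErr <- mean(m@trainingScores < -1e-5)
        svFrac <- length(dualCoefs(m)) / N
        expect_lte(marginErr, nu)
        expect_gte(svFrac, nu - 1 / N)
    }
})

test_that("SVDD with C = 1/(nu N) reproduces the nu-one-class solution", {
    set.seed(303)
    for (r in 1:10) {
        N <- sample(8:30, 1)
        d <- sample(2:6, 1)
        nu <- runif(1, 0.1, 0.8)
        X <- matrix(rnorm(N * d), N, d)
        Xt <- matrix(rnorm(20 * d), 20, d)
        m1 <- fitOneClass(X, nu = nu, gamma = 0.3)
        m2 <- fitSVDD(X, C = 1 / (nu * N), gamma = 0.3)
        expect_identical(m1@svIndex, m2@svIndex)
        expect_identical(order(decisionValues(m1, Xt)),
                         order(decisionValues(m2, Xt)))
    }
    expect_error(fitSVDD(matrix(rnorm(20), 10, 2), C = 0.05), "infeasible")
})

test_that("SVDD degenerates to radius zero on identical points", {
    X <- matrix(1, 6, 3)
    m <- fitSVDD(X, C = 1, gamma = 0.5, standardize = FALSE)
    expect_equal(m@radius2, 0, tolerance = 1e-9)
    ## linear-kernel center lies in the convex hull (here: the point itself)
    Xl <- matrix(rnorm(10), 5, 2)
    ml <- fitSVDD(Xl, C = 1, kernel = "linear", standardize = FALSE)
    ctr <- drop(t(fullAlpha(ml)) %*% Xl)
    expect_true(all(ctr >= apply(Xl, 2, min) - 1e-9))
    expect_true(all(ctr <= apply(Xl, 2, max) + 1e-9))
})

test_that("decision values behave at the margin and at infinity", {
    set.seed(404)
    X <- matrix(rnorm(60), 20, 3)
    m <- fitOneClass(X, nu = 0.3, standardize = FALSE, gamma = 0.5)
    C <- 1 / (0.3 * 20)
    a <- fullAlpha(m)
    free <- which(a > C * 1e-6 & a < C * (1 - 1e-6))
    expect_true(length(free) > 0)
    expect_lt(max(abs(m@trainingScores[free])), 1e-5)
    far <- matrix(1e6, 1, 3)
    expect_equal(decisionValues(m, far), -m@rho, tolerance = 1e-12)
})

test_that("heuristic gamma is the inverse feature count", {
    X <- matrix(rnorm(10 * 314), 10, 314)
    m <- fitOneClass(X, nu = 0.5)
    expect_equal(kernelGamma(m), 1 / 314)
})

test_that("a constant column does not change standardized decisions", {
    set.seed(505)
    X <- matrix(rnorm(45), 15, 3)
    Xt <- matrix(rnorm(15), 5, 3)
    m1 <- fitOneClass(X, nu = 0.2, gamma = 0.3)
    m2 <- fitOneClass(cbind(X, 7), nu = 0.2, gamma = 0.3)
    expect_equal(decisionValues(m1, Xt),
                 decisionValues(m2, cbind(Xt, 7)), tolerance = 1e-12)
})

test_that("decisions agree with the libsvm one-class implementation", {
    ## libsvm scales the same dual by nu*N: its decision values equal ours
    ## times nu*N.
    set.seed(606)
    X <- matrix(rnorm(40 * 4), 40, 4)
    Xt <- matrix(rnorm(60), 15, 4)
    nu <- 0.25
    m <- fitOneClass(X, nu = nu, gamma = 0.25, standardize = FALSE)
    sv <- e1071::svm(X, y = NULL, type = "one-classification", nu = nu,
                     gamma = 0.25, scale = FALSE, kernel = "radial",
                     tolerance = 1e-6)
    ours <- decisionValues(m, Xt) * (nu * nrow(X))
    theirs <- drop(attr(stats::predict(sv, Xt, decision.values = TRUE),
                        "decision.values"))
    expect_equal(ours, unname(theirs), tolerance = 1e-4)
})

test_that("models survive a JSON round trip", {
    X <- matrix(rnorm(30), 10, 3)
    colnames(X) <- paste0("f", 1:3)
    m <- fitOneClass(X, nu = 0.3)
    p <- withr::local_tempfile(fileext = ".json")
    writeOneClassModel(m, p)
    m2 <- readOneClassModel(p)
    Xt <- matrix(rnorm(15), 5, 3)
    expect_equal(decisionValues(m, Xt), decisionValues(m2, Xt),
                 tolerance = 1e-12)
})
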