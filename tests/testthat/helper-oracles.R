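## Independent oracles and small fixture builders shared across test files.
## These deliberately avoid the package's own solver paths: the QP oracle is
## accelerated projected gradient + an exact KKT polish, the AUC oracle is
## brute-force pairwise counting, and the assignment oracle enumerates
## permutations.

## Projection onto {a : sum(a) = 1, 0 <= a <= C} by bisection on the dual
## shift.
projSimplexBox <- function(v, C) {
    f <- function(t) sum(pmin(pmax(v - t, 0), C)) - 1
    lo <- min(v) - C - 1
    hi <- max(v)
    for (i in 1:80) {
        mid <- (lo + hi) / 2
        if (f(mid) > 0) lo <- mid else hi <- mid
    }
    pmin(pmax(v - (lo + hi) / 2, 0), C)
}

## FISTA on 0.5 a'Ka over the simplex-box, then an exact equality-
## constrained solve on the identified free set (KKT polish).
qpOracle <- function(K, C, iters = 2000) {
    n <- nrow(K)
    a <- projSimplexBox(rep(1 / n, n), C)
    y <- a
    t0 <- 1
    L <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
    for (i in seq_len(iters)) {
        anew <- projSimplexBox(y - (K %*% y)[, 1] / L, C)
        t1 <- (1 + sqrt(1 + 4 * t0^2)) / 2
        y <- anew + (t0 - 1) / t1 * (anew - a)
        a <- anew
        t0 <- t1
    }
    eps <- C * 1e-6
    free <- a > eps & a < C - eps
    atC <- a >= C - eps
    if (any(free)) {
        nf <- sum(free)
        rhs <- c(-K[free, atC, drop = FALSE] %*% rep(C, sum(atC)),
                 1 - C * sum(atC))
        M <- rbind(cbind(K[free, free, drop = FALSE], rep(1, nf)),
                   c(rep(1, nf), 0))
        sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
        if (!is.null(sol)) {
            af <- sol[seq_len(nf)]
            if (all(af > -1e-12) && all(af < C + 1e-12)) {
                a[free] <- pmin(pmax(af, 0), C)
                a[atC] <- C
                a[!free & !atC] <- 0
            }
        }
    }
    a
}

## Exact AUC by pairwise comparison, ties counted one half.
bruteAuc <- function(scores, labels, positive = "case") {
    sp <- scores[labels == positive]
    sn <- scores[labels != positive]
    tot <- 0
    for (a in sp) for (b in sn)
        tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(sp) * length(sn))
}

## Minimum assignment cost by enumeration (nrow <= ncol, ncol <= 7).
bruteAssignCost <- function(cost) {
    n <- nrow(cost)
    m <- ncol(cost)
    perms <- function(v) {
        if (length(v) <= 1) return(list(v))
        out <- list()
        for (i in seq_along(v))
            for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
        out
    }
    best <- Inf
    for (p in perms(seq_len(m))) {
        tot <- sum(cost[cbind(seq_len(n), p[seq_len(n)])])
        best <- min(best, tot)
    }
    best
}

## Small null cohort used throughout (20 + 20 subjects, 8 regions ->
## 44 features including the 4 globals).
smallNullCohort <- function(seed = 1L, nCases = 20, nControls = 20) {
    simulateCohort(cohortConfig(nCases = nCases, nControls = nControls,
                                nRegions = 8, seed = seed))
}

## Gram matrix of the one-class training problem for oracle comparisons.
trainGram <- function(x, gamma) {
    d2 <- as.matrix(dist(x))^2
    exp(-gamma * d2)
}

## Full dual vector (length N) of a fitted model.
fullAlpha <- function(model) {
    a <- numeric(model@nTrain)
    a[model@svIndex] <- dualCoefs(model)
    a
}
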