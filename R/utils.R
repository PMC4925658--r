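## Small internal helpers shared across modules.

## Derive a per-task seed below 2^31 from a base seed and an index, so that
## permutation b's random stream depends only on (seed, b) and results are
## independent of how permutations are batched.
deriveSeed <- function(seed, index) {
    a <- (as.numeric(seed) %% 2147483647) * 69621 %% 2147483647
    as.integer((a + as.numeric(index) * 48271 + 1) %% 2147483647)
}

## Inverse-CDF sampling from a normal truncated to [lo, hi].
rtruncnorm <- function(n, mean, sd, lo, hi) {
    plo <- pnorm(lo, mean, sd)
    phi <- pnorm(hi, mean, sd)
    qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

## Per-feature location/scale learned on a training matrix.
fitStandardizer <- function(x) {
    ctr <- colMeans(x)
    scl <- apply(x, 2L, sd)
    scl[!is.finite(scl) | scl < 1e-12] <- 1
    list(center = ctr, scale = scl)
}

applyStandardizer <- function(x, st) {
    if (is.null(st)) return(x)
    sweep(sweep(x, 2L, st$center, "-"), 2L, st$scale, "/")
}

## Subjects x features matrix (native units) from a cohort
## SummarizedExperiment; features are stored as rows in the assay.
#' Extract the subjects x features matrix of a cohort
#'
#' @param cohort a `SummarizedExperiment` as produced by [simulateCohort()]
#'   or [assembleFeatureMatrix()].
#' @return numeric matrix, subjects in rows, canonical feature columns.
#' @export
featureMatrix <- function(cohort) {
    t(assay(cohort, "morphometry"))
}

#' Extract the subject metadata table of a cohort
#'
#' @inheritParams featureMatrix
#' @return `data.frame` with columns id, group, sex, age_months, nviq, dd.
#' @export
subjectTable <- function(cohort) {
    as.data.frame(colData(cohort))
}

## Validate a subject metadata data.frame (shared by the reader and the
## generator output).
validateSubjects <- function(subjects) {
    need <- c("id", "group", "sex", "age_months", "nviq")
    miss <- setdiff(need, colnames(subjects))
    if (length(miss))
        stop("subject table lacks column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(subjects$id))
        stop("duplicate subject id(s): ",
             paste(unique(subjects$id[duplicated(subjects$id)]),
                   collapse = ", "))
    bad <- setdiff(unique(subjects$group), c("case", "control"))
    if (length(bad))
        stop("unknown group label(s): ", paste(bad, collapse = ", "),
             " (expected 'case' or 'control')")
    if (!all(subjects$sex %in% c("M", "F")))
        stop("sex must be 'M' or 'F'")
    if (any(!is.finite(subjects$age_months)) || any(subjects$age_months <= 0))
        stop("age_months must be finite and positive")
    if (any(!is.finite(subjects$nviq)) || any(subjects$nviq <= 0))
        stop("nviq must be finite and positive")
    subjects$dd <- subjects$nviq < 70
    rownames(subjects) <- subjects$id
    subjects
}

## Restrict a subject table to a stratum.
strataSubset <- function(subjects, stratum = c("pooled", "male", "female")) {
    stratum <- match.arg(stratum)
    keep <- switch(stratum,
                   pooled = rep(TRUE, nrow(subjects)),
                   male = subjects$sex == "M",
                   female = subjects$sex == "F")
    subjects[keep, , drop = FALSE]
}
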