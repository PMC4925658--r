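## Matched case-control units: cases and controls are paired by optimal
## assignment minimizing the summed Euclidean distance on standardized
## (age, NVIQ); a single surplus case joins the pair whose control is
## nearest, forming one triplet. The units double as leave-pair-out CV folds
## and as the exchangeable swap units of the permutation null.

#' Match cases to controls on age and NVIQ
#'
#' Minimum-cost one-to-one assignment of cases to controls on standardized
#' (age, NVIQ) Euclidean distance (Jonker-Volgenant algorithm; deterministic
#' given the inputs). If the stratum has exactly one case more than controls,
#' the surplus case is attached to the pair whose control is closest in
#' covariate distance, forming a triplet, so M = number of controls.
#'
#' @param subjects subject table (see [readSubjectTable()]).
#' @param stratum `"pooled"`, `"male"`, or `"female"`.
#' @return a [MatchedPartition-class].
#' @examples
#' cfg <- cohortConfig(nCases = 9, nControls = 8, nRegions = 4, seed = 7)
#' matchPairs(sampleCovariates(cfg), "pooled")  # 7 pairs + 1 triplet
#' @export
matchPairs <- function(subjects, stratum = c("pooled", "male", "female")) {
    stratum <- match.arg(stratum)
    subjects <- validateSubjects(as.data.frame(subjects))
    sub <- strataSubset(subjects, stratum)
    cases <- sub[sub$group == "case", , drop = FALSE]
    ctrls <- sub[sub$group == "control", , drop = FALSE]
    if (!nrow(cases) || !nrow(ctrls))
        stop("stratum '", stratum, "' needs at least one case and one control")
    if (nrow(cases) < nrow(ctrls))
        stop("unsupported composition: more controls (", nrow(ctrls),
             ") than cases (", nrow(cases), ") in stratum '", stratum, "'")
    if (nrow(cases) > nrow(ctrls) + 1L)
        stop("unsupported composition: cases may exceed controls by at ",
             "most one (got ", nrow(cases), " vs ", nrow(ctrls), ")")
    cov <- rbind(cases[, c("age_months", "nviq")],
                 ctrls[, c("age_months", "nviq")])
    st <- fitStandardizer(as.matrix(cov))
    zc <- applyStandardizer(as.matrix(cases[, c("age_months", "nviq")]), st)
    zk <- applyStandardizer(as.matrix(ctrls[, c("age_months", "nviq")]), st)
    cost <- outer(seq_len(nrow(zk)), seq_len(nrow(zc)),
                  Vectorize(function(i, j) sqrt(sum((zk[i, ] - zc[j, ])^2))))
    assign <- cpp_lap_assign(cost)  # for each control, its case
    units <- lapply(seq_len(nrow(ctrls)), function(i)
        list(cases = cases$id[assign[i]], controls = ctrls$id[i]))
    surplus <- setdiff(seq_len(nrow(cases)), assign)
    if (length(surplus) == 1L) {
        d <- sqrt(colSums((t(zk) - zc[surplus, ])^2))
        host <- which.min(d)
        units[[host]]$cases <- sort(c(units[[host]]$cases,
                                      cases$id[surplus]))
    }
    new("MatchedPartition", units = units, stratum = stratum,
        subjectIds = unlist(lapply(units, unlist), use.names = FALSE))
}

#' Leave-pair-out cross-validation folds
#'
#' Fold j trains on all matched units except unit j and tests on unit j; the
#' test sets are disjoint and cover every subject exactly once.
#'
#' @param partition a [MatchedPartition-class] with M >= 2 units.
#' @return list of M folds, each `list(fold, testUnit, trainUnits,
#'   testSubjects, trainSubjects)`.
#' @export
lpoSplits <- function(partition) {
    validObject(partition)
    M <- length(partition@units)
    if (M < 2L) stop("leave-pair-out CV needs at least 2 matched units")
    ids <- lapply(partition@units, function(u) unlist(u, use.names = FALSE))
    lapply(seq_len(M), function(j)
        list(fold = j, testUnit = j, trainUnits = setdiff(seq_len(M), j),
             testSubjects = ids[[j]],
             trainSubjects = unlist(ids[-j], use.names = FALSE)))
}

#' @rdname partition-accessors
#' @export
setMethod("nUnits", "MatchedPartition", function(object)
    length(object@units))

#' @rdname partition-accessors
#' @export
setMethod("partitionUnits", "MatchedPartition", function(object)
    object@units)

## subject id -> unit index map
unitIndexOf <- function(partition, ids) {
    map <- rep(seq_along(partition@units),
               vapply(partition@units, function(u) length(unlist(u)),
                      integer(1)))
    names(map) <- unlist(lapply(partition@units, unlist), use.names = FALSE)
    unname(map[ids])
}

setMethod("show", "MatchedPartition", function(object) {
    sizes <- vapply(object@units, function(u) length(unlist(u)), integer(1))
    cat("MatchedPartition (stratum: ", object@stratum, ")\n",
        "  M = ", length(object@units), " units: ",
        sum(sizes == 2L), " pairs, ", sum(sizes > 2L), " triplet(s); ",
        length(object@subjectIds), " subjects\n", sep = "")
})
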