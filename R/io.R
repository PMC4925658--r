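## Readers for the tab-separated regional morphometry dialect: one table per
## (hemisphere, measure) with subjects as rows and region columns, plus one
## subject metadata table. Parsing is strict by default - the analysis is
## invalid with silently missing features - with a lenient flag that ignores
## unknown columns with a warning. Units are trusted as-is; no conversion.

#' Read one regional measure table
#'
#' Parses a tab-separated table whose first column is `subject` and whose
#' remaining columns are region labels (plus, optionally, the global columns
#' `WhiteSurfArea` / `MeanThickness`), and returns the values in long form.
#'
#' @param path file path.
#' @param hemisphere `"lh"` or `"rh"`.
#' @param measure one of [surfaceMeasures()].
#' @param regions admissible region labels (default the 31 DKT labels).
#' @param lenient if `TRUE`, unknown columns are dropped with a warning
#'   instead of failing.
#' @return `data.frame` with columns subject, hemisphere, region, measure,
#'   value; global columns appear with region `"global"` and the global
#'   measure name.
#' @export
readMeasureTable <- function(path, hemisphere = c("lh", "rh"),
                             measure = surfaceMeasures(),
                             regions = dktRegions(), lenient = FALSE) {
    hemisphere <- match.arg(hemisphere)
    measure <- match.arg(measure)
    if (!file.exists(path)) stop("no such file: ", path)
    tab <- tryCatch(
        read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
        error = function(e) stop("parse error in ", path, ": ",
                                 conditionMessage(e)))
    if (!nrow(tab) || !ncol(tab)) stop("parse error: ", path, " is empty")
    if (colnames(tab)[1L] != "subject")
        stop("malformed header in ", path,
             ": first column must be 'subject', found '",
             colnames(tab)[1L], "'")
    cols <- colnames(tab)[-1L]
    known <- cols %in% regions | cols %in% globalMeasures()
    if (any(!known)) {
        if (!lenient)
            stop("unknown region column(s) in ", path, ": ",
                 paste(cols[!known], collapse = ", "))
        warning("ignoring unknown column(s) in ", path, ": ",
                paste(cols[!known], collapse = ", "))
        tab <- tab[, c(TRUE, known), drop = FALSE]
        cols <- cols[known]
    }
    if (!length(cols)) stop("no region columns in ", path)
    for (j in seq_along(cols)) {
        v <- tab[[j + 1L]]
        if (!is.numeric(v)) {
            bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
            stop("non-numeric cell in ", path, " at row ",
                 if (is.na(bad)) "?" else bad, ", column '", cols[j], "'")
        }
    }
    isGlob <- cols %in% globalMeasures()
    long <- data.frame(
        subject = rep(as.character(tab$subject), length(cols)),
        hemisphere = hemisphere,
        region = rep(ifelse(isGlob, "global", cols), each = nrow(tab)),
        measure = rep(ifelse(isGlob, cols, measure), each = nrow(tab)),
        value = unlist(tab[-1L], use.names = FALSE),
        stringsAsFactors = FALSE)
    if (any(!is.finite(long$value)))
        stop("missing or non-finite value(s) in ", path)
    long
}

#' Read and validate a subject metadata table
#'
#' Expects tab-separated columns `subject` (or `id`), `group` (case/control),
#' `sex` (M/F), `age_months`, `nviq`. The developmental-delay flag `dd` is
#' derived as NVIQ < 70 (so NVIQ = 70 is no-DD).
#'
#' @param path file path.
#' @return validated `data.frame` with columns id, group, sex, age_months,
#'   nviq, dd.
#' @export
readSubjectTable <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    tab <- read.delim(path, stringsAsFactors = FALSE)
    if ("subject" %in% colnames(tab) && !("id" %in% colnames(tab)))
        colnames(tab)[colnames(tab) == "subject"] <- "id"
    tab$id <- as.character(tab$id)
    validateSubjects(tab)
}

#' Assemble the canonical feature matrix from measure tables
#'
#' Combines long-form partial tables (from [readMeasureTable()]) into the
#' canonical subjects x features cohort object, failing loudly if any
#' (subject, feature) cell is absent.
#'
#' @param partials list of long tables.
#' @param subjects validated subject table ([readSubjectTable()]).
#' @param index the canonical feature index to assemble against; by default
#'   it is built from the regions/measures present in `partials`.
#' @return cohort `SummarizedExperiment` (features x subjects assay
#'   `"morphometry"`, `rowData` = index, `colData` = subjects).
#' @export
assembleFeatureMatrix <- function(partials, subjects, index = NULL) {
    long <- do.call(rbind, partials)
    if (is.null(long) || !nrow(long)) stop("no partial tables supplied")
    subjects <- validateSubjects(subjects)
    if (is.null(index)) {
        regs <- sort(unique(long$region[long$region != "global"]))
        meas <- unique(long$measure[long$region != "global"])
        index <- dktFeatureIndex(
            regions = regs,
            measures = surfaceMeasures()[surfaceMeasures() %in% meas],
            includeGlobal = any(long$region == "global"))
    }
    long$featureName <- featureName(long$hemisphere, long$region, long$measure)
    unknown <- setdiff(long$featureName, index$featureName)
    if (length(unknown))
        stop("values outside the feature index: ",
             paste(utils::head(unknown, 5L), collapse = ", "))
    x <- matrix(NA_real_, nrow(subjects), nrow(index),
                dimnames = list(subjects$id, index$featureName))
    extra <- setdiff(unique(long$subject), subjects$id)
    if (length(extra))
        stop("measure tables contain unknown subject(s): ",
             paste(utils::head(extra, 5L), collapse = ", "))
    x[cbind(long$subject, long$featureName)] <- long$value
    if (anyNA(x)) {
        bad <- which(is.na(x), arr.ind = TRUE)
        badSubj <- sort(unique(rownames(x)[bad[, 1L]]))
        stop("incomplete feature matrix: ", sum(is.na(x)),
             " missing cell(s); affected subject(s): ",
             paste(utils::head(badSubj, 10L), collapse = ", "))
    }
    SummarizedExperiment(
        assays = list(morphometry = t(x)),
        rowData = index,
        colData = DataFrame(subjects, row.names = subjects$id))
}

#' Read a cohort directory
#'
#' Reads the `<hemi>.<measure>.tsv` tables plus `subjects.tsv` written by
#' [writeCohort()] (or exported from a surface-analysis pipeline) and
#' assembles the canonical cohort object. Inverse of [writeCohort()].
#'
#' @param dir directory with the stats tables.
#' @param metaPath path of the metadata table (default `dir/subjects.tsv`).
#' @param regions admissible region labels.
#' @param lenient passed to [readMeasureTable()].
#' @return cohort `SummarizedExperiment`.
#' @export
readCohort <- function(dir, metaPath = file.path(dir, "subjects.tsv"),
                       regions = dktRegions(), lenient = FALSE) {
    files <- list.files(dir, pattern = "^(lh|rh)\\.[A-Za-z]+\\.tsv$",
                        full.names = TRUE)
    if (!length(files)) stop("no measure tables found in ", dir)
    subjects <- readSubjectTable(metaPath)
    partials <- lapply(files, function(f) {
        parts <- strsplit(basename(f), ".", fixed = TRUE)[[1L]]
        readMeasureTable(f, hemisphere = parts[1L], measure = parts[2L],
                         regions = regions, lenient = lenient)
    })
    assembleFeatureMatrix(partials, subjects)
}

#' Split a cohort back into long measure tables
#'
#' Inverse of [assembleFeatureMatrix()]: one long table per (hemisphere,
#' measure), global entries attached to their natural measure.
#'
#' @param cohort cohort `SummarizedExperiment`.
#' @return list of long `data.frame`s.
#' @export
splitFeatureMatrix <- function(cohort) {
    idx <- as.data.frame(rowData(cohort))
    x <- featureMatrix(cohort)
    key <- paste(idx$hemisphere,
                 ifelse(idx$region == "global",
                        ifelse(idx$measure == "WhiteSurfArea", "Area",
                               "Thickness"),
                        idx$measure))
    lapply(split(seq_len(nrow(idx)), key), function(sel) {
        data.frame(
            subject = rep(rownames(x), length(sel)),
            hemisphere = rep(idx$hemisphere[sel], each = nrow(x)),
            region = rep(idx$region[sel], each = nrow(x)),
            measure = rep(idx$measure[sel], each = nrow(x)),
            value = as.vector(x[, idx$featureName[sel], drop = FALSE]),
            stringsAsFactors = FALSE)
    })
}
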