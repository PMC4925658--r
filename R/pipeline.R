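## End-to-end orchestration: validate input -> match -> LPO-CV -> AUC +
## permutation significance -> preimage map -> region report, from a single
## configuration, with a JSON run manifest that makes every artifact
## re-derivable from config + inputs.

#' Build a run configuration
#'
#' Exactly one of (`statsDir`, `metaPath`) or `synthetic` must be given:
#' either the analysis reads morphometry tables from disk, or it simulates a
#' cohort from a [CohortConfig-class] (+ optional [EffectSpec-class]).
#'
#' @param statsDir directory of measure tables (see [readCohort()]).
#' @param metaPath subject metadata TSV.
#' @param synthetic a [CohortConfig-class] for a simulated cohort.
#' @param effects an [EffectSpec-class] used with `synthetic`.
#' @param stratum `"pooled"`, `"male"`, or `"female"`.
#' @param targetClass class the one-class description is trained on.
#' @param optimize nested (gamma, nu) optimization instead of fixed
#'   nu = 0.1 / heuristic gamma.
#' @param nu,gamma fixed parameters when `optimize = FALSE`.
#' @param nPermutations permutations for both the AUC test and the map.
#' @param alpha retention level of the significance map.
#' @param seed base seed for every random stage.
#' @param outDir output directory.
#' @return a validated `occmapRunConfig` list.
#' @export
runConfig <- function(statsDir = NULL, metaPath = NULL, synthetic = NULL,
                      effects = effectSpec(), stratum = "pooled",
                      targetClass = "case", optimize = FALSE, nu = 0.1,
                      gamma = NULL, nPermutations = 1000, alpha = 0.05,
                      seed = 1L, outDir = tempfile("occmap_run")) {
    fromFiles <- !is.null(statsDir)
    if (fromFiles == !is.null(synthetic))
        stop("exactly one of statsDir or synthetic must be given")
    if (fromFiles) {
        if (is.null(metaPath)) metaPath <- file.path(statsDir, "subjects.tsv")
        for (p in c(statsDir, metaPath))
            if (!file.exists(p)) stop("no such input: ", p)
    }
    cfg <- list(statsDir = statsDir, metaPath = metaPath,
                synthetic = synthetic, effects = effects,
                stratum = match.arg(stratum, c("pooled", "male", "female")),
                targetClass = match.arg(targetClass, c("case", "control")),
                optimize = isTRUE(optimize), nu = nu, gamma = gamma,
                nPermutations = as.integer(nPermutations), alpha = alpha,
                seed = as.integer(seed), outDir = outDir)
    class(cfg) <- "occmapRunConfig"
    cfg
}

#' Read a run configuration from YAML
#'
#' Key names follow [runConfig()]; a `synthetic:` block holds
#' [cohortConfig()] fields and an `effects:` block holds [effectSpec()]
#' fields.
#'
#' @param path YAML file.
#' @return an `occmapRunConfig`.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    if (!is.null(y$synthetic)) y$synthetic <- do.call(cohortConfig, y$synthetic)
    if (!is.null(y$effects)) y$effects <- do.call(effectSpec, y$effects)
    do.call(runConfig, y)
}

#' Run the complete one-class morphometry analysis
#'
#' Stages, in order: load or simulate the cohort; build the matched
#' partition; leave-pair-out one-class CV with overall and NVIQ-stratified
#' AUCs; matched-pair AUC permutation test; preimage significance map and
#' region report; JSON manifest. Every numeric artifact is a deterministic
#' function of config + inputs (+ seed).
#'
#' @param config an `occmapRunConfig` from [runConfig()] /
#'   [readRunConfig()].
#' @param quiet suppress per-stage messages.
#' @return invisibly, a list with the cohort, partition, CV result, AUC
#'   table, permutation test, significance map, region report and the
#'   written file paths.
#' @export
runFullAnalysis <- function(config, quiet = FALSE) {
    stopifnot(inherits(config, "occmapRunConfig"))
    say <- function(...) if (!quiet) message("[occmap] ", ...)
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    stage <- "load"
    out <- tryCatch({
        cohort <- if (!is.null(config$synthetic)) {
            say("simulating cohort (seed ", config$seed, ")")
            simulateCohort(config$synthetic, config$effects,
                           seed = config$seed)
        } else {
            say("reading cohort from ", config$statsDir)
            readCohort(config$statsDir, config$metaPath)
        }
        subjects <- subjectTable(cohort)

        stage <- "match"
        partition <- matchPairs(subjects, config$stratum)
        say("matched ", nUnits(partition), " units (stratum ",
            config$stratum, ")")
        punits <- partitionUnits(partition)
        ptab <- data.frame(
            unit = seq_along(punits),
            cases = vapply(punits, function(u)
                paste(u$cases, collapse = ","), character(1)),
            controls = vapply(punits, function(u)
                paste(u$controls, collapse = ","), character(1)))
        f <- file.path(config$outDir, "partition.tsv")
        write.table(ptab, f, sep = "\t", quote = FALSE, row.names = FALSE)
        paths <- c(paths, f)

        stage <- "cross-validation"
        cv <- runOneClassCV(cohort, partition, config$targetClass,
                            nu = config$nu, gamma = config$gamma,
                            optimize = config$optimize)
        f <- file.path(config$outDir, "cv_scores.tsv")
        write.table(as.data.frame(cvScores(cv)), f, sep = "\t",
                    quote = FALSE, row.names = FALSE)
        paths <- c(paths, f)
        tryAuc <- function(pred) tryCatch(subgroupAuc(cv, subjects, pred),
                                          error = function(e) NA_real_)
        aucs <- data.frame(
            subset = c("all", "nviq_ge_70", "nviq_lt_70"),
            auc = c(cvAuc(cv), tryAuc(function(s) s$nviq >= 70),
                    tryAuc(function(s) s$nviq < 70)))
        say("AUC = ", sprintf("%.3f", aucs$auc[1L]))
        f <- file.path(config$outDir, "auc.tsv")
        write.table(aucs, f, sep = "\t", quote = FALSE, row.names = FALSE)
        paths <- c(paths, f)

        stage <- "auc permutation test"
        say("AUC permutation test (", config$nPermutations, " permutations)")
        at <- aucPermutationTest(cohort, partition, config$targetClass,
                                 nPermutations = config$nPermutations,
                                 seed = config$seed, nu = config$nu,
                                 gamma = config$gamma,
                                 optimize = config$optimize, observed = cv)
        f <- file.path(config$outDir, "auc_null.tsv")
        write.table(data.frame(permutation = seq_along(at$nullAuc),
                               auc = at$nullAuc),
                    f, sep = "\t", quote = FALSE, row.names = FALSE)
        paths <- c(paths, f)

        stage <- "preimage map"
        say("preimage significance map")
        map <- preimageSignificance(cohort, partition, config$targetClass,
                                    nu = config$nu, gamma = config$gamma,
                                    nPermutations = config$nPermutations,
                                    alpha = config$alpha,
                                    seed = config$seed)
        paths <- c(paths, writeSignificanceMap(map, config$outDir))
        report <- makeRegionReport(map)

        stage <- "manifest"
        manifest <- list(
            package = "occmap",
            version = as.character(utils::packageVersion("occmap")),
            seed = config$seed, stratum = config$stratum,
            targetClass = config$targetClass, optimize = config$optimize,
            nu = config$nu,
            gamma = config$gamma %||% 1 / nrow(cohort),
            nPermutations = config$nPermutations, alpha = config$alpha,
            nSubjects = ncol(cohort), nFeatures = nrow(cohort),
            nUnits = nUnits(partition),
            foldParams = as.data.frame(cvParams(cv)),
            auc = aucs, aucPValue = at$pValue,
            aucPValueAddOne = at$pValueAddOne,
            nSignificantFeatures = sum(map$significant),
            synthetic = !is.null(config$synthetic))
        f <- file.path(config$outDir, "manifest.json")
        jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
        paths <- c(paths, f)
        list(cohort = cohort, partition = partition, cv = cv, auc = aucs,
             aucTest = at, map = map, report = report, paths = paths)
    }, error = function(e) {
        stop("pipeline failed at stage '", stage, "': ",
             conditionMessage(e), "\ncompleted outputs: ",
             if (length(paths)) paste(paths, collapse = ", ") else "none",
             call. = FALSE)
    })
    say("done; outputs in ", config$outDir)
    invisible(out)
}
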