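## Canonical feature index: hemisphere-major, region-alphabetical, measures
## in the fixed order below, then the 4 global features.

#' The five regional surface measures, in canonical order
#'
#' Area (white surface area, mm^2), Volume (gray matter volume, mm^3),
#' Thickness (mean cortical thickness, mm), ThicknessStd (SD of cortical
#' thickness, mm), MeanCurv (integrated rectified mean curvature, mm^-1).
#'
#' @return character vector of length 5.
#' @export
surfaceMeasures <- function() {
    c("Area", "Volume", "Thickness", "ThicknessStd", "MeanCurv")
}

#' DKT cortical region labels (one hemisphere)
#'
#' The 31 cortical labels of the Desikan-Killiany-Tourville parcellation, in
#' alphabetical order. A custom label set can be supplied to the readers and
#' the feature index builder instead.
#'
#' @return character vector of length 31.
#' @export
dktRegions <- function() {
    sort(c(
        "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
        "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
        "insula", "isthmuscingulate", "lateraloccipital",
        "lateralorbitofrontal", "lingual", "medialorbitofrontal",
        "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
        "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
        "posteriorcingulate", "precentral", "precuneus",
        "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
        "superiorparietal", "superiortemporal", "supramarginal",
        "transversetemporal"))
}

globalMeasures <- function() c("WhiteSurfArea", "MeanThickness")

featureName <- function(hemisphere, region, measure) {
    ifelse(region == "global",
           paste(hemisphere, measure, sep = "_"),
           paste(hemisphere, region, measure, sep = "_"))
}

#' Canonical morphometric feature index
#'
#' Builds the ordered (hemisphere, region, measure) index defining the column
#' layout of every feature matrix in the package: left then right hemisphere,
#' regions alphabetically within hemisphere, the requested measures in the
#' fixed canonical order within region, followed (optionally) by the 4 global
#' features (lh/rh white-surface total area and mean thickness). With the
#' defaults the index has 62 x 5 + 4 = 314 entries. The ordering is a pure
#' function of the label set: permuting the inputs does not change it.
#'
#' @param regions per-hemisphere region labels (default the 31 DKT labels).
#' @param measures measures per region, a subset of [surfaceMeasures()].
#' @param includeGlobal append the 4 global features.
#' @return `DataFrame` with columns hemisphere, region, measure, featureName.
#' @examples
#' nrow(dktFeatureIndex())  # 314
#' @export
dktFeatureIndex <- function(regions = dktRegions(),
                            measures = surfaceMeasures(),
                            includeGlobal = TRUE) {
    if (!length(regions)) stop("at least one region required")
    if (!length(measures)) stop("at least one measure required")
    if (!all(measures %in% surfaceMeasures()))
        stop("unknown measure(s): ",
             paste(setdiff(measures, surfaceMeasures()), collapse = ", "))
    regions <- sort(unique(regions))
    measures <- surfaceMeasures()[surfaceMeasures() %in% measures]
    hemis <- c("lh", "rh")
    idx <- expand.grid(measure = measures, region = regions,
                       hemisphere = hemis, stringsAsFactors = FALSE)
    idx <- idx[, c("hemisphere", "region", "measure")]
    if (includeGlobal) {
        glob <- expand.grid(measure = globalMeasures(), region = "global",
                            hemisphere = hemis, stringsAsFactors = FALSE)
        glob <- glob[order(glob$hemisphere,
                           match(glob$measure, globalMeasures())),
                     c("hemisphere", "region", "measure")]
        idx <- rbind(idx, glob)
    }
    out <- DataFrame(idx)
    out$featureName <- featureName(out$hemisphere, out$region, out$measure)
    if (anyDuplicated(out$featureName)) stop("feature names must be unique")
    rownames(out) <- out$featureName
    out
}

## Feature index for a synthetic cohort configuration.
configFeatureIndex <- function(config) {
    dktFeatureIndex(regions = dktRegions()[seq_len(config@nRegions / 2L)],
                    measures = config@measures,
                    includeGlobal = config@includeGlobal)
}
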