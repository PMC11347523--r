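#' Merge per-feature MI across hemispheres
#'
#' The regional contribution of a measure is the SUM of its left- and
#' right-hemisphere per-feature MI values.
#'
#' @param featureMI named numeric vector, feature key
#'   (`region__hemisphere__measure`) -> MI value.
#' @param schema the [RegionSchema-class]; both hemispheres must be present
#'   for every region x measure.
#' @return matrix regions x measures of merged MI.
#' @export
aggregateHemispheres <- function(featureMI, schema) {
    keys <- featureKeys(schema)
    missing <- setdiff(keys, names(featureMI))
    if (length(missing))
        stop("missing hemisphere value(s): ",
             paste(utils::head(missing, 4), collapse = ", "))
    info <- parseFeatureKeys(keys)
    regions <- regionLabels(schema)
    measures <- measureLabels(schema)
    out <- matrix(0, length(regions), length(measures),
                  dimnames = list(regions, measures))
    for (i in seq_along(keys))
        out[info$region[i], info$measure[i]] <-
            out[info$region[i], info$measure[i]] + featureMI[[keys[i]]]
    out
}

#' Combine per-region MI across measures
#'
#' Regional parenchyma = GMV + WMV; regional intracranial = GMV + WMV + CSF
#' (sums of the hemisphere-merged MI values).
#'
#' @param regionMI matrix regions x measures (from [aggregateHemispheres()]).
#' @param combo a [MeasureCombination-class].
#' @return named numeric vector, one combined value per region.
#' @export
aggregateMeasures <- function(regionMI, combo) {
    if (!methods::is(combo, "MeasureCombination"))
        stop("unknown combination: expected a MeasureCombination")
    missing <- setdiff(combo@members, colnames(regionMI))
    if (length(missing))
        stop("combination '", combo@name, "' needs measure(s): ",
             paste(missing, collapse = ", "))
    rowSums(regionMI[, combo@members, drop = FALSE])
}

#' Rank regions and assign tertiles
#'
#' Sorts the 33 per-region values in descending order (ties broken by region
#' label, ascending, stable), labels the highest/middle/lowest thirds
#' (11 regions each), and extracts the top-k list.
#'
#' @param values named numeric vector of per-region values.
#' @param topK length of the top list (default 10).
#' @param nRegions expected region count (default 33; the tertile partition
#'   requires a multiple of 3).
#' @return list with `ranking` (region labels, decreasing value), `tertile`
#'   (named character, `highest`/`middle`/`lowest`, in input order) and
#'   `top` (first `topK` of the ranking).
#' @export
rankAndTertile <- function(values, topK = 10L, nRegions = 33L) {
    if (length(values) != nRegions)
        stop("expected ", nRegions, " region values, got ", length(values))
    if (nRegions %% 3L != 0L)
        stop("tertile partition requires a region count divisible by 3")
    if (is.null(names(values))) stop("values must be named by region")
    ord <- order(-values, names(values))
    ranking <- names(values)[ord]
    third <- nRegions %/% 3L
    lab <- rep(c("highest", "middle", "lowest"), each = third)
    tertile <- stats::setNames(lab[match(names(values), ranking)],
                               names(values))
    list(ranking = ranking, tertile = tertile,
         top = utils::head(ranking, topK))
}

#' Decode feature contributions with mutual information
#'
#' Computes the KSG mutual information between a target variable (by
#' convention, bias-corrected brain age) and every morphometry feature of
#' the table, then assembles the aggregates used to rank regional
#' contributions: hemisphere-merged region x measure MI, parenchymal and
#' intracranial combinations, per-measure totals, tertile labels and top-10
#' lists.
#'
#' @param table a [MorphometryExperiment-class].
#' @param target per-subject target values aligned with the table's
#'   subjects (typically corrected brain age, years). If named, names must
#'   match the subject ids.
#' @param schema the [RegionSchema-class] (defaults to the table's).
#' @param k KSG neighbour count (default 3).
#' @param seed integer; expanded deterministically into one tie-break jitter
#'   seed per feature.
#' @param units `"nats"` (default) or `"bits"`.
#' @param combineVolumes if TRUE, the parenchyma/intracranial values are the
#'   MI of the summed member volumes (secondary mode) instead of the sum of
#'   the member MI values (primary mode).
#' @return An [MIProfile-class].
#' @export
miProfile <- function(table, target, schema = schemaOf(table), k = 3L,
                      seed = 1L, units = c("nats", "bits"),
                      combineVolumes = FALSE) {
    units <- match.arg(units)
    n <- ncol(table)
    if (length(target) != n)
        stop("misaligned subjects: target length ", length(target),
             " vs ", n, " subjects")
    if (!is.null(names(target)) && !identical(names(target), colnames(table)))
        stop("misaligned subjects: target names do not match subject ids")
    if (n <= k) stop("need more subjects than neighbours (n > k)")
    m <- SummarizedExperiment::assay(table, "morphometry")
    keys <- featureKeys(schema)
    if (!identical(rownames(m), keys))
        stop("schema mismatch between table and requested schema")
    target <- as.numeric(target)

    ests <- lapply(seq_along(keys), function(i)
        ksgMI(m[i, ], target, k = k, seed = deriveSeed(seed, i)))
    featureMI <- stats::setNames(vapply(ests, miValue, numeric(1)), keys)
    rawMI <- stats::setNames(vapply(ests, miRaw, numeric(1)), keys)

    regionMI <- aggregateHemispheres(featureMI, schema)
    measures <- measureLabels(schema)
    regions <- regionLabels(schema)

    combos <- list()
    if (all(c("GMV", "WMV") %in% measures))
        combos$parenchyma <- parenchymaCombination()
    if (all(c("GMV", "WMV", "CSF") %in% measures))
        combos$intracranial <- intracranialCombination()
    comboMI <- matrix(numeric(0), length(regions), 0,
                      dimnames = list(regions, NULL))
    if (length(combos)) {
        cols <- lapply(combos, function(cb) {
            if (!combineVolumes) return(aggregateMeasures(regionMI, cb))
            # secondary mode: MI of the summed member volumes, merged L+R
            v <- stats::setNames(numeric(length(regions)), regions)
            for (r in regions) for (h in hemisphereLabels(schema)) {
                rows <- paste(r, h, cb@members, sep = "__")
                v[r] <- v[r] + miValue(ksgMI(colSums(m[rows, , drop = FALSE]),
                                             target, k = k,
                                             seed = deriveSeed(seed, 0L)))
            }
            v
        })
        comboMI <- do.call(cbind, cols)
        colnames(comboMI) <- names(combos)
    }

    measureTotals <- colSums(regionMI)
    allCols <- cbind(regionMI, comboMI)
    if (length(regions) == 33L) {
        rt <- lapply(colnames(allCols), function(cn)
            rankAndTertile(allCols[, cn]))
        names(rt) <- colnames(allCols)
        tertiles <- do.call(cbind, lapply(rt, `[[`, "tertile"))
        topRegions <- lapply(rt, `[[`, "top")
    } else {
        tertiles <- matrix(NA_character_, length(regions), ncol(allCols),
                           dimnames = dimnames(allCols))
        topRegions <- lapply(seq_len(ncol(allCols)), function(j)
            rownames(allCols)[order(-allCols[, j], rownames(allCols))])
        names(topRegions) <- colnames(allCols)
        topRegions <- lapply(topRegions, utils::head, 10L)
    }

    scale <- if (units == "bits") 1 / log(2) else 1
    new("MIProfile",
        featureMI = featureMI * scale, rawMI = rawMI * scale,
        regionMI = regionMI * scale, comboMI = comboMI * scale,
        measureTotals = measureTotals * scale, tertiles = tertiles,
        topRegions = topRegions, k = as.integer(k), n = as.integer(n),
        seed = as.integer(seed), units = units)
}

#' @describeIn miProfile Per-feature MI (clipped).
#' @param profile an [MIProfile-class].
#' @export
featureMI <- function(profile) profile@featureMI

#' @describeIn miProfile Hemisphere-merged region x measure MI matrix.
#' @export
regionMI <- function(profile) profile@regionMI

#' @describeIn miProfile Region x combination (parenchyma, intracranial) MI.
#' @export
comboMI <- function(profile) profile@comboMI

#' @describeIn miProfile Per-measure totals (sum over merged regions).
#' @export
measureTotals <- function(profile) profile@measureTotals

#' @describeIn miProfile Grand total MI over all features.
#' @export
totalMI <- function(profile) sum(profile@featureMI)

#' @describeIn miProfile Tertile labels (regions x measures/combinations).
#' @export
tertiles <- function(profile) profile@tertiles

#' @describeIn miProfile Top-ranked regions for a measure or combination.
#' @param what a measure (`"GMV"`, ...) or combination (`"parenchyma"`,
#'   `"intracranial"`).
#' @export
topRegions <- function(profile, what) {
    if (!what %in% names(profile@topRegions))
        stop("no ranking for '", what, "'")
    profile@topRegions[[what]]
}

setMethod("show", "MIProfile", function(object) {
    cat(sprintf("MIProfile: %d features, %d subjects, k = %d (%s)\n",
                length(object@featureMI), object@n, object@k, object@units))
    cat("  per-measure totals:",
        paste(sprintf("%s %.2f", names(object@measureTotals),
                      object@measureTotals), collapse = ", "), "\n")
    cat(sprintf("  total MI %.2f %s\n", totalMI(object), object@units))
    for (nm in names(object@topRegions))
        cat(sprintf("  top %s: %s\n", nm,
                    paste(utils::head(object@topRegions[[nm]], 3),
                          collapse = ", ")))
})
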