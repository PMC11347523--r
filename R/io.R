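.namedNum <- function(x) {
    # named numeric from a (possibly empty) parsed-JSON object
    if (!length(x)) return(stats::setNames(numeric(0), character(0)))
    unlist(x)
}

.matFromJSON <- function(lst, regions) {
    cols <- names(lst)
    m <- matrix(numeric(0), length(regions), 0,
                dimnames = list(regions, NULL))
    if (!length(cols)) return(m)
    m <- do.call(cbind, lapply(lst, function(v) .namedNum(v)[regions]))
    dimnames(m) <- list(regions, cols)
    m
}

#' Serialize analysis results to JSON
#'
#' Machine-readable, round-trippable serialization: labels and integers are
#' stored exactly, reals at full shortest-round-trip precision, and an
#' explicit `units` field is always present. `readResults()` reconstructs
#' the original object; `readResults(writeResults(x, p))` equals `x`.
#'
#' @param x an [MIProfile-class] or [PerformanceMetrics-class].
#' @param path output JSON path (its directory must exist and be writable).
#' @export
setGeneric("writeResults", function(x, path) standardGeneric("writeResults"))

.writeJSON <- function(obj, path) {
    ok <- tryCatch({
        # I(17) significant digits: shortest-round-trip precision for doubles
        jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                             null = "null", na = "null", pretty = TRUE)
        TRUE
    }, error = function(e) e, warning = function(w) w)
    if (!isTRUE(ok))
        stop("I/O error writing results to ", path, ": ",
             conditionMessage(ok))
    invisible(path)
}

#' @rdname writeResults
setMethod("writeResults", "MIProfile", function(x, path) {
    regions <- rownames(x@regionMI)
    obj <- list(
        class = "MIProfile", version = "1", units = x@units,
        k = x@k, n = x@n, seed = x@seed,
        regions = regions,
        featureMI = as.list(x@featureMI),
        rawMI = as.list(x@rawMI),
        regionMI = lapply(seq_len(ncol(x@regionMI)), function(j)
            as.list(x@regionMI[, j])),
        comboMI = lapply(seq_len(ncol(x@comboMI)), function(j)
            as.list(x@comboMI[, j])),
        measureTotals = as.list(x@measureTotals),
        tertiles = lapply(seq_len(ncol(x@tertiles)), function(j)
            as.list(x@tertiles[, j])),
        topRegions = x@topRegions)
    names(obj$regionMI) <- colnames(x@regionMI)
    names(obj$comboMI) <- colnames(x@comboMI)
    names(obj$tertiles) <- colnames(x@tertiles)
    .writeJSON(obj, path)
})

#' @rdname writeResults
setMethod("writeResults", "PerformanceMetrics", function(x, path) {
    .writeJSON(list(class = "PerformanceMetrics", version = "1",
                    units = "years", mae = x@mae, rmse = x@rmse,
                    r2 = x@r2), path)
})

#' @rdname writeResults
#' @param path path to a JSON file written by `writeResults()`.
#' @export
readResults <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    cls <- obj$class
    if (is.null(cls)) stop("not a results file (no class field): ", path)
    if (cls == "PerformanceMetrics") {
        return(new("PerformanceMetrics", mae = obj$mae, rmse = obj$rmse,
                   r2 = if (is.null(obj$r2)) NA_real_ else obj$r2))
    }
    if (cls == "MIProfile") {
        regions <- as.character(unlist(obj$regions))
        tert <- obj$tertiles
        tertM <- matrix(NA_character_, length(regions), length(tert),
                        dimnames = list(regions, names(tert)))
        for (cn in names(tert)) {
            v <- unlist(lapply(tert[[cn]], function(e)
                if (is.null(e)) NA_character_ else e))
            tertM[names(tert[[cn]]), cn] <- v
        }
        return(new("MIProfile",
            featureMI = .namedNum(obj$featureMI),
            rawMI = .namedNum(obj$rawMI),
            regionMI = .matFromJSON(obj$regionMI, regions),
            comboMI = .matFromJSON(obj$comboMI, regions),
            measureTotals = .namedNum(obj$measureTotals),
            tertiles = tertM,
            topRegions = lapply(obj$topRegions, function(v)
                as.character(unlist(v))),
            k = as.integer(obj$k), n = as.integer(obj$n),
            seed = as.integer(obj$seed), units = obj$units))
    }
    stop("unknown results class: ", cls)
}
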