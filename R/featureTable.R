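#' Construct a MorphometryExperiment
#'
#' @param features numeric matrix, either features x subjects or
#'   subjects x features (orientation is resolved against the schema's
#'   feature keys found in the dimnames). Row/column names must carry the
#'   `region__hemisphere__measure` feature keys and subject ids.
#' @param age numeric vector of chronological ages (years), one per subject.
#' @param sex character vector, `"male"`/`"female"`, one per subject.
#' @param schema the governing [RegionSchema-class].
#' @return A validated [MorphometryExperiment-class], features ordered to
#'   schema order.
#' @export
MorphometryExperiment <- function(features, age, sex,
                                  schema = defaultRegionSchema()) {
    keys <- featureKeys(schema)
    if (is.null(rownames(features)) && is.null(colnames(features)))
        stop("feature matrix must carry feature keys in its dimnames")
    if (!all(keys %in% rownames(features))) {
        if (all(keys %in% colnames(features))) {
            features <- t(features)
        } else {
            present <- union(rownames(features), colnames(features))
            stop("schema mismatch: missing feature column(s): ",
                 paste(utils::head(setdiff(keys, present), 5), collapse = ", "))
        }
    }
    extra <- setdiff(rownames(features), keys)
    if (length(extra))
        stop("schema mismatch: unexpected feature column(s): ",
             paste(utils::head(extra, 5), collapse = ", "))
    features <- features[keys, , drop = FALSE]
    if (is.null(colnames(features)))
        colnames(features) <- if (ncol(features)) paste0("S", seq_len(ncol(features))) else character()
    rd <- parseFeatureKeys(keys)
    rd$unit <- unname(measureUnits(schema)[rd$measure])
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(morphometry = features),
        rowData = S4Vectors::DataFrame(rd[c("region", "hemisphere", "measure", "unit")],
                                       row.names = keys),
        colData = S4Vectors::DataFrame(age = as.numeric(age),
                                       sex = as.character(sex),
                                       row.names = colnames(features)))
    S4Vectors::metadata(se)$schema <- schema
    me <- methods::as(se, "MorphometryExperiment")
    methods::validObject(me)
    me
}

setValidity("MorphometryExperiment", function(object) {
    msg <- character()
    if (!"morphometry" %in% SummarizedExperiment::assayNames(object))
        return("assay 'morphometry' is required")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("age", "sex") %in% names(cd)))
        return("colData must contain 'age' and 'sex'")
    sch <- S4Vectors::metadata(object)$schema
    if (is.null(sch) || !methods::is(sch, "RegionSchema"))
        return("metadata(x)$schema must hold a RegionSchema")
    if (!identical(rownames(object), featureKeys(sch)))
        msg <- c(msg, "row names must equal featureKeys(schema) in schema order")
    age <- cd$age
    if (length(age) && (any(!is.finite(age)) || any(age < 0 | age > 120)))
        msg <- c(msg, "ages must be finite and within [0, 120]")
    if (length(cd$sex) && !all(cd$sex %in% c("male", "female")))
        msg <- c(msg, "sex must be coded 'male'/'female'")
    m <- SummarizedExperiment::assay(object, "morphometry")
    if (length(m) && (any(!is.finite(m)) || any(m <= 0))) {
        bad <- which(!is.finite(m) | m <= 0, arr.ind = TRUE)
        msg <- c(msg, paste0("non-positive or non-finite feature value(s), e.g. ",
                             rownames(object)[bad[1, 1]], " for subject ",
                             colnames(object)[bad[1, 2]]))
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn MorphometryExperiment Chronological ages in years.
#' @param x a [MorphometryExperiment-class].
#' @export
ages <- function(x) SummarizedExperiment::colData(x)$age

#' @describeIn MorphometryExperiment Subject sexes (`"male"`/`"female"`).
#' @export
sexes <- function(x) SummarizedExperiment::colData(x)$sex

#' @describeIn MorphometryExperiment Subject identifiers.
#' @export
subjectIds <- function(x) colnames(x)

#' @describeIn MorphometryExperiment The governing [RegionSchema-class].
#' @export
schemaOf <- function(x) S4Vectors::metadata(x)$schema

#' Read a feature table from CSV
#'
#' Expects a header row with columns `subject_id`, `age`, `sex` followed by
#' one column per feature named `region__hemisphere__measure`. The column
#' set must match the schema exactly (no extras, none missing); feature
#' columns are reordered to schema order.
#'
#' @param path path to a CSV file (RFC-4180, UTF-8, header mandatory).
#' @param schema the expected [RegionSchema-class].
#' @return A validated [MorphometryExperiment-class].
#' @export
readFeatureTable <- function(path, schema = defaultRegionSchema()) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    meta <- c("subject_id", "age", "sex")
    if (!all(meta %in% names(df)))
        stop("feature table must start with columns subject_id, age, sex")
    keys <- featureKeys(schema)
    have <- setdiff(names(df), meta)
    missing <- setdiff(keys, have)
    if (length(missing))
        stop("schema mismatch: missing feature column(s): ",
             paste(utils::head(missing, 5), collapse = ", "))
    extra <- setdiff(have, keys)
    if (length(extra))
        stop("schema mismatch: unexpected feature column(s): ",
             paste(utils::head(extra, 5), collapse = ", "))
    m <- t(as.matrix(df[, keys, drop = FALSE]))
    storage.mode(m) <- "double"
    colnames(m) <- as.character(df$subject_id)
    if (nrow(df) && any(m <= 0, na.rm = TRUE)) {
        bad <- which(m <= 0, arr.ind = TRUE)[1, ]
        stop("validation error: non-positive value for feature ",
             keys[bad[1]], ", subject ", colnames(m)[bad[2]])
    }
    MorphometryExperiment(m, age = df$age, sex = df$sex, schema = schema)
}

#' Write a feature table to CSV
#'
#' Inverse of [readFeatureTable()]: columns `subject_id`, `age`, `sex`, then
#' the features in schema order.
#'
#' @param x a [MorphometryExperiment-class].
#' @param path output CSV path.
#' @export
writeFeatureTable <- function(x, path) {
    m <- SummarizedExperiment::assay(x, "morphometry")
    df <- data.frame(subject_id = colnames(x), age = ages(x), sex = sexes(x),
                     check.names = FALSE, stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(t(m), check.names = FALSE))
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
    invisible(path)
}

#' Combine cohorts subject-wise
#'
#' Column-binds two or more [MorphometryExperiment-class] objects sharing the
#' same schema into one cohort (subject ids must be disjoint).
#'
#' @param ... [MorphometryExperiment-class] objects.
#' @return A combined [MorphometryExperiment-class].
#' @export
combineCohorts <- function(...) {
    tabs <- list(...)
    if (!length(tabs)) stop("nothing to combine")
    sch <- schemaOf(tabs[[1]])
    keys <- featureKeys(sch)
    for (t in tabs)
        if (!identical(rownames(t), keys))
            stop("schema mismatch between cohorts")
    ids <- unlist(lapply(tabs, colnames))
    if (anyDuplicated(ids))
        stop("duplicate subject id(s): ",
             paste(utils::head(unique(ids[duplicated(ids)]), 5),
                   collapse = ", "))
    m <- do.call(cbind, lapply(tabs, SummarizedExperiment::assay, "morphometry"))
    MorphometryExperiment(m, age = unlist(lapply(tabs, ages)),
                          sex = unlist(lapply(tabs, sexes)), schema = sch)
}

#' Assemble the model input matrix
#'
#' @param x a [MorphometryExperiment-class].
#' @param schema optional [RegionSchema-class]; must match the table's schema
#'   feature-for-feature.
#' @return list with `matrix` (subjects x features, deterministic schema
#'   column order) and `featureIndex` (ordered feature keys).
#' @export
assembleFeatureMatrix <- function(x, schema = schemaOf(x)) {
    keys <- featureKeys(schema)
    if (!identical(rownames(x), keys))
        stop("schema mismatch between table and requested schema")
    m <- t(SummarizedExperiment::assay(x, "morphometry"))
    list(matrix = m, featureIndex = keys)
}

setMethod("show", "MorphometryExperiment", function(object) {
    sch <- schemaOf(object)
    cat("MorphometryExperiment:", ncol(object), "subjects x", nrow(object),
        "features (", length(regionLabels(sch)), "regions )\n")
    if (ncol(object)) {
        a <- ages(object)
        cat(sprintf("  age %.1f-%.1f y; %d male / %d female\n", min(a), max(a),
                    sum(sexes(object) == "male"), sum(sexes(object) == "female")))
    }
})
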