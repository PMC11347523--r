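.MEASURES <- c("GMV", "WMV", "CSF", "CT")
.MEASURE_UNITS <- c(GMV = "mm3", WMV = "mm3", CSF = "mm3", CT = "mm")
.HEMISPHERES <- c("left", "right")

# Default registry of 33 bilateral cortical region labels. The atlas the
# feature tables are parcellated with defines 33 cortical regions per
# hemisphere; computations key on labels only, so the registry can be
# overridden wholesale (see regionSchema()) when a different label set is
# needed. Labels are normalized tokens: lower case, single underscores.
.DEFAULT_REGIONS <- c(
    "superior_frontal_gyrus", "middle_frontal_gyrus", "inferior_frontal_gyrus",
    "pre_central_gyrus", "post_central_gyrus", "paracentral_lobule",
    "superior_parietal_lobule", "inferior_parietal_lobule",
    "supramarginal_gyrus", "angular_gyrus", "precuneus",
    "superior_occipital_gyrus", "middle_occipital_gyrus",
    "inferior_occipital_gyrus", "cuneus", "lingual_gyrus", "fusiform_gyrus",
    "parahippocampal_gyrus", "superior_temporal_gyrus",
    "middle_temporal_gyrus", "inferior_temporal_gyrus", "temporal_pole",
    "transverse_temporal_gyrus", "insula", "cingulate", "gyrus_rectus",
    "medial_orbitofrontal_gyrus", "lateral_orbitofrontal_gyrus",
    "frontal_pole", "entorhinal_cortex", "planum_temporale",
    "occipital_pole", "subcallosal_gyrus"
)

#' Construct a region schema
#'
#' @param regions character vector of unique region labels. The default is the
#'   shipped 33-region bilateral cortical registry, which yields the standard
#'   33 x 2 x 4 = 264-feature layout.
#' @param hemispheres ordered hemispheres to include.
#' @param measures ordered measures to include (subset of GMV, WMV, CSF, CT).
#' @return A [RegionSchema-class].
#' @examples
#' sch <- regionSchema()
#' length(featureKeys(sch)) # 264
#' @export
regionSchema <- function(regions = .DEFAULT_REGIONS,
                         hemispheres = .HEMISPHERES,
                         measures = .MEASURES) {
    new("RegionSchema",
        regions = as.character(regions),
        hemispheres = as.character(hemispheres),
        measures = as.character(measures),
        units = .MEASURE_UNITS[measures])
}

#' Default 33-region, 264-feature schema
#' @return A [RegionSchema-class] with 33 regions, both hemispheres and all
#'   four measures.
#' @export
defaultRegionSchema <- function() regionSchema()

#' Load a region schema from a YAML or JSON config file
#'
#' The file may define any of the keys `regions`, `hemispheres`, `measures`;
#' omitted keys fall back to the defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A [RegionSchema-class].
#' @export
readRegionSchema <- function(path) {
    if (!file.exists(path)) stop("schema file not found: ", path)
    cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
        jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
        yaml::read_yaml(path)
    }
    regionSchema(
        regions = if (!is.null(cfg$regions)) cfg$regions else .DEFAULT_REGIONS,
        hemispheres = if (!is.null(cfg$hemispheres)) cfg$hemispheres else .HEMISPHERES,
        measures = if (!is.null(cfg$measures)) cfg$measures else .MEASURES)
}

#' @describeIn regionSchema Region labels, in schema order.
#' @param schema a [RegionSchema-class].
#' @export
regionLabels <- function(schema) schema@regions

#' @describeIn regionSchema Hemispheres, in schema order.
#' @export
hemisphereLabels <- function(schema) schema@hemispheres

#' @describeIn regionSchema Measures, in schema order.
#' @export
measureLabels <- function(schema) schema@measures

#' @describeIn regionSchema Named character of measure units.
#' @export
measureUnits <- function(schema) schema@units

#' Feature keys of a schema
#'
#' Deterministic feature naming and ordering: for each region (schema order),
#' for each hemisphere (left, right), for each measure (GMV, WMV, CSF, CT),
#' the key `region__hemisphere__measure` (double-underscore separator, so
#' region labels may themselves contain single underscores).
#'
#' @param schema a [RegionSchema-class].
#' @return character vector of feature column names, length
#'   `regions x hemispheres x measures`.
#' @export
featureKeys <- function(schema) {
    grid <- expand.grid(
        measure = schema@measures,
        hemisphere = schema@hemispheres,
        region = schema@regions,
        stringsAsFactors = FALSE)
    # expand.grid varies the first factor fastest; region must vary slowest
    paste(grid$region, grid$hemisphere, grid$measure, sep = "__")
}

#' Decompose feature keys into region/hemisphere/measure
#'
#' @param keys character vector of `region__hemisphere__measure` keys.
#' @return data.frame with columns `key`, `region`, `hemisphere`, `measure`.
#' @export
parseFeatureKeys <- function(keys) {
    parts <- strsplit(keys, "__", fixed = TRUE)
    bad <- lengths(parts) != 3L
    if (any(bad))
        stop("malformed feature key(s): ", paste(keys[bad], collapse = ", "))
    data.frame(
        key = keys,
        region = vapply(parts, `[[`, "", 1L),
        hemisphere = vapply(parts, `[[`, "", 2L),
        measure = vapply(parts, `[[`, "", 3L),
        stringsAsFactors = FALSE)
}

#' Number of features implied by a schema
#' @param schema a [RegionSchema-class].
#' @export
nFeatures <- function(schema) {
    length(schema@regions) * length(schema@hemispheres) * length(schema@measures)
}

#' Restrict a schema to subsets of regions, hemispheres or measures
#'
#' @param schema a [RegionSchema-class].
#' @param regions,hemispheres,measures subsets to keep (schema order is
#'   preserved); NULL keeps all.
#' @return A restricted [RegionSchema-class].
#' @export
subSchema <- function(schema, regions = NULL, hemispheres = NULL,
                      measures = NULL) {
    keep <- function(all, want, what) {
        if (is.null(want)) return(all)
        missing <- setdiff(want, all)
        if (length(missing))
            stop("unknown ", what, ": ", paste(missing, collapse = ", "))
        all[all %in% want]
    }
    regionSchema(
        regions = keep(schema@regions, regions, "region(s)"),
        hemispheres = keep(schema@hemispheres, hemispheres, "hemisphere(s)"),
        measures = keep(schema@measures, measures, "measure(s)"))
}

#' Measure combinations
#'
#' `parenchymaCombination()` sums GMV and WMV per region (regional brain
#' parenchyma volume); `intracranialCombination()` sums GMV, WMV and CSF
#' (regional intracranial volume).
#'
#' @return A [MeasureCombination-class].
#' @export
parenchymaCombination <- function()
    new("MeasureCombination", name = "parenchyma", members = c("GMV", "WMV"))

#' @rdname parenchymaCombination
#' @export
intracranialCombination <- function()
    new("MeasureCombination", name = "intracranial",
        members = c("GMV", "WMV", "CSF"))

setMethod("show", "RegionSchema", function(object) {
    cat("RegionSchema:", length(object@regions), "regions x",
        length(object@hemispheres), "hemispheres x",
        length(object@measures), "measures =", nFeatures(object),
        "features\n")
    cat("  measures:", paste(object@measures, collapse = ", "), "\n")
    cat("  regions: ", paste(utils::head(object@regions, 4), collapse = ", "),
        if (length(object@regions) > 4) ", ..." else "", "\n", sep = "")
})
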