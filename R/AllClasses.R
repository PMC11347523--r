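#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Atlas feature schema
#'
#' A `RegionSchema` fixes the naming contract for a regional morphometry
#' feature table: an ordered set of bilateral cortical region labels, the two
#' hemispheres, and the four morphometric measures (GMV, WMV, CSF in mm^3 and
#' CT in mm). The derived feature set is the Cartesian product
#' region x hemisphere x measure, ordered by region, then hemisphere
#' (left, right), then measure (GMV, WMV, CSF, CT). The default schema has
#' 33 regions and therefore 33 x 2 x 4 = 264 features.
#'
#' @slot regions character vector of unique region labels.
#' @slot hemispheres character pair, `c("left", "right")`.
#' @slot measures character, `c("GMV", "WMV", "CSF", "CT")`.
#' @slot units named character giving the unit of each measure.
#' @export
setClass("RegionSchema",
    representation(
        regions = "character",
        hemispheres = "character",
        measures = "character",
        units = "character"
    )
)

setValidity("RegionSchema", function(object) {
    msg <- character()
    if (anyDuplicated(object@regions))
        msg <- c(msg, "region labels must be unique")
    if (length(object@regions) < 1L)
        msg <- c(msg, "at least one region label is required")
    if (!identical(object@hemispheres, c("left", "right")) &&
        !identical(object@hemispheres, "left") &&
        !identical(object@hemispheres, "right"))
        msg <- c(msg, "hemispheres must be a subset of c(\"left\", \"right\") in that order")
    if (!all(object@measures %in% c("GMV", "WMV", "CSF", "CT")))
        msg <- c(msg, "measures must be drawn from GMV, WMV, CSF, CT")
    if (anyDuplicated(object@measures))
        msg <- c(msg, "measures must be unique")
    if (!all(object@measures %in% names(object@units)))
        msg <- c(msg, "every measure needs a unit")
    if (length(msg)) msg else TRUE
})

#' Subject-level morphometry table
#'
#' `MorphometryExperiment` is a [SummarizedExperiment::SummarizedExperiment]
#' holding one assay `"morphometry"` (features x subjects), subject metadata
#' `age` (years) and `sex` (`"male"`/`"female"`) in `colData`, feature
#' metadata (`region`, `hemisphere`, `measure`, `unit`) in `rowData`, and the
#' governing [RegionSchema-class] in `metadata(x)$schema`. Validity enforces
#' the feature-table contract: ages finite in [0, 120], sex coded, all
#' morphometric values strictly positive, and row names exactly matching the
#' schema's feature keys in schema order.
#'
#' @export
setClass("MorphometryExperiment", contains = "SummarizedExperiment")

#' Measure combination
#'
#' Named subset of measures whose per-region MI values are summed:
#' `parenchyma` = GMV + WMV, `intracranial` = GMV + WMV + CSF.
#'
#' @slot name combination name.
#' @slot members measures included.
#' @export
setClass("MeasureCombination",
    representation(name = "character", members = "character"))

setValidity("MeasureCombination", function(object) {
    msg <- character()
    if (!object@name %in% c("parenchyma", "intracranial"))
        msg <- c(msg, "unknown combination name")
    if (object@name == "parenchyma" && !setequal(object@members, c("GMV", "WMV")))
        msg <- c(msg, "parenchyma must combine exactly GMV and WMV")
    if (object@name == "intracranial" && !setequal(object@members, c("GMV", "WMV", "CSF")))
        msg <- c(msg, "intracranial must combine exactly GMV, WMV and CSF")
    if (length(msg)) msg else TRUE
})

#' Cohort simulation parameters
#'
#' Per-feature trajectory parameters plus cohort-level settings for the
#' synthetic morphometry generator. Each feature value is generated as
#' `baseline + slope * age + quad * age^2 + sexOffset * (sex == "male") +
#' N(0, noiseSd)`, truncated below at 1% of baseline.
#'
#' @slot features data.frame with columns `key`, `region`, `hemisphere`,
#'   `measure`, `baseline`, `slope`, `quad`, `sexOffset`, `noiseSd`, `unit`.
#' @slot ageRange numeric length-2, simulated age range in years.
#' @slot sexRatio numeric in [0, 1], probability a subject is male.
#' @slot globalScaleSd sd of the per-subject log-normal multiplicative
#'   head-size factor applied to all volume features (0 = off, the default).
#' @slot n default number of subjects.
#' @slot seed default random seed.
#' @export
setClass("TrajectoryParams",
    representation(
        features = "data.frame",
        ageRange = "numeric",
        sexRatio = "numeric",
        globalScaleSd = "numeric",
        n = "integer",
        seed = "integer"
    ),
    prototype(globalScaleSd = 0)
)

setValidity("TrajectoryParams", function(object) {
    f <- object@features
    need <- c("key", "region", "hemisphere", "measure", "baseline", "slope",
              "quad", "sexOffset", "noiseSd", "unit")
    msg <- character()
    if (!all(need %in% names(f)))
        msg <- c(msg, paste("features table must have columns:",
                            paste(need, collapse = ", ")))
    else {
        if (any(f$noiseSd < 0)) msg <- c(msg, "noise sd must be >= 0")
        if (any(f$baseline <= 0)) msg <- c(msg, "baselines must be > 0")
    }
    if (length(object@ageRange) != 2L || diff(object@ageRange) < 0)
        msg <- c(msg, "ageRange must be increasing length-2 numeric")
    if (object@sexRatio < 0 || object@sexRatio > 1)
        msg <- c(msg, "sexRatio must lie in [0, 1]")
    if (length(object@globalScaleSd) != 1L || object@globalScaleSd < 0)
        msg <- c(msg, "globalScaleSd must be a single value >= 0")
    if (object@n < 0L) msg <- c(msg, "n must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Planted ground truth of a synthetic cohort
#'
#' Per-feature standardized age-effect sizes (|range of the deterministic age
#' trajectory over the simulated age span| / noise sd) and the derived
#' per-measure region ranking (regions ordered by the summed left+right
#' effect size, descending).
#'
#' @slot effectSizes named numeric, feature key -> effect size.
#' @slot regionEffects matrix regions x measures of merged effect sizes.
#' @slot ranking named list, measure -> character vector of region labels in
#'   decreasing effect order.
#' @export
setClass("SyntheticTruth",
    representation(
        effectSizes = "numeric",
        regionEffects = "matrix",
        ranking = "list"
    )
)

#' Age-bias correction coefficients
#'
#' Ordinary-least-squares fit of predicted on chronological age in the
#' training set: `predicted ~ alpha * age + beta`. The correction applied to
#' a subject is `corrected = predicted + [age - (alpha * age + beta)]`.
#'
#' @slot alpha dimensionless slope.
#' @slot beta intercept in years.
#' @export
setClass("BiasCoefficients",
    representation(alpha = "numeric", beta = "numeric"))

setValidity("BiasCoefficients", function(object) {
    if (!is.finite(object@alpha) || !is.finite(object@beta))
        "alpha and beta must be finite" else TRUE
})

#' Trained brain-age model
#'
#' Bundles the fitted epsilon-insensitive RBF-kernel support vector
#' regressor, the feature/target standardization learned on the training
#' split, the hyperparameter search record, out-of-fold training predictions,
#' and the fitted [BiasCoefficients-class].
#'
#' @slot fit fitted `e1071::svm` object (or NULL for a degenerate
#'   constant-target model).
#' @slot schema the [RegionSchema-class] the model expects.
#' @slot cost selected regularization constant C.
#' @slot epsilon insensitivity margin on the standardized target.
#' @slot gamma RBF kernel width.
#' @slot gridScores named numeric, cross-validated MAE (years) per candidate C.
#' @slot featureCenter,featureScale named numeric standardization vectors.
#' @slot droppedFeatures constant features removed before fitting.
#' @slot yCenter,yScale target standardization.
#' @slot constantTarget logical; TRUE when the training ages had no variance.
#' @slot oofPredictions out-of-fold cross-validated training predictions (years).
#' @slot trainAges chronological training ages (years).
#' @slot foldId outer fold assignment used for selection and OOF predictions.
#' @slot bias fitted [BiasCoefficients-class] (may be absent for degenerate fits).
#' @slot seed fold-shuffling seed.
#' @export
setClass("BrainAgeModel",
    representation(
        fit = "ANY",
        schema = "RegionSchema",
        cost = "numeric",
        epsilon = "numeric",
        gamma = "numeric",
        gridScores = "numeric",
        featureCenter = "numeric",
        featureScale = "numeric",
        droppedFeatures = "character",
        yCenter = "numeric",
        yScale = "numeric",
        constantTarget = "logical",
        oofPredictions = "numeric",
        trainAges = "numeric",
        foldId = "integer",
        bias = "ANY",
        seed = "integer"
    )
)

setValidity("BrainAgeModel", function(object) {
    msg <- character()
    if (object@cost <= 0) msg <- c(msg, "C must be > 0")
    if (object@epsilon < 0) msg <- c(msg, "epsilon must be >= 0")
    if (length(object@featureScale) && any(object@featureScale <= 0))
        msg <- c(msg, "standardization sds must be > 0 for retained features")
    if (length(msg)) msg else TRUE
})

#' Regression performance metrics
#'
#' @slot mae mean absolute error (years).
#' @slot rmse root-mean-square error (years).
#' @slot r2 coefficient of determination (NA when the reference ages have no
#'   variance).
#' @export
setClass("PerformanceMetrics",
    representation(mae = "numeric", rmse = "numeric", r2 = "numeric"))

setValidity("PerformanceMetrics", function(object) {
    msg <- character()
    if (object@mae < 0) msg <- c(msg, "mae must be >= 0")
    if (object@rmse + 1e-12 < object@mae) msg <- c(msg, "rmse must be >= mae")
    if (!is.na(object@r2) && object@r2 > 1) msg <- c(msg, "r2 cannot exceed 1")
    if (length(msg)) msg else TRUE
})

#' A single KSG mutual-information estimate
#'
#' @slot value MI in nats, clipped below at zero.
#' @slot raw the unclipped estimate.
#' @slot k neighbour count used.
#' @slot n sample count.
#' @export
setClass("MIEstimate",
    representation(value = "numeric", raw = "numeric", k = "integer",
                   n = "integer"))

setValidity("MIEstimate", function(object) {
    msg <- character()
    if (object@value < 0) msg <- c(msg, "clipped MI must be >= 0")
    if (object@k < 1L) msg <- c(msg, "k must be >= 1")
    if (object@n <= object@k) msg <- c(msg, "n must exceed k")
    if (length(msg)) msg else TRUE
})

#' Mutual-information decoding profile
#'
#' Per-feature KSG mutual information between a target (corrected brain age)
#' and every morphometry feature, with the aggregates used to rank regional
#' contributions: hemisphere-merged region x measure values (left + right),
#' parenchymal and intracranial combinations, per-measure totals, tertile
#' labels, and top-k region lists.
#'
#' @slot featureMI named numeric, feature key -> MI (nats, clipped at 0).
#' @slot rawMI named numeric, unclipped per-feature estimates.
#' @slot regionMI matrix regions x measures of merged MI.
#' @slot comboMI matrix regions x combinations (parenchyma, intracranial).
#' @slot measureTotals named numeric, per-measure totals over regions.
#' @slot tertiles character matrix regions x (measures + combinations) with
#'   labels highest/middle/lowest.
#' @slot topRegions named list of top-ranked region vectors.
#' @slot k,n,seed estimator settings.
#' @slot units `"nats"` or `"bits"`.
#' @export
setClass("MIProfile",
    representation(
        featureMI = "numeric",
        rawMI = "numeric",
        regionMI = "matrix",
        comboMI = "matrix",
        measureTotals = "numeric",
        tertiles = "matrix",
        topRegions = "list",
        k = "integer",
        n = "integer",
        seed = "integer",
        units = "character"
    )
)

#' Sex-subgroup comparison of MI decoding
#'
#' @slot subgroups named list (male, female, all) each holding the subgroup's
#'   `metrics` (before/after correction [PerformanceMetrics-class]),
#'   `profile` ([MIProfile-class]), `totalMI`, and subject count `n`.
#' @slot comparisons data.frame of pairwise Spearman rank comparisons of
#'   region MI (per measure, per combination and on the all-measure merged
#'   profile) with rho, p and a significance flag at 0.05.
#' @export
setClass("SubgroupComparison",
    representation(subgroups = "list", comparisons = "data.frame"))
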