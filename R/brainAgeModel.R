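#' Fit the brain-age regression model
#'
#' Trains an epsilon-insensitive support vector regressor with an RBF kernel
#' on the standardized feature matrix, selecting the regularization constant
#' C by exhaustive grid search under shuffled 10-fold cross-validation scored
#' by mean absolute error in years (the inner loop of the nested scheme; the
#' final model is refit on the full training split with the selected C).
#' Feature and target standardization are learned on the training split only
#' and stored in the model. Out-of-fold cross-validated training predictions
#' are retained and, by default, used to fit the age-bias correction
#' coefficients.
#'
#' @param train a [MorphometryExperiment-class] training cohort.
#' @param schema the [RegionSchema-class] (defaults to the table's).
#' @param grid candidate C values; the default `c(0.1, 1, 10, 100)`.
#' @param epsilon insensitivity margin on the standardized target.
#' @param nfolds folds for the cross-validated search (default 10).
#' @param seed integer seed driving the shuffled fold assignment.
#' @param biasFrom `"oof"` (default) fits the bias correction on out-of-fold
#'   cross-validated training predictions; `"insample"` on refit in-sample
#'   predictions.
#' @return A [BrainAgeModel-class].
#' @export
fitBrainAgeModel <- function(train, schema = schemaOf(train),
                             grid = c(0.1, 1, 10, 100), epsilon = 0.1,
                             nfolds = 10L, seed = 1L,
                             biasFrom = c("oof", "insample")) {
    biasFrom <- match.arg(biasFrom)
    am <- assembleFeatureMatrix(train, schema)
    X <- am$matrix
    y <- ages(train)
    n <- nrow(X)
    if (n < nfolds)
        stop("configuration error: ", n, " subjects is fewer than ", nfolds,
             " folds")
    if (!length(grid) || any(grid <= 0)) stop("C grid must be positive")

    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    dropped <- colnames(X)[scl == 0]
    if (length(dropped)) {
        warning("dropping constant feature(s): ",
                paste(utils::head(dropped, 5), collapse = ", "),
                if (length(dropped) > 5) ", ..." else "")
        keep <- scl > 0
        X <- X[, keep, drop = FALSE]
        ctr <- ctr[keep]
        scl <- scl[keep]
    }
    Xs <- scale(X, center = ctr, scale = scl)

    yc <- mean(y)
    ysd <- stats::sd(y)
    if (ysd == 0) {
        # degenerate constant target: predict the constant, no regression fit
        model <- new("BrainAgeModel", fit = NULL, schema = schema,
                     cost = grid[1], epsilon = epsilon, gamma = NaN,
                     gridScores = stats::setNames(numeric(0), character(0)),
                     featureCenter = ctr, featureScale = scl,
                     droppedFeatures = dropped, yCenter = yc, yScale = 0,
                     constantTarget = TRUE, oofPredictions = rep(yc, n),
                     trainAges = y, foldId = integer(n), bias = NULL,
                     seed = as.integer(seed))
        return(model)
    }
    ys <- (y - yc) / ysd
    gamma <- 1 / (ncol(Xs) * mean(apply(Xs, 2, stats::var)))

    foldId <- withSeed(seed, sample(rep_len(seq_len(nfolds), n)))
    oofFor <- function(C) {
        pred <- numeric(n)
        for (f in seq_len(nfolds)) {
            hold <- foldId == f
            fit <- e1071::svm(x = Xs[!hold, , drop = FALSE], y = ys[!hold],
                              type = "eps-regression", kernel = "radial",
                              cost = C, gamma = gamma, epsilon = epsilon,
                              scale = FALSE)
            pred[hold] <- stats::predict(fit, Xs[hold, , drop = FALSE])
        }
        pred * ysd + yc
    }
    oofByC <- lapply(grid, oofFor)
    scores <- vapply(oofByC, function(p) mean(abs(p - y)), numeric(1))
    names(scores) <- as.character(grid)
    best <- which(scores == min(scores))[1]   # ties -> smallest C in grid order
    C <- grid[best]

    fit <- e1071::svm(x = Xs, y = ys, type = "eps-regression",
                      kernel = "radial", cost = C, gamma = gamma,
                      epsilon = epsilon, scale = FALSE)
    oof <- oofByC[[best]]

    model <- new("BrainAgeModel", fit = fit, schema = schema, cost = C,
                 epsilon = epsilon, gamma = gamma, gridScores = scores,
                 featureCenter = ctr, featureScale = scl,
                 droppedFeatures = dropped, yCenter = yc, yScale = ysd,
                 constantTarget = FALSE, oofPredictions = oof, trainAges = y,
                 foldId = as.integer(foldId), bias = NULL,
                 seed = as.integer(seed))
    biasPred <- if (biasFrom == "oof") oof else predictAge(model, train)
    model@bias <- fitBiasCorrection(biasPred, y)
    model
}

#' Predict brain age
#'
#' Applies the model's stored feature standardization (never refit on new
#' data) and returns one estimated brain age in years per subject.
#'
#' @param model a [BrainAgeModel-class].
#' @param table a [MorphometryExperiment-class] matching the model's schema.
#' @return numeric vector of predicted ages, named by subject id.
#' @export
predictAge <- function(model, table) {
    if (!identical(rownames(table), featureKeys(model@schema)))
        stop("schema mismatch: table features do not match the model's schema")
    n <- ncol(table)
    if (n == 0L) return(stats::setNames(numeric(0), character(0)))
    if (model@constantTarget)
        return(stats::setNames(rep(model@yCenter, n), colnames(table)))
    X <- assembleFeatureMatrix(table, model@schema)$matrix
    X <- X[, names(model@featureCenter), drop = FALSE]
    Xs <- scale(X, center = model@featureCenter, scale = model@featureScale)
    p <- stats::predict(model@fit, Xs) * model@yScale + model@yCenter
    stats::setNames(as.numeric(p), colnames(table))
}

#' Regression performance metrics
#'
#' MAE = mean |pred - actual|, RMSE = sqrt(mean (pred - actual)^2),
#' R^2 = 1 - SSres/SStot.
#'
#' @param predicted,actual equal-length numeric vectors of ages (years).
#' @return A [PerformanceMetrics-class]. R^2 is NA (with a warning) when the
#'   actual ages have zero variance.
#' @export
evaluatePerformance <- function(predicted, actual) {
    if (length(predicted) != length(actual))
        stop("predicted and actual must have equal length")
    if (!length(actual)) stop("cannot evaluate an empty prediction vector")
    err <- predicted - actual
    mae <- mean(abs(err))
    rmse <- sqrt(mean(err^2))
    sstot <- sum((actual - mean(actual))^2)
    r2 <- if (sstot == 0) {
        warning("R^2 undefined: actual ages have zero variance")
        NA_real_
    } else 1 - sum(err^2) / sstot
    new("PerformanceMetrics", mae = mae, rmse = rmse, r2 = r2)
}

#' @describeIn evaluatePerformance Mean absolute error in years.
#' @param x a [PerformanceMetrics-class].
#' @export
mae <- function(x) x@mae

#' @describeIn evaluatePerformance Root-mean-square error in years.
#' @export
rmse <- function(x) x@rmse

#' @describeIn evaluatePerformance Coefficient of determination.
#' @export
r2 <- function(x) x@r2

#' Fit age-bias correction coefficients
#'
#' Ordinary least squares of predicted on chronological age in the training
#' set, `predicted ~ alpha * age + beta`. Younger subjects are typically
#' over-predicted and older subjects under-predicted (regression toward the
#' mean), giving alpha < 1.
#'
#' @param predicted training-set brain-age predictions (years). The default
#'   model pipeline supplies out-of-fold cross-validated predictions.
#' @param actual chronological ages (years).
#' @return A [BiasCoefficients-class].
#' @export
fitBiasCorrection <- function(predicted, actual) {
    if (length(predicted) != length(actual) || length(actual) < 3L)
        stop("need at least 3 paired observations to fit the correction")
    va <- stats::var(actual)
    if (!is.finite(va) || va == 0)
        stop("degenerate fit: actual ages have zero variance")
    alpha <- stats::cov(predicted, actual) / va
    beta <- mean(predicted) - alpha * mean(actual)
    new("BiasCoefficients", alpha = alpha, beta = beta)
}

#' Apply the age-bias correction
#'
#' `corrected_i = predicted_i + [age_i - (alpha * age_i + beta)]`. Note the
#' correction consumes each subject's chronological age at application time.
#'
#' @param predicted predicted brain ages (years).
#' @param actual chronological ages (years).
#' @param coeffs a [BiasCoefficients-class].
#' @return corrected brain ages (years).
#' @export
applyBiasCorrection <- function(predicted, actual, coeffs) {
    if (length(predicted) != length(actual))
        stop("predicted and actual must have equal length")
    predicted + (actual - (coeffs@alpha * actual + coeffs@beta))
}

#' @describeIn fitBiasCorrection Slope alpha.
#' @param coeffs a [BiasCoefficients-class].
#' @export
biasAlpha <- function(coeffs) coeffs@alpha

#' @describeIn fitBiasCorrection Intercept beta (years).
#' @export
biasBeta <- function(coeffs) coeffs@beta

#' @describeIn fitBrainAgeModel The model's fitted [BiasCoefficients-class].
#' @param model a [BrainAgeModel-class].
#' @export
biasCoefficients <- function(model) model@bias

#' @describeIn fitBrainAgeModel Selected regularization constant C.
#' @export
selectedCost <- function(model) model@cost

#' @describeIn fitBrainAgeModel Out-of-fold cross-validated training
#'   predictions (years).
#' @export
oofPredictions <- function(model) model@oofPredictions

#' Persist / restore a trained model
#'
#' The model is stored as a directory: `metadata.json` (version, schema,
#' hyperparameters, standardization vectors, bias coefficients, a schema
#' fingerprint) plus the serialized regressor state.
#'
#' @param model a [BrainAgeModel-class].
#' @param dir directory to create/populate.
#' @export
saveBrainAgeModel <- function(model, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    sch <- model@schema
    meta <- list(
        version = "1",
        class = "BrainAgeModel",
        schema = list(regions = regionLabels(sch),
                      hemispheres = hemisphereLabels(sch),
                      measures = measureLabels(sch)),
        schemaHash = fnv1a32(paste(featureKeys(sch), collapse = ",")),
        C = model@cost, epsilon = model@epsilon, gamma = model@gamma,
        gridScores = as.list(model@gridScores),
        featureCenter = as.list(model@featureCenter),
        featureScale = as.list(model@featureScale),
        droppedFeatures = model@droppedFeatures,
        yCenter = model@yCenter, yScale = model@yScale,
        constantTarget = model@constantTarget,
        seed = model@seed,
        bias = if (!is.null(model@bias))
            list(alpha = model@bias@alpha, beta = model@bias@beta))
    .writeJSON(meta, file.path(dir, "metadata.json"))
    saveRDS(list(fit = model@fit, oof = model@oofPredictions,
                 trainAges = model@trainAges, foldId = model@foldId),
            file.path(dir, "regressor.rds"))
    invisible(dir)
}

#' @rdname saveBrainAgeModel
#' @export
readBrainAgeModel <- function(dir) {
    metaPath <- file.path(dir, "metadata.json")
    if (!file.exists(metaPath)) stop("not a model directory: ", dir)
    meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
    if (is.null(meta$version)) stop("model metadata lacks a version field")
    state <- readRDS(file.path(dir, "regressor.rds"))
    sch <- regionSchema(meta$schema$regions, meta$schema$hemispheres,
                        meta$schema$measures)
    bias <- if (!is.null(meta$bias) && !is.null(meta$bias$alpha))
        new("BiasCoefficients", alpha = meta$bias$alpha, beta = meta$bias$beta)
    asNum <- function(v) stats::setNames(as.numeric(v), names(v))
    new("BrainAgeModel", fit = state$fit, schema = sch,
        cost = as.numeric(meta$C),
        epsilon = as.numeric(meta$epsilon), gamma = as.numeric(meta$gamma),
        gridScores = asNum(unlist(meta$gridScores)),
        featureCenter = asNum(unlist(meta$featureCenter)),
        featureScale = asNum(unlist(meta$featureScale)),
        droppedFeatures = as.character(meta$droppedFeatures),
        yCenter = meta$yCenter, yScale = meta$yScale,
        constantTarget = meta$constantTarget,
        oofPredictions = state$oof, trainAges = state$trainAges,
        foldId = state$foldId, bias = bias, seed = as.integer(meta$seed))
}

setMethod("show", "BrainAgeModel", function(object) {
    cat("BrainAgeModel (eps-insensitive RBF SVR)\n")
    if (object@constantTarget) {
        cat("  degenerate constant-target model, predicts",
            object@yCenter, "\n")
        return(invisible(NULL))
    }
    cat(sprintf("  C = %g (grid CV MAE: %s)\n", object@cost,
                paste(sprintf("%s=%.2f", names(object@gridScores),
                              object@gridScores), collapse = ", ")))
    cat(sprintf("  epsilon = %g, gamma = %.3g, %d features (%d dropped)\n",
                object@epsilon, object@gamma, length(object@featureCenter),
                length(object@droppedFeatures)))
    if (!is.null(object@bias))
        cat(sprintf("  bias correction: alpha = %.3f, beta = %.3f years\n",
                    object@bias@alpha, object@bias@beta))
})

setMethod("show", "PerformanceMetrics", function(object) {
    cat(sprintf("PerformanceMetrics: MAE %.2f y, RMSE %.2f y, R^2 %s\n",
                object@mae, object@rmse,
                ifelse(is.na(object@r2), "NA", sprintf("%.3f", object@r2))))
})

setMethod("show", "BiasCoefficients", function(object) {
    cat(sprintf("BiasCoefficients: alpha = %.4f, beta = %.4f years\n",
                object@alpha, object@beta))
})
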