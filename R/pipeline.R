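#' Default pipeline configuration
#'
#' @param outDir run output directory.
#' @param seed master seed; expanded deterministically into stage seeds
#'   (preset, train/test simulation, fold shuffling, MI jitter).
#' @param nTrain,nTest simulated cohort sizes (ignored when `trainPath` /
#'   `testPath` point at existing feature tables).
#' @param k KSG neighbour count.
#' @param grid candidate C values for the hyperparameter search.
#' @param epsilon SVR insensitivity margin (standardized target).
#' @param units `"nats"` or `"bits"` for MI output.
#' @param combineVolumes secondary combination mode (MI of summed volumes).
#' @param subgroup run the sex-subgroup stage.
#' @param trainPath,testPath optional CSV feature tables to use instead of
#'   simulation.
#' @return named list understood by [runPipeline()].
#' @export
pipelineConfig <- function(outDir = tempfile("brainage_run_"), seed = 42L,
                           nTrain = 600L, nTest = 550L, k = 3L,
                           grid = c(0.1, 1, 10, 100), epsilon = 0.1,
                           units = "nats", combineVolumes = FALSE,
                           subgroup = TRUE, trainPath = NULL,
                           testPath = NULL) {
    as.list(environment())
}

.stage <- function(name, expr) {
    t0 <- Sys.time()
    message("[", name, "] started")
    out <- tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
    message(sprintf("[%s] done in %.1f s", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    out
}

#' Run the full decoding pipeline
#'
#' Orchestrates simulate (unless input tables are given) -> train ->
#' predict/correct -> MI decoding (corrected and uncorrected targets) ->
#' sex subgroups -> summary, writing every artifact into the run directory.
#' Stages communicate only via the documented file formats, so each stage
#' function is independently runnable on a prior run's files. Identical
#' config + seed reproduce the run bit-for-bit.
#'
#' @param config a list from [pipelineConfig()], or a path to a YAML file
#'   with the same keys.
#' @return the run directory path, invisibly.
#' @export
runPipeline <- function(config = pipelineConfig()) {
    if (is.character(config)) {
        if (!file.exists(config)) stop("config file not found: ", config)
        user <- yaml::read_yaml(config)
        config <- utils::modifyList(pipelineConfig(), user)
    }
    # startup validation before any computation
    for (p in c(config$trainPath, config$testPath))
        if (!is.null(p) && !file.exists(p))
            stop("input path does not exist: ", p)
    stopifnot(config$nTrain >= 0, config$nTest >= 0, config$k >= 1)
    out <- config$outDir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    seed <- as.integer(config$seed)
    schema <- defaultRegionSchema()

    cfgTxt <- paste(deparse(config[order(names(config))]), collapse = "")
    runMeta <- list(config = config[setdiff(names(config), "outDir")],
                    configHash = fnv1a32(cfgTxt),
                    seeds = list(master = seed,
                                 preset = deriveSeed(seed, 1L),
                                 trainCohort = deriveSeed(seed, 2L),
                                 testCohort = deriveSeed(seed, 3L),
                                 folds = deriveSeed(seed, 4L),
                                 jitter = deriveSeed(seed, 5L)),
                    package = as.character(utils::packageVersion("BrainAgeMI")))
    .writeJSON(runMeta, file.path(out, "run_config.json"))

    if (is.null(config$trainPath)) {
        .stage("simulate", {
            params <- agingPreset(schema, seed = deriveSeed(seed, 1L))
            trainSim <- simulateCohort(params, schema, n = config$nTrain,
                                       seed = deriveSeed(seed, 2L))
            testSim <- simulateCohort(params, schema, n = config$nTest,
                                      seed = deriveSeed(seed, 3L))
            writeFeatureTable(trainSim$table, file.path(out, "cohort_train.csv"))
            writeFeatureTable(testSim$table, file.path(out, "cohort_test.csv"))
            .writeJSON(list(units = "dimensionless",
                            effectSizes = as.list(effectSizes(trainSim$truth))),
                       file.path(out, "truth.json"))
        })
        trainPath <- file.path(out, "cohort_train.csv")
        testPath <- file.path(out, "cohort_test.csv")
    } else {
        trainPath <- config$trainPath
        testPath <- config$testPath
    }

    train <- readFeatureTable(trainPath, schema)
    test <- readFeatureTable(testPath, schema)
    message("loaded ", ncol(train), " train / ", ncol(test),
            " test subjects x ", nrow(train), " features")

    model <- .stage("train", {
        m <- fitBrainAgeModel(train, schema, grid = config$grid,
                              epsilon = config$epsilon,
                              seed = deriveSeed(seed, 4L))
        saveBrainAgeModel(m, file.path(out, "model"))
        m
    })

    predCorr <- .stage("predict", {
        pred <- predictAge(model, test)
        corr <- applyBiasCorrection(pred, ages(test), biasCoefficients(model))
        utils::write.csv(
            data.frame(subject_id = colnames(test), age = ages(test),
                       predicted = unname(pred), corrected = unname(corr)),
            file.path(out, "predictions.csv"), row.names = FALSE)
        oof <- oofPredictions(model)
        oofCorr <- applyBiasCorrection(oof, ages(train),
                                       biasCoefficients(model))
        metrics <- list(
            train = evaluatePerformance(oof, ages(train)),
            trainCorrected = evaluatePerformance(oofCorr, ages(train)),
            test = evaluatePerformance(pred, ages(test)),
            testCorrected = evaluatePerformance(corr, ages(test)))
        .writeJSON(list(
            class = "PipelineMetrics", units = "years",
            note = "training metrics use out-of-fold cross-validated predictions",
            alpha = biasAlpha(biasCoefficients(model)),
            beta = biasBeta(biasCoefficients(model)),
            C = selectedCost(model),
            metrics = lapply(metrics, function(m)
                list(mae = mae(m), rmse = rmse(m), r2 = r2(m)))),
            file.path(out, "metrics.json"))
        list(pred = pred, corr = corr)
    })

    .stage("decode-mi", {
        prof <- miProfile(test, unname(predCorr$corr), k = config$k,
                          seed = deriveSeed(seed, 5L), units = config$units,
                          combineVolumes = isTRUE(config$combineVolumes))
        writeResults(prof, file.path(out, "mi_profile.json"))
        profU <- miProfile(test, unname(predCorr$pred), k = config$k,
                           seed = deriveSeed(seed, 5L), units = config$units)
        writeResults(profU, file.path(out, "mi_profile_uncorrected.json"))
    })

    if (isTRUE(config$subgroup)) .stage("subgroup", {
        sg <- subgroupReport(test, model, k = config$k,
                             seed = deriveSeed(seed, 6L))
        res <- subgroupResults(sg)
        .writeJSON(list(
            class = "SubgroupComparison", units = config$units,
            subgroups = lapply(res, function(s) list(
                n = s$n, totalMI = s$totalMI,
                measureTotals = as.list(measureTotals(s$profile)),
                metricsBefore = list(mae = mae(s$metricsBefore),
                                     rmse = rmse(s$metricsBefore),
                                     r2 = r2(s$metricsBefore)),
                metricsAfter = list(mae = mae(s$metricsAfter),
                                    rmse = rmse(s$metricsAfter),
                                    r2 = r2(s$metricsAfter)))),
            comparisons = rankComparisons(sg)),
            file.path(out, "subgroup.json"))
    })

    .stage("summary", summarizeRun(out))
    invisible(out)
}

#' Summarize a completed run directory
#'
#' Tabulates model performance before/after bias correction, per-measure MI
#' totals, the top-10 regions for each measure and combination, and the
#' subgroup Spearman comparisons (omitted gracefully when that stage was
#' skipped). Writes `summary.md` into the run directory and returns its
#' lines invisibly.
#'
#' @param dir a run directory produced by [runPipeline()].
#' @export
summarizeRun <- function(dir) {
    if (!dir.exists(dir) || !length(list.files(dir)))
        stop("not a run directory (empty or missing): ", dir)
    need <- c("run_config.json", "metrics.json", "mi_profile.json")
    missing <- need[!file.exists(file.path(dir, need))]
    if (length(missing))
        stop("incomplete run; missing artifact(s): ",
             paste(missing, collapse = ", "))
    met <- jsonlite::read_json(file.path(dir, "metrics.json"),
                               simplifyVector = TRUE)
    prof <- readResults(file.path(dir, "mi_profile.json"))

    L <- c("# Brain-age MI decoding run summary", "")
    L <- c(L, sprintf("- features: %d; regions: %d; MI units: %s; k = %d",
                      length(featureMI(prof)), nrow(regionMI(prof)),
                      prof@units, prof@k))
    L <- c(L, sprintf("- selected C = %g; bias correction alpha = %.3f, beta = %.3f years",
                      met$C, met$alpha, met$beta), "")
    L <- c(L, "## Model performance (before -> after age-bias correction)", "")
    fmt <- function(nmB, nmA, label) {
        b <- met$metrics[[nmB]]; a <- met$metrics[[nmA]]
        sprintf("- %s: MAE %.2f -> %.2f y; RMSE %.2f -> %.2f y; R^2 %.3f -> %.3f",
                label, b$mae, a$mae, b$rmse, a$rmse, b$r2, a$r2)
    }
    L <- c(L, fmt("train", "trainCorrected", "train (out-of-fold)"),
           fmt("test", "testCorrected", "test"), "")
    L <- c(L, "## Mutual information totals (corrected brain age)", "")
    tot <- measureTotals(prof)
    L <- c(L, paste0("- ", names(tot), ": ", sprintf("%.2f", tot)))
    L <- c(L, sprintf("- all features: %.2f %s", totalMI(prof), prof@units))
    uPath <- file.path(dir, "mi_profile_uncorrected.json")
    if (file.exists(uPath)) {
        profU <- readResults(uPath)
        L <- c(L, sprintf("- all features vs uncorrected brain age: %.2f %s",
                          totalMI(profU), profU@units))
    }
    L <- c(L, "", "## Top-10 regions")
    for (what in names(prof@topRegions)) {
        vals <- if (what %in% colnames(regionMI(prof)))
            regionMI(prof)[, what] else comboMI(prof)[, what]
        top <- topRegions(prof, what)
        L <- c(L, "", sprintf("### %s", what), "",
               sprintf("%2d. %s (%.3f)", seq_along(top), top,
                       vals[top]))
    }
    sgPath <- file.path(dir, "subgroup.json")
    if (file.exists(sgPath)) {
        sg <- jsonlite::read_json(sgPath, simplifyVector = TRUE)
        L <- c(L, "", "## Sex subgroups", "")
        for (nm in names(sg$subgroups)) {
            s <- sg$subgroups[[nm]]
            L <- c(L, sprintf("- %s: n = %d, total MI = %.2f, corrected MAE = %.2f y",
                              nm, s$n, s$totalMI, s$metricsAfter$mae))
        }
        cmp <- sg$comparisons
        amm <- cmp[cmp$scope == "all_measures", , drop = FALSE]
        L <- c(L, "", sprintf("- %s vs %s (all measures): rho = %.3f, p = %.3g",
                              amm$groupA, amm$groupB, amm$rho, amm$p))
    }
    writeLines(L, file.path(dir, "summary.md"))
    invisible(L)
}
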