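test_that("simulation is reproducible from the seed and varies across seeds", {
    sch <- defaultRegionSchema()
    params <- agingPreset(sch)
    a <- simulateCohort(params, sch, n = 25, seed = 11)
    b <- simulateCohort(params, sch, n = 25, seed = 11)
    c <- simulateCohort(params, sch, n = 25, seed = 12)
    expect_identical(SummarizedExperiment::assay(a$table),
                     SummarizedExperiment::assay(b$table))
    expect_identical(ages(a$table), ages(b$table))
    expect_false(identical(SummarizedExperiment::assay(a$table),
                           SummarizedExperiment::assay(c$table)))
})

test_that("empty cohorts and bad parameters are handled", {
    sch <- tinySchema()
    params <- agingPreset(sch)
    sim <- simulateCohort(params, sch, n = 0)
    expect_equal(ncol(sim$table), 0L)
    expect_length(effectSizes(sim$truth), nFeatures(sch))
    expect_error(simulateCohort(params, sch, n = -3), "parameter error")
    badParams <- params
    badParams@features$noiseSd[1] <- -1
    expect_error(simulateCohort(badParams, sch), "parameter error")
    expect_error(methods::validObject(badParams), "noise sd")
})

test_that("noiseless linear features correlate perfectly with age", {
    sch <- tinySchema(measures = "GMV", regions = "insula")
    keys <- featureKeys(sch)
    params <- new("TrajectoryParams",
        features = data.frame(parseFeatureKeys(keys), baseline = 8000,
                              slope = -25, quad = 0, sexOffset = 0,
                              noiseSd = 0, unit = "mm3",
                              stringsAsFactors = FALSE),
        ageRange = c(18, 88), sexRatio = 0.5, n = 60L, seed = 4L)
    sim <- simulateCohort(params, sch)
    x <- SummarizedExperiment::assay(sim$table)[1, ]
    expect_equal(cor(x, ages(sim$table)), -1, tolerance = 1e-12)
})

test_that("at zero noise each feature is the exact deterministic trajectory", {
    sch <- tinySchema()
    params <- agingPreset(sch)
    params@features$noiseSd[] <- 0
    sim <- simulateCohort(params, sch, n = 30, seed = 8)
    tab <- sim$table
    f <- params@features[match(featureKeys(sch), params@features$key), ]
    age <- ages(tab)
    male <- as.numeric(sexes(tab) == "male")
    for (i in sample(nrow(f), 6)) {
        expected <- pmax(f$baseline[i] + f$slope[i] * age +
                         f$quad[i] * age^2 + f$sexOffset[i] * male,
                         0.01 * f$baseline[i])
        expect_equal(unname(SummarizedExperiment::assay(tab)[f$key[i], ]),
                     expected, tolerance = 1e-12)
    }
})

test_that("doubling a slope strictly increases the planted effect size", {
    sch <- defaultRegionSchema()
    params <- agingPreset(sch)
    picks <- c("pre_central_gyrus__left__GMV", "insula__right__WMV",
               "cingulate__left__CSF", "precuneus__right__CT")
    base <- effectSizes(syntheticTruth(params, sch))
    doubled <- params
    doubled@features$slope[doubled@features$key %in% picks] <-
        2 * doubled@features$slope[doubled@features$key %in% picks]
    eff2 <- effectSizes(syntheticTruth(doubled, sch))
    for (k in picks) expect_gt(eff2[[k]], base[[k]])
})

test_that("volumes are truncated at the positive floor under extreme noise", {
    sch <- tinySchema(measures = "GMV", regions = "insula")
    keys <- featureKeys(sch)
    params <- new("TrajectoryParams",
        features = data.frame(parseFeatureKeys(keys), baseline = 1000,
                              slope = 0, quad = 0, sexOffset = 0,
                              noiseSd = 1e5, unit = "mm3",
                              stringsAsFactors = FALSE),
        ageRange = c(18, 88), sexRatio = 0.5, n = 200L, seed = 2L)
    m <- SummarizedExperiment::assay(simulateCohort(params, sch)$table)
    expect_true(all(m >= 10))     # 1% of baseline
    expect_true(any(m == 10))     # the floor actually engaged
})

test_that("the optional head-size factor couples volumes across features", {
    sch <- tinySchema(measures = c("GMV", "CT"))
    resid <- function(tab, key) {
        v <- SummarizedExperiment::assay(tab)[key, ]
        stats::residuals(lm(v ~ ages(tab) + I(sexes(tab) == "male")))
    }
    indep <- simulateCohort(agingPreset(sch), sch, n = 400, seed = 6)$table
    coupled <- simulateCohort(agingPreset(sch, globalScaleSd = 0.15), sch,
                              n = 400, seed = 6)$table
    k1 <- "insula__left__GMV"; k2 <- "cingulate__right__GMV"
    expect_lt(abs(cor(resid(indep, k1), resid(indep, k2))), 0.15)
    expect_gt(cor(resid(coupled, k1), resid(coupled, k2)), 0.4)
    # CT is not volume-scaled
    expect_lt(abs(cor(resid(coupled, "insula__left__CT"),
                      resid(coupled, k2))), 0.2)
})

test_that("the null preset plants zero effect everywhere", {
    sch <- tinySchema()
    params <- agingPreset(sch, effectScale = 0)
    expect_true(all(effectSizes(syntheticTruth(params, sch)) == 0))
})

test_that("the default preset plants the flagship regions at rank 1", {
    sch <- defaultRegionSchema()
    truth <- simulateCohort(agingPreset(sch), sch, n = 0)$truth
    expect_equal(truthRanking(truth, "GMV")[1], "pre_central_gyrus")
    expect_equal(truthRanking(truth, "CSF")[1], "cingulate")
    expect_equal(truthRanking(truth, "CT")[1], "superior_temporal_gyrus")
    expect_equal(truthRanking(truth, "WMV")[1], "insula")
    # parenchyma (GMV+WMV merged effects) peaks in the superior frontal gyrus
    paren <- truth@regionEffects[, "GMV"] + truth@regionEffects[, "WMV"]
    expect_equal(names(which.max(paren)), "superior_frontal_gyrus")
    # aging-consistent signs in the default preset
    params <- agingPreset(sch)
    f <- params@features
    expect_true(all(f$slope[f$measure == "GMV"] <= 0))
    expect_true(all(f$slope[f$measure == "CT"] <= 0))
    expect_true(all(f$slope[f$measure == "CSF"] >= 0))
})

test_that("reversed presets plant the opposite region order", {
    sch <- defaultRegionSchema()
    fwd <- syntheticTruth(agingPreset(sch), sch)
    bwd <- syntheticTruth(agingPreset(sch, reverse = TRUE), sch)
    for (m in c("GMV", "WMV", "CSF", "CT")) {
        rho <- cor(fwd@regionEffects[, m], bwd@regionEffects[, m],
                   method = "spearman")
        expect_lt(rho, -0.95)
    }
})
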