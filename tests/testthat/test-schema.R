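test_that("default schema yields the 33 x 2 x 4 = 264 feature layout", {
    sch <- defaultRegionSchema()
    keys <- featureKeys(sch)
    expect_length(regionLabels(sch), 33L)
    expect_length(keys, 264L)
    expect_false(anyDuplicated(keys) > 0)
    info <- parseFeatureKeys(keys)
    expect_equal(nrow(unique(info[c("region", "hemisphere")])), 66L)
    expect_setequal(unique(info$measure), c("GMV", "WMV", "CSF", "CT"))
    # deterministic nesting: region slowest, then hemisphere, then measure
    expect_equal(keys[1:4], paste0("superior_frontal_gyrus__left__",
                                   c("GMV", "WMV", "CSF", "CT")))
    expect_equal(info$hemisphere[5], "right")
})

test_that("feature count is conserved for arbitrary sub-schemas", {
    sch <- defaultRegionSchema()
    cases <- list(
        list(r = 5, h = c("left", "right"), m = c("GMV", "CT")),
        list(r = 1, h = "left", m = "GMV"),
        list(r = 12, h = c("left", "right"), m = c("GMV", "WMV", "CSF", "CT")))
    for (cs in cases) {
        sub <- subSchema(sch, regions = regionLabels(sch)[seq_len(cs$r)],
                         hemispheres = cs$h, measures = cs$m)
        expect_equal(nFeatures(sub), cs$r * length(cs$h) * length(cs$m))
        expect_length(featureKeys(sub), nFeatures(sub))
    }
    expect_error(subSchema(sch, regions = "not_a_region"), "unknown region")
})

test_that("schema invariants are enforced", {
    expect_error(regionSchema(regions = c("a", "a", "b")), "unique")
    expect_error(regionSchema(measures = c("GMV", "BAD")), "drawn from")
    sub <- tinySchema(measures = "GMV")
    expect_equal(unname(measureUnits(sub)["GMV"]), "mm3")
})

test_that("schema config files round-trip through YAML", {
    path <- withr::local_tempfile(fileext = ".yaml")
    writeLines(yaml::as.yaml(list(regions = c("insula", "cingulate"),
                                  measures = c("GMV", "CSF"))), path)
    sch <- readRegionSchema(path)
    expect_equal(regionLabels(sch), c("insula", "cingulate"))
    expect_equal(nFeatures(sch), 2 * 2 * 2)
})

test_that("feature tables survive a CSV write/read round trip", {
    sch <- tinySchema()
    tab <- linearCohort(10, sch, noiseSd = 5)
    path <- withr::local_tempfile(fileext = ".csv")
    writeFeatureTable(tab, path)
    back <- readFeatureTable(path, sch)
    expect_s4_class(back, "MorphometryExperiment")
    expect_equal(SummarizedExperiment::assay(back), SummarizedExperiment::assay(tab))
    expect_equal(ages(back), ages(tab))
    expect_equal(sexes(back), sexes(tab))
    expect_equal(subjectIds(back), subjectIds(tab))
})

test_that("schema mismatches on load name the offending column", {
    sch <- tinySchema()
    tab <- linearCohort(5, sch)
    path <- withr::local_tempfile(fileext = ".csv")
    writeFeatureTable(tab, path)
    df <- utils::read.csv(path, check.names = FALSE)

    dropped <- df[, setdiff(names(df), "insula__left__GMV")]
    p2 <- withr::local_tempfile(fileext = ".csv")
    utils::write.csv(dropped, p2, row.names = FALSE)
    expect_error(readFeatureTable(p2, sch), "insula__left__GMV")

    extra <- df
    extra$bogus__left__GMV <- 1
    p3 <- withr::local_tempfile(fileext = ".csv")
    utils::write.csv(extra, p3, row.names = FALSE)
    expect_error(readFeatureTable(p3, sch), "bogus__left__GMV")
})

test_that("non-positive volumes are rejected with the subject id", {
    sch <- tinySchema()
    tab <- linearCohort(5, sch)
    path <- withr::local_tempfile(fileext = ".csv")
    writeFeatureTable(tab, path)
    df <- utils::read.csv(path, check.names = FALSE)
    df[3, "cingulate__right__CSF"] <- -10
    utils::write.csv(df, path, row.names = FALSE)
    expect_error(readFeatureTable(path, sch), "t003")
})

test_that("a header-only file gives a valid empty table", {
    sch <- tinySchema()
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(paste(c("subject_id", "age", "sex", featureKeys(sch)),
                     collapse = ","), path)
    tab <- readFeatureTable(path, sch)
    expect_equal(ncol(tab), 0L)
    expect_equal(nrow(tab), nFeatures(sch))
})

test_that("assembleFeatureMatrix is deterministic and schema-shaped", {
    sch <- defaultRegionSchema()
    tab <- presetCohort(8, seed = 5)$table
    am <- assembleFeatureMatrix(tab)
    expect_equal(dim(am$matrix), c(8L, 264L))
    expect_identical(colnames(am$matrix), featureKeys(sch))

    single <- subSchema(sch, regions = "insula", hemispheres = "left",
                        measures = "GMV")
    stab <- linearCohort(6, single)
    expect_equal(ncol(assembleFeatureMatrix(stab)$matrix), 1L)

    path <- withr::local_tempfile(fileext = ".csv")
    writeFeatureTable(tab, path)
    a1 <- assembleFeatureMatrix(readFeatureTable(path, sch))
    a2 <- assembleFeatureMatrix(readFeatureTable(path, sch))
    expect_identical(a1, a2)
})

test_that("results serialization round-trips exactly", {
    tab <- presetCohort(40, seed = 9)$table
    prof <- miProfile(tab, unname(ages(tab)) + rnorm(40), k = 3, seed = 2)
    path <- withr::local_tempfile(fileext = ".json")
    writeResults(prof, path)
    back <- readResults(path)
    expect_identical(featureMI(back), featureMI(prof))
    expect_identical(regionMI(back), regionMI(prof))
    expect_identical(comboMI(back), comboMI(prof))
    expect_identical(measureTotals(back), measureTotals(prof))
    expect_identical(tertiles(back), tertiles(prof))
    expect_identical(back@topRegions, prof@topRegions)
    expect_identical(back@k, prof@k)
    expect_identical(back@units, prof@units)

    pm <- evaluatePerformance(c(30, 40, 50), c(20, 40, 60))
    p2 <- withr::local_tempfile(fileext = ".json")
    writeResults(pm, p2)
    pmb <- readResults(p2)
    expect_identical(mae(pmb), mae(pm))
    expect_identical(rmse(pmb), rmse(pm))
    expect_identical(r2(pmb), r2(pm))
})

test_that("results writing to an unwritable path raises an I/O error", {
    pm <- evaluatePerformance(1:3, c(1, 2, 4))
    expect_error(writeResults(pm, "/nonexistent-dir/x.json"), "I/O error")
})

test_that("an empty MI profile serializes to a valid file", {
    empty <- new("MIProfile",
                 featureMI = stats::setNames(numeric(0), character(0)),
                 rawMI = stats::setNames(numeric(0), character(0)),
                 regionMI = matrix(numeric(0), 0, 0),
                 comboMI = matrix(numeric(0), 0, 0),
                 measureTotals = stats::setNames(numeric(0), character(0)),
                 tertiles = matrix(character(0), 0, 0),
                 topRegions = list(), k = 3L, n = 10L, seed = 1L,
                 units = "nats")
    path <- withr::local_tempfile(fileext = ".json")
    writeResults(empty, path)
    back <- readResults(path)
    expect_length(featureMI(back), 0L)
    expect_identical(back@units, "nats")
})
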