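test_that("a full-schema profile has the expected shape and conservation", {
    sim <- presetCohort(120, seed = 44)
    tab <- sim$table
    target <- ages(tab) + rnorm(120, 0, 3)   # age-like target
    prof <- miProfile(tab, unname(target), k = 3, seed = 6)

    expect_length(featureMI(prof), 264L)
    expect_equal(dim(regionMI(prof)), c(33L, 4L))
    expect_equal(colnames(comboMI(prof)), c("parenchyma", "intracranial"))

    # merged region value = left MI + right MI, exactly
    fmi <- featureMI(prof)
    for (key in sample(rownames(regionMI(prof)), 5)) {
        for (m in colnames(regionMI(prof))) {
            expect_identical(regionMI(prof)[key, m],
                             fmi[[paste(key, "left", m, sep = "__")]] +
                             fmi[[paste(key, "right", m, sep = "__")]])
        }
    }
    # per-measure totals are the sums of their merged region values
    expect_identical(measureTotals(prof), colSums(regionMI(prof)))
    expect_identical(totalMI(prof), sum(featureMI(prof)))
    # intracranial = GMV + WMV + CSF and parenchyma = GMV + WMV per region
    expect_equal(comboMI(prof)[, "parenchyma"],
                 rowSums(regionMI(prof)[, c("GMV", "WMV")]))
    expect_equal(comboMI(prof)[, "intracranial"],
                 rowSums(regionMI(prof)[, c("GMV", "WMV", "CSF")]))
    # tertiles partition 33 regions into 11/11/11 in every column
    for (j in seq_len(ncol(tertiles(prof))))
        expect_equal(as.integer(table(tertiles(prof)[, j])[c("highest", "middle", "lowest")]),
                     c(11L, 11L, 11L))
})

test_that("an independent target drives merged MI to zero", {
    sim <- presetCohort(600, seed = 45)
    target <- withr::with_seed(99, rnorm(600, 50, 15))
    prof <- miProfile(sim$table, target, k = 3, seed = 2)
    # per-feature clipping at zero makes each merged null value the sum of
    # two half-rectified estimates, so the null ceiling sits slightly above
    # the raw estimator's sampling noise
    expect_true(all(regionMI(prof) <= 0.15))
    expect_lt(mean(regionMI(prof)), 0.05)
    expect_lt(abs(mean(prof@rawMI)), 0.01)  # raw estimator centred on zero
})

test_that("subject misalignment and tiny samples are rejected", {
    tab <- presetCohort(20, seed = 3)$table
    expect_error(miProfile(tab, rnorm(19)), "misaligned")
    wrongNames <- stats::setNames(rnorm(20), paste0("x", 1:20))
    expect_error(miProfile(tab, wrongNames), "misaligned")
    expect_error(miProfile(tab[, 1:3], rnorm(3), k = 3), "n > k")
})

test_that("hemisphere merging requires and uses both hemispheres", {
    sch <- tinySchema(measures = c("GMV", "CSF"),
                      regions = c("insula", "cingulate"))
    keys <- featureKeys(sch)
    vals <- stats::setNames(seq(0.1, by = 0.1, length.out = length(keys)),
                            keys)
    merged <- aggregateHemispheres(vals, sch)
    expect_equal(merged["insula", "GMV"],
                 vals[["insula__left__GMV"]] + vals[["insula__right__GMV"]])
    expect_error(aggregateHemispheres(vals[-1], sch), "missing hemisphere")
    zero <- stats::setNames(rep(0, length(keys)), keys)
    expect_true(all(aggregateHemispheres(zero, sch) == 0))
})

test_that("measure combinations sum their members", {
    rm <- matrix(c(0.5, 0.3, 0.4, 0.2), 1, 4,
                 dimnames = list("insula", c("GMV", "WMV", "CSF", "CT")))
    expect_equal(unname(aggregateMeasures(rm, parenchymaCombination())), 0.8)
    expect_equal(unname(aggregateMeasures(rm, intracranialCombination())), 1.2)
    expect_error(aggregateMeasures(rm, "parenchyma"), "unknown combination")
    expect_error(aggregateMeasures(rm[, 1:2, drop = FALSE],
                                   intracranialCombination()), "CSF")
})

test_that("ranking and tertiles follow the tie and partition rules", {
    labs <- sort(regionLabels(defaultRegionSchema()))
    distinct <- stats::setNames(sample(seq(1, 33)), labs)
    rt <- rankAndTertile(distinct)
    expect_equal(as.integer(table(rt$tertile)[c("highest", "middle", "lowest")]),
                 c(11L, 11L, 11L))
    expect_equal(rt$ranking[1], names(which.max(distinct)))

    equal <- stats::setNames(rep(1, 33), labs)
    rtEq <- rankAndTertile(equal)
    expect_equal(rtEq$ranking, labs)  # alphabetical under total ties
    expect_equal(as.integer(table(rtEq$tertile)[c("highest", "middle", "lowest")]),
                 c(11L, 11L, 11L))

    desc <- stats::setNames(33:1, labs)
    expect_equal(rankAndTertile(desc)$top[1], labs[1])
    expect_length(rankAndTertile(desc)$top, 10L)
    expect_error(rankAndTertile(desc[1:10]), "expected 33")
})

test_that("merged region MI is stable under log-transforming volumes", {
    sim <- presetCohort(600, seed = 46)
    tab <- sim$table
    target <- ages(tab) + withr::with_seed(1, rnorm(600, 0, 3))
    prof <- miProfile(tab, unname(target), k = 3, seed = 9)

    m2 <- SummarizedExperiment::assay(tab)
    volRows <- !grepl("__CT$", rownames(m2))
    m2[volRows, ] <- log(m2[volRows, ])  # strictly monotone, stays positive
    tab2 <- MorphometryExperiment(m2, ages(tab), sexes(tab), schemaOf(tab))
    prof2 <- miProfile(tab2, unname(target), k = 3, seed = 9)
    expect_lt(max(abs(regionMI(prof) - regionMI(prof2))), 0.05)
})

test_that("bits output rescales nats by log(2)", {
    tab <- presetCohort(40, seed = 12)$table
    tn <- miProfile(tab, unname(ages(tab)), k = 3, seed = 1, units = "nats")
    tb <- miProfile(tab, unname(ages(tab)), k = 3, seed = 1, units = "bits")
    expect_equal(featureMI(tb), featureMI(tn) / log(2), tolerance = 1e-12)
})

test_that("the secondary combined-volume mode produces its own MI values", {
    sim <- presetCohort(80, seed = 13)
    target <- unname(ages(sim$table))
    p1 <- miProfile(sim$table, target, k = 3, seed = 1)
    p2 <- miProfile(sim$table, target, k = 3, seed = 1,
                    combineVolumes = TRUE)
    expect_false(identical(comboMI(p1), comboMI(p2)))
    expect_identical(regionMI(p1), regionMI(p2))
    expect_true(all(comboMI(p2) >= 0))
})
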