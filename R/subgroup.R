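#' Split a cohort by sex
#'
#' @param table a [MorphometryExperiment-class].
#' @return list with elements `male` and `female`, a disjoint exhaustive
#'   partition of the input subjects (schema preserved).
#' @export
splitBySex <- function(table) {
    sex <- sexes(table)
    bad <- is.na(sex) | !sex %in% c("male", "female")
    if (any(bad))
        stop("missing/uncoded sex for subject(s): ",
             paste(utils::head(colnames(table)[bad], 10), collapse = ", "))
    list(male = table[, sex == "male"], female = table[, sex == "female"])
}

#' Compare two region MI rankings
#'
#' Spearman rank correlation (average ranks for ties) with a two-sided
#' p-value from the t approximation.
#'
#' @param profileA,profileB named numeric vectors of per-region MI values
#'   over the same region set.
#' @return list with `rho`, `p` and `significant` (at the 0.05 level).
#' @export
compareMIRankings <- function(profileA, profileB) {
    if (is.null(names(profileA)) || is.null(names(profileB)) ||
        !setequal(names(profileA), names(profileB)) ||
        length(profileA) != length(profileB))
        stop("mismatched regions between the two profiles")
    b <- profileB[names(profileA)]
    ct <- suppressWarnings(
        stats::cor.test(profileA, b, method = "spearman", exact = FALSE))
    list(rho = unname(ct$estimate), p = ct$p.value,
         significant = ct$p.value < 0.05)
}

#' Sex-subgroup decoding report
#'
#' Predicts and bias-corrects brain age on the full test cohort with a
#' single pre-trained model (training-set bias coefficients are reused, not
#' refit per subgroup), splits by sex, and re-evaluates per subgroup: model
#' performance before/after correction, the full MI profile against the
#' corrected brain age, and the total MI. Region MI rankings are then
#' compared pairwise (male vs female, male vs all, female vs all) by
#' Spearman correlation, per measure, per combination, and on the
#' all-measure merged profile.
#'
#' @param test a [MorphometryExperiment-class] test cohort.
#' @param model a trained [BrainAgeModel-class] with fitted bias
#'   coefficients.
#' @param k KSG neighbour count.
#' @param seed integer seed (expanded per subgroup).
#' @return A [SubgroupComparison-class].
#' @export
subgroupReport <- function(test, model, k = 3L, seed = 1L) {
    if (is.null(model@bias))
        stop("model has no fitted bias coefficients")
    pred <- predictAge(model, test)
    corr <- applyBiasCorrection(pred, ages(test), model@bias)
    halves <- splitBySex(test)
    groups <- c(halves, list(all = test))
    for (nm in c("male", "female")) {
        ng <- ncol(groups[[nm]])
        if (ng == 0L) stop("empty ", nm, " subgroup: cannot analyse")
        if (ng <= k) stop(nm, " subgroup too small for MI (n = ", ng,
                          " <= k = ", k, ")")
    }
    subgroups <- list()
    for (gi in seq_along(groups)) {
        g <- groups[[gi]]
        ids <- colnames(g)
        p <- pred[ids]
        cr <- corr[ids]
        prof <- miProfile(g, unname(cr), k = k, seed = deriveSeed(seed, gi))
        subgroups[[names(groups)[gi]]] <- list(
            n = ncol(g),
            metricsBefore = evaluatePerformance(p, ages(g)),
            metricsAfter = evaluatePerformance(cr, ages(g)),
            profile = prof,
            totalMI = totalMI(prof))
    }
    scopes <- c(colnames(regionMI(subgroups$all$profile)),
                colnames(comboMI(subgroups$all$profile)), "all_measures")
    scopeValues <- function(prof, scope) {
        if (scope == "all_measures") return(rowSums(regionMI(prof)))
        cm <- comboMI(prof)
        if (scope %in% colnames(cm)) cm[, scope] else regionMI(prof)[, scope]
    }
    pairs <- list(c("male", "female"), c("male", "all"), c("female", "all"))
    rows <- list()
    for (pr in pairs) for (sc in scopes) {
        cmp <- compareMIRankings(
            scopeValues(subgroups[[pr[1]]]$profile, sc),
            scopeValues(subgroups[[pr[2]]]$profile, sc))
        rows[[length(rows) + 1L]] <- data.frame(
            groupA = pr[1], groupB = pr[2], scope = sc,
            rho = cmp$rho, p = cmp$p, significant = cmp$significant,
            stringsAsFactors = FALSE)
    }
    new("SubgroupComparison", subgroups = subgroups,
        comparisons = do.call(rbind, rows))
}

#' @describeIn subgroupReport Per-subgroup results list.
#' @param x a [SubgroupComparison-class].
#' @export
subgroupResults <- function(x) x@subgroups

#' @describeIn subgroupReport Pairwise Spearman comparison table.
#' @export
rankComparisons <- function(x) x@comparisons

setMethod("show", "SubgroupComparison", function(object) {
    cat("SubgroupComparison\n")
    for (nm in names(object@subgroups)) {
        s <- object@subgroups[[nm]]
        cat(sprintf("  %-6s n = %3d  total MI %.2f  MAE %.2f -> %.2f y\n",
                    nm, s$n, s$totalMI, mae(s$metricsBefore),
                    mae(s$metricsAfter)))
    }
    mvf <- subset(object@comparisons,
                  object@comparisons$groupA == "male" &
                  object@comparisons$groupB == "female" &
                  object@comparisons$scope == "all_measures")
    if (nrow(mvf))
        cat(sprintf("  male vs female (all measures): rho = %.3f, p = %.3g\n",
                    mvf$rho, mvf$p))
})
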