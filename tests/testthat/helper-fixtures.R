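# Shared fixtures, all generated in code.

tinySchema <- function(measures = c("GMV", "WMV", "CSF", "CT"),
                       regions = c("insula", "cingulate", "precuneus")) {
    regionSchema(regions = regions, measures = measures)
}

# Cohort in which every feature is an exact linear function of age (plus an
# optional iid Gaussian noise), built directly without the preset machinery.
linearCohort <- function(n = 200, schema = tinySchema(), slope = -30,
                         baseline = 8000, noiseSd = 0, seed = 1,
                         ageRange = c(20, 80)) {
    set.seed(seed)
    age <- runif(n, ageRange[1], ageRange[2])
    sex <- rep(c("male", "female"), length.out = n)
    keys <- featureKeys(schema)
    m <- matrix(0, length(keys), n, dimnames = list(keys, NULL))
    for (i in seq_along(keys)) {
        sl <- slope * (1 + 0.1 * (i - 1))  # distinct slope per feature
        m[i, ] <- baseline + sl * age + rnorm(n, 0, noiseSd)
    }
    m <- pmax(m, 1)
    colnames(m) <- sprintf("t%03d", seq_len(n))
    MorphometryExperiment(m, age = age, sex = sex, schema = schema)
}

# Default aging-preset cohort at a given size (shared across tests).
presetCohort <- function(n, seed, schema = defaultRegionSchema(), ...) {
    params <- agingPreset(schema, ...)
    simulateCohort(params, schema, n = n, seed = seed)
}
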