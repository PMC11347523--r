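# Evaluate expr with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Polynomial rolling hash (mod 2^31 - 1) of a character scalar; used only to
# fingerprint configs/schemas in run artifacts. Returns an 8-hex-digit string.
fnv1a32 <- function(x) {
    bytes <- utf8ToInt(paste(x, collapse = "\n"))
    h <- 2166136261 %% 2147483647
    for (b in bytes) h <- (h * 31 + b) %% 2147483647
    sprintf("%08x", h)
}

# Deterministic sub-seed derivation: keep everything below 2^31.
deriveSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) * 1000 + offset) %% .Machine$integer.max)
}
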