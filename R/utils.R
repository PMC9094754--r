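# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All randomness in the package flows through this, so a single user-facing
# seed makes every generator reproducible in isolation.
.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Deterministic sub-seed derivation: sub-generator `k` of a study seeded with
# `seed` draws from seed*1000003 + k reduced into 32-bit integer range.
.subSeed <- function(seed, k) {
    as.integer((as.numeric(seed) * 1000003 + as.numeric(k)) %% 2147483647)
}

.msg <- function(verbose, ...) if (isTRUE(verbose)) message(...)
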