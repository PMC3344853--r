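## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit({
        if (had) assign(".Random.seed", old, envir = genv)
        else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv)
    })
    set.seed(seed)
    code
}

## Derive a stream-specific 31-bit sub-seed from a base seed.
subSeed <- function(seed, stream) {
    (as.integer(seed) %% 100003L) * 7919L + match(
        stream, c("truth", "evidence", "panel", "phenotype", "sampling")) * 104729L
}
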