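# Evaluate expr under a local RNG seed, restoring global RNG state after.
.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv()))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}
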