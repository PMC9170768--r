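# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's .Random.seed afterwards, so seeded helpers do not perturb the
# global stream.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        set.seed(seed)
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
    }
    force(expr)
}

# largest-remainder apportionment of n items into parts with the given
# fractions; ties broken in argument order
largestRemainder <- function(n, fractions) {
    raw <- n * fractions
    base <- floor(raw)
    rem <- n - sum(base)
    if (rem > 0) {
        ord <- order(raw - base, decreasing = TRUE)
        base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
    }
    as.integer(base)
}
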