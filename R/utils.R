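## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG state afterwards. All package-level randomness flows
## through explicit seeds via this helper; nothing perturbs the global stream.
.with_seed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## sequences -> 0-based index matrix (n x L) for the C++ core
.seq_index_matrix <- function(sequences) {
    n <- length(sequences)
    L <- nchar(sequences[1L])
    m <- matrix(0L, nrow = n, ncol = L)
    for (i in seq_len(n)) {
        idx <- .seq_to_idx(sequences[i])
        if (anyNA(idx) || length(idx) != L)
            stop("invalid sequence at record ", i, ": '", sequences[i], "'")
        m[i, ] <- idx - 1L
    }
    m
}
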