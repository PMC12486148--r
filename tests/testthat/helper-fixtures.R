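# Shared fixtures, built lazily and cached for the whole test session.
# The "bench" objects are the standard synthetic benchmark: default landscape
# (6 couplings, weight scale 2, offset -40, noise sd 0.5), 20 000 records,
# 80/10/10 split. Trained surrogates on it are expensive, so each
# architecture is trained at most once per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
    if (is.null(.fixture_cache[[key]]))
        assign(key, builder(), envir = .fixture_cache)
    .fixture_cache[[key]]
}

bench_landscape <- function() cached("bench_ls", function()
    makeLandscape(seed = 101, label = "bench"))

bench_splits <- function() cached("bench_splits", function() {
    tab <- generateDataset(bench_landscape(), n = 20000, seed = 202)
    splitScoreTable(tab, seed = 303)
})

bench_model <- function(arch = "lstm") {
    cached(paste0("bench_", arch), function() {
        parts <- bench_splits()
        trainSurrogate(parts$train, parts$validation,
                       toyProfile(arch, seed = 7, epochs = 25L))
    })
}

# tiny additive landscape over full alphabet, L = 3: 8000 enumerable states
toy_landscape <- function(seed = 11) {
    makeLandscape(seed = seed, length = 3L, nCouplings = 1L, weightScale = 2,
                  offset = -40, noiseSigma = 0, label = "toy3")
}

# enumerate all sequences over `letters` at length L, return data.frame
enumerate_space <- function(ls, letters = aaAlphabet(), L = nrow(ls@positionWeights)) {
    grid <- do.call(expand.grid,
                    c(rep(list(letters), L), stringsAsFactors = FALSE))
    seqs <- do.call(paste0, grid)
    data.frame(sequence = seqs, score = oracleScore(ls, seqs),
               stringsAsFactors = FALSE)
}

random_peptides <- function(n, length = 12L, seed = 1) {
    withr::with_seed(seed, randomPeptide(n, length))
}
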