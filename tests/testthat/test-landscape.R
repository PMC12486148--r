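test_that("degenerate landscape scores every peptide at the offset", {
    ls0 <- makeLandscape(seed = 1, weightScale = 0, nCouplings = 0L,
                         noiseSigma = 0)
    ps <- random_peptides(20, seed = 2)
    expect_equal(oracleScore(ls0, ps), rep(-40, 20))
})

test_that("landscapes are pure functions of their seed", {
    a <- makeLandscape(seed = 7)
    b <- makeLandscape(seed = 7)
    expect_identical(a@positionWeights, b@positionWeights)
    expect_identical(a@couplings, b@couplings)
    expect_false(identical(a@positionWeights,
                           makeLandscape(seed = 8)@positionWeights))
})

test_that("random-peptide scores center on the offset within Monte Carlo error", {
    ls1 <- bench_landscape()
    ps <- random_peptides(10000, seed = 3)
    sc <- oracleScore(ls1, ps)
    se <- sd(sc) / sqrt(length(sc))
    expect_lt(abs(mean(sc) - ls1@offset), 4 * se)
    # scale: sd approximately weightScale * sqrt(L), loose factor-2 band
    expect_gt(sd(sc), 2 * sqrt(12) / 2)
    expect_lt(sd(sc), 2 * sqrt(12) * 2)
})

test_that("oracle scoring matches a naive per-sequence re-implementation", {
    ls3 <- toy_landscape()
    space <- enumerate_space(ls3)
    expect_identical(nrow(space), 8000L)
    naive <- function(s) {
        ch <- strsplit(s, "")[[1L]]
        v <- ls3@offset
        for (i in seq_along(ch))
            v <- v + ls3@positionWeights[i, ch[i]]
        for (cp in ls3@couplings)
            v <- v + cp$mat[match(ch[cp$i], aaAlphabet()),
                            match(ch[cp$j], aaAlphabet())]
        unname(v)
    }
    probe <- withr::with_seed(4, sample.int(8000, 300))
    for (i in probe)
        expect_equal(space$score[i], naive(space$sequence[i]), tolerance = 1e-12)
})

test_that("noise flag controls determinism of oracle scores", {
    ls1 <- bench_landscape()
    p <- random_peptides(5, seed = 5)
    expect_identical(oracleScore(ls1, p), oracleScore(ls1, p))
    n1 <- withr::with_seed(6, oracleScore(ls1, p, withNoise = TRUE))
    n2 <- withr::with_seed(6, oracleScore(ls1, p, withNoise = TRUE))
    expect_identical(n1, n2)
    expect_false(identical(n1, oracleScore(ls1, p)))
})

test_that("generated datasets have n unique records and honor sigma = 0", {
    ls1 <- bench_landscape()
    tab <- generateDataset(ls1, n = 1000, seed = 11)
    expect_identical(length(tab), 1000L)
    expect_identical(anyDuplicated(peptides(tab)), 0L)
    expect_identical(peptides(generateDataset(ls1, 1000, seed = 11)),
                     peptides(tab))
    ls_clean <- makeLandscape(seed = 101, noiseSigma = 0)
    t0 <- generateDataset(ls_clean, n = 500, seed = 12)
    expect_equal(scores(t0), oracleScore(ls_clean, peptides(t0)))
    expect_error(generateDataset(toy_landscape(), n = 8001, seed = 1),
                 "exceeds")
})

test_that("biased sampling enriches low scores relative to uniform", {
    ls1 <- bench_landscape()
    uni <- generateDataset(ls1, n = 5000, seed = 13, sampling = "uniform")
    bia <- generateDataset(ls1, n = 5000, seed = 13, sampling = "biased")
    expect_lt(mean(scores(bia)), mean(scores(uni)))
})

test_that("family correlation control hits the target", {
    ps <- random_peptides(10000, seed = 14)
    # rho = 1: identical additive members score identically (no couplings/noise)
    fam1 <- makeFamily(k = 2, targetCorrelation = 1, seed = 21,
                       nCouplings = 0L, noiseSigma = 0)
    m <- landscapes(fam1)
    expect_equal(oracleScore(m[[1L]], ps), oracleScore(m[[2L]], ps))
    # rho = 0: empirical score correlation within +/- 0.05 of 0
    fam0 <- makeFamily(k = 2, targetCorrelation = 0, seed = 22,
                       nCouplings = 0L, noiseSigma = 0)
    m0 <- landscapes(fam0)
    r0 <- cor(oracleScore(m0[[1L]], ps), oracleScore(m0[[2L]], ps))
    expect_lt(abs(r0), 0.05)
    # rho = -0.8: negative and within +/- 0.1
    famn <- makeFamily(k = 2, targetCorrelation = -0.8, seed = 23,
                       nCouplings = 0L, noiseSigma = 0)
    mn <- landscapes(famn)
    rn <- cor(oracleScore(mn[[1L]], ps), oracleScore(mn[[2L]], ps))
    expect_lt(rn, 0)
    expect_lt(abs(rn - (-0.8)), 0.1)
    expect_error(makeFamily(k = 3, targetCorrelation = -0.5, seed = 1),
                 "negative")
})

test_that("landscape JSON serialization is bit-exact both ways", {
    ls1 <- bench_landscape()
    path <- withr::local_tempfile(fileext = ".json")
    writeLandscapeJSON(ls1, path)
    back <- readLandscapeJSON(path)
    expect_identical(back@positionWeights, ls1@positionWeights)
    expect_identical(length(back@couplings), length(ls1@couplings))
    for (i in seq_along(back@couplings)) {
        expect_identical(back@couplings[[i]]$i, ls1@couplings[[i]]$i)
        expect_identical(back@couplings[[i]]$mat, ls1@couplings[[i]]$mat)
    }
    ps <- random_peptides(50, seed = 15)
    expect_identical(oracleScore(back, ps), oracleScore(ls1, ps))
    # family round trip
    fam <- makeFamily(k = 3, targetCorrelation = 0.5, seed = 24)
    fpath <- withr::local_tempfile(fileext = ".json")
    writeLandscapeJSON(fam, fpath)
    fback <- readLandscapeJSON(fpath)
    expect_s4_class(fback, "LandscapeFamily")
    for (i in 1:3)
        expect_identical(oracleScore(landscapes(fback)[[i]], ps),
                         oracleScore(landscapes(fam)[[i]], ps))
})
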