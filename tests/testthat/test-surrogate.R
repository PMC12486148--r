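# Small, fast trainings; the full-scale benchmark lives in the acceptance
# suite. Scales here were chosen so each block runs in seconds to ~1 minute.

tiny_model <- function() {
    cached("tiny_model", function() {
        ls1 <- bench_landscape()
        tab <- generateDataset(ls1, n = 1200, seed = 61)
        parts <- splitScoreTable(tab, seed = 62)
        trainSurrogate(parts$train, parts$validation,
                       surrogateConfig("lstm", 1, 16, epochs = 8,
                                       batchSize = 128, learningRate = 1e-2,
                                       seed = 63))
    })
}

test_that("a constant-score dataset is learned to near-zero error", {
    seqs <- random_peptides(600, seed = 51)
    tab <- ScoreTable(seqs[1:500], rep(-47.3, 500), "const")
    val <- ScoreTable(seqs[501:600], rep(-47.3, 100), "const")
    m <- trainSurrogate(tab, val,
                        surrogateConfig("lstm", 1, 8, epochs = 15,
                                        batchSize = 64, learningRate = 1e-2,
                                        seed = 52))
    expect_lt(sqrt(min(m@history$val_loss)), 0.1)
})

test_that("training is deterministic under a fixed seed", {
    ls1 <- bench_landscape()
    tab <- generateDataset(ls1, n = 800, seed = 53)
    parts <- splitScoreTable(tab, seed = 54)
    cfg <- surrogateConfig("gru", 1, 8, epochs = 3, batchSize = 128,
                           learningRate = 5e-3, seed = 55)
    m1 <- trainSurrogate(parts$train, parts$validation, cfg)
    m2 <- trainSurrogate(parts$train, parts$validation, cfg)
    expect_identical(m1@history, m2@history)
    probe <- random_peptides(20, seed = 56)
    expect_identical(predictScores(m1, probe), predictScores(m2, probe))
})

test_that("prediction is batch-invariant and permutation-equivariant", {
    m <- tiny_model()
    ps <- random_peptides(1000, seed = 57)
    all_at_once <- predictScores(m, ps)
    expect_true(all(is.finite(all_at_once)))
    expect_equal(predictScores(m, ps[1L]), all_at_once[1L],
                 tolerance = 1e-10)
    expect_equal(predictScores(m, ps, batchSize = 64L), all_at_once,
                 tolerance = 1e-10)
    perm <- withr::with_seed(58, sample.int(1000))
    expect_equal(predictScores(m, ps[perm]), all_at_once[perm],
                 tolerance = 1e-10)
})

test_that("prediction rejects peptides that do not match the artifact", {
    m <- tiny_model()
    expect_error(predictScores(m, "AAA"), "length")
    expect_error(predictScores(m, "XAAAAAAAAAAA"), "non-canonical")
})

test_that("a noiseless additive landscape is recovered almost exactly", {
    ls_add <- makeLandscape(seed = 31, nCouplings = 0L, noiseSigma = 0)
    tab <- generateDataset(ls_add, n = 8000, seed = 32)
    parts <- splitScoreTable(tab, seed = 33)
    m <- trainSurrogate(parts$train, parts$validation,
                        surrogateConfig("lstm", 1, 64, epochs = 30,
                                        batchSize = 64, learningRate = 1e-2,
                                        weightDecay = 0, seed = 34))
    e <- evaluateSurrogate(m, parts$test)
    expect_gte(e$rSquared, 0.99)
    # individual training-set predictions sit near the oracle values
    probe <- peptides(parts$train)[1:200]
    expect_lt(max(abs(predictScores(m, probe) - oracleScore(ls_add, probe))),
              5 * e$rmse + 1)
})

test_that("evaluation reports R^2 and RMSE by their definitions", {
    m <- tiny_model()
    ls1 <- bench_landscape()
    test_tab <- generateDataset(ls1, n = 300, seed = 64)
    e <- evaluateSurrogate(m, test_tab)
    p <- predictScores(m, peptides(test_tab))
    y <- scores(test_tab)
    expect_equal(e$rmse, sqrt(mean((y - p)^2)), tolerance = 1e-12)
    expect_equal(e$rSquared, 1 - sum((y - p)^2) / sum((y - mean(y))^2),
                 tolerance = 1e-12)
    expect_identical(e$n, 300L)
    # zero-variance test targets: R^2 undefined, RMSE still reported
    flat <- ScoreTable(peptides(test_tab)[1:5], rep(-40, 5), "flat")
    ef <- evaluateSurrogate(m, flat)
    expect_true(is.na(ef$rSquared))
    expect_true(is.finite(ef$rmse))
})

test_that("grid search returns one cell per combination and a consistent argmax", {
    ls1 <- bench_landscape()
    tab <- generateDataset(ls1, n = 1000, seed = 65)
    parts <- splitScoreTable(tab, seed = 66)
    grid <- gridSearch(parts$train, parts$validation,
                       layerChoices = 1:2, hiddenChoices = c(4L, 8L),
                       baseConfig = surrogateConfig("lstm", epochs = 3,
                                                    batchSize = 128,
                                                    learningRate = 1e-2,
                                                    seed = 67))
    expect_identical(nrow(grid), 4L)
    expect_true(all(is.finite(grid$rSquared)))
    best <- attr(grid, "best")
    expect_true(all(best$rSquared >= grid$rSquared))
})

test_that("capacity matters: a 2-unit model underfits an epistatic landscape", {
    ls_ep <- makeLandscape(seed = 41)
    tab <- generateDataset(ls_ep, n = 4000, seed = 42)
    parts <- splitScoreTable(tab, seed = 43)
    r2 <- vapply(c(2L, 32L), function(h) {
        m <- trainSurrogate(parts$train, parts$validation,
                            surrogateConfig("lstm", 1, h, epochs = 20,
                                            batchSize = 128,
                                            learningRate = 1e-2,
                                            weightDecay = 0, seed = 44))
        evaluateSurrogate(m, parts$validation)$rSquared
    }, numeric(1L))
    expect_lt(r2[1L], r2[2L])
})

test_that("architecture comparison covers all five families deterministically", {
    ls1 <- bench_landscape()
    tab <- generateDataset(ls1, n = 1500, seed = 71)
    parts <- splitScoreTable(tab, seed = 72)
    cfg <- surrogateConfig(numLayers = 1, hiddenDim = 16, epochs = 4,
                           batchSize = 128, learningRate = 1e-2, seed = 73)
    res <- compareArchitectures(parts$train, parts$validation, parts$test,
                                config = cfg)
    expect_identical(nrow(res), 5L)
    expect_setequal(res$architecture,
                    c("lstm", "bilstm", "gru", "rnn", "transformer"))
    expect_true(all(is.finite(res$rSquared)))
    expect_true(all(res$rmse >= 0))
    expect_true(all(is.na(res$error)))
    res2 <- compareArchitectures(parts$train, parts$validation, parts$test,
                                 config = cfg)
    expect_identical(res$rSquared, res2$rSquared)
})

test_that("model artifacts round-trip through save/load with identical predictions", {
    m <- tiny_model()
    dir <- withr::local_tempdir()
    saveSurrogate(m, dir)
    expect_true(file.exists(file.path(dir, "meta.json")))
    back <- loadSurrogate(dir)
    probe <- random_peptides(50, seed = 74)
    expect_identical(predictScores(back, probe), predictScores(m, probe))
    expect_identical(back@alphabet, aaAlphabet())
})

test_that("more training data never hurts the median benchmark fit", {
    ls1 <- bench_landscape()
    med <- vapply(c(2000L, 10000L, 20000L), function(n) {
        r2 <- vapply(1:3, function(s) {
            tab <- generateDataset(ls1, n = n, seed = 900 + s)
            parts <- splitScoreTable(tab, seed = s)
            m <- trainSurrogate(parts$train, parts$validation,
                                surrogateConfig("lstm", 1, 32, epochs = 10,
                                                batchSize = 128,
                                                learningRate = 1e-2,
                                                seed = s))
            evaluateSurrogate(m, parts$test)$rSquared
        }, numeric(1L))
        median(r2)
    }, numeric(1L))
    expect_true(all(diff(med) >= 0))
})

test_that("z-scored training stores and inverts its normalization", {
    ls1 <- bench_landscape()
    tab <- generateDataset(ls1, n = 1000, seed = 81)
    parts <- splitScoreTable(tab, seed = 82)
    m <- trainSurrogate(parts$train, parts$validation,
                        surrogateConfig("lstm", 1, 16, epochs = 6,
                                        batchSize = 128, learningRate = 1e-2,
                                        normalize = TRUE, seed = 83))
    expect_named(m@normalization, c("mean", "sd"))
    p <- predictScores(m, peptides(parts$test))
    # predictions come back on the raw score scale
    expect_lt(abs(mean(p) - mean(scores(parts$test))), 5)
    dir <- withr::local_tempdir()
    saveSurrogate(m, dir)
    expect_identical(predictScores(loadSurrogate(dir), peptides(parts$test)),
                     p)
})
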