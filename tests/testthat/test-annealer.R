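const_scorer <- function(v) function(sequences) rep(v, length(sequences))

test_that("objective values follow the mean / difference / identity rules", {
    sc <- list(a = const_scorer(-55), b = const_scorer(-60),
               c = const_scorer(-65))
    p <- "YWYERIFWRRMW"
    expect_equal(objectiveValue(sc, designObjective("promiscuous",
                                                    c("a", "b", "c")), p), -60)
    expect_equal(objectiveValue(sc, designObjective("single", "b"), p), -60)
    same <- list(x = const_scorer(-50), y = const_scorer(-50))
    expect_equal(objectiveValue(same, designObjective("selective",
                                                      c("x", "y")), p), 0)
    ls1 <- bench_landscape()
    sc_ls <- list(bench = ls1)
    expect_equal(objectiveValue(sc_ls, designObjective("single", "bench"), p),
                 oracleScore(ls1, p))
    expect_error(objectiveValue(sc, designObjective("single", "zz"), p),
                 "no scorer")
    expect_error(designObjective("selective", "a"), "exactly")
    expect_error(designObjective("promiscuous", "a"), "at least two")
})

test_that("Metropolis acceptance matches exp(-delta/T) frequencies", {
    expect_true(all(metropolisAccept(rep(-5, 100), 0.01)))
    expect_true(all(metropolisAccept(rep(0, 100), 0.01)))
    expect_error(metropolisAccept(1, 0), "positive")
    withr::with_seed(31, {
        n <- 1e5
        for (cell in list(c(1, 1), c(2, 1), c(0.5, 1), c(1, 2), c(3, 10))) {
            delta <- cell[1]; temp <- cell[2]
            p <- exp(-delta / temp)
            acc <- mean(metropolisAccept(rep(delta, n), temp))
            se <- sqrt(p * (1 - p) / n)
            expect_lt(abs(acc - p), 4 * se)
        }
    })
})

test_that("temperature program hits its endpoints and decays monotonically", {
    s <- annealSchedule(steps = 100, tInitial = 5, tFinal = 0.05)
    temps <- peptideSA:::.schedule_temps(s)
    expect_equal(temps[1], 5)
    expect_equal(temps[100], 0.05)
    expect_true(all(diff(temps) < 0))
    lin <- peptideSA:::.schedule_temps(
        annealSchedule(steps = 3, tInitial = 4, tFinal = 2, decay = "linear"))
    expect_equal(lin, c(4, 3, 2))
    expect_error(annealSchedule(tInitial = 1, tFinal = 2), "tFinal")
})

test_that("a one-step schedule makes exactly one proposal", {
    run <- runAnnealing(list(toy = toy_landscape()),
                        designObjective("single", "toy"),
                        annealSchedule(steps = 1L), seed = 5, length = 3L)
    expect_identical(nrow(trajectory(run)), 1L)
    expect_lte(nrow(archive(run)), 2L)  # start and/or its mutant
    expect_gte(nrow(archive(run)), 1L)
})

test_that("design runs are reproducible and keep ordered unique archives", {
    sch <- annealSchedule(steps = 500L)
    obj <- designObjective("single", "bench")
    r1 <- runAnnealing(list(bench = bench_landscape()), obj, sch, seed = 42)
    r2 <- runAnnealing(list(bench = bench_landscape()), obj, sch, seed = 42)
    expect_identical(archive(r1), archive(r2))
    expect_identical(trajectory(r1), trajectory(r2))
    a <- archive(r1)
    expect_identical(anyDuplicated(a$sequence), 0L)
    expect_false(is.unsorted(a$value))
    expect_true(all(nchar(a$sequence) == 12L))
    # best-so-far curve is monotone non-increasing
    expect_true(all(diff(bestSoFar(r1)) <= 0))
    expect_equal(min(trajectory(r1)$objective), min(bestSoFar(r1)))
})

test_that("acceptance rate approaches 1 at high T and 0 uphill at low T", {
    ls1 <- bench_landscape()
    hot <- runAnnealing(list(b = ls1), designObjective("single", "b"),
                        annealSchedule(steps = 2000L, tInitial = 1e6,
                                       tFinal = 1e6), seed = 1)
    expect_gt(mean(trajectory(hot)$accepted), 0.999)
    cold <- runAnnealing(list(b = ls1), designObjective("single", "b"),
                         annealSchedule(steps = 3000L, tInitial = 1e-9,
                                        tFinal = 1e-9), seed = 2)
    tr <- trajectory(cold)
    uphill <- tr$objective > c(Inf, cummin(tr$objective)[-nrow(tr)])
    # every accepted move must have been downhill (or equal) at T ~ 0
    expect_true(all(!tr$accepted[uphill]))
})

test_that("annealing finds the enumerated optimum on the 8000-state space", {
    ls3 <- toy_landscape()
    space <- enumerate_space(ls3)
    truth <- min(space$score)
    sch <- annealSchedule(steps = 4000L)
    hits <- vapply(1:20, function(s) {
        run <- runAnnealing(list(toy = ls3), designObjective("single", "toy"),
                            sch, seed = 100 + s, length = 3L)
        isTRUE(all.equal(archive(run)$value[1L], truth, tolerance = 1e-12))
    }, logical(1L))
    expect_gte(sum(hits), 18L)
})

test_that("annealing finds the optimum on the 531441-state reduced-alphabet space", {
    ls12 <- makeLandscape(seed = 77, length = 12L, nCouplings = 6L,
                          noiseSigma = 0, label = "reduced")
    letters3 <- c("A", "C", "D")
    space <- enumerate_space(ls12, letters = letters3)
    expect_identical(nrow(space), 531441L)
    truth <- min(space$score)
    sch <- annealSchedule()  # full default budget: 21 525 proposals
    hits <- vapply(1:10, function(s) {
        run <- runAnnealing(list(r = ls12), designObjective("single", "r"),
                            sch, seed = 200 + s, letters = letters3)
        isTRUE(all.equal(archive(run)$value[1L], truth, tolerance = 1e-12))
    }, logical(1L))
    expect_gte(sum(hits), 9L)
})

test_that("campaigns merge, deduplicate and keep per-run metadata", {
    ls1 <- bench_landscape()
    obj <- designObjective("single", "bench")
    sch <- annealSchedule(steps = 400L)
    camp <- runCampaign(list(bench = ls1), obj, sch, nRuns = 4L,
                        baseSeed = 10L)
    a <- archive(camp)
    expect_identical(anyDuplicated(a$sequence), 0L)
    expect_false(is.unsorted(a$value))
    expect_length(camp@runBest, 4L)
    expect_true(all(a$value[1L] <= camp@runBest))
    # reproducible end-to-end
    camp2 <- runCampaign(list(bench = ls1), obj, sch, nRuns = 4L,
                         baseSeed = 10L)
    expect_identical(archive(camp2), a)
    # two runs with the same seed collapse to the single-run archive
    single <- runAnnealing(list(bench = ls1), obj, sch, seed = 99L)
    both <- lapply(1:2, function(i) archive(single))
    merged <- do.call(rbind, both)
    merged <- merged[order(merged$value, merged$sequence), ]
    merged <- merged[!duplicated(merged$sequence), ]
    expect_equal(merged$sequence, archive(single)$sequence)
})

test_that("optimizing selectivity beats incidental selectivity on an anti-correlated family", {
    fam <- makeFamily(k = 2, targetCorrelation = -0.8, seed = 55,
                      labels = c("target", "off"))
    sc <- landscapes(fam)
    sch <- annealSchedule(steps = 2000L)
    sel <- runCampaign(sc, designObjective("selective", c("target", "off")),
                       sch, nRuns = 5L, baseSeed = 500L)
    pro <- runCampaign(sc, designObjective("promiscuous", c("target", "off")),
                       sch, nRuns = 5L, baseSeed = 600L)
    sel_obj <- designObjective("selective", c("target", "off"))
    top_sel <- utils::head(archive(sel)$sequence, 100L)
    top_pro <- utils::head(archive(pro)$sequence, 100L)
    m_sel <- mean(objectiveValue(sc, sel_obj, top_sel))
    m_pro <- mean(objectiveValue(sc, sel_obj, top_pro))
    expect_lt(m_sel, m_pro)
})

test_that("archive TSV export carries rank, scores and survives FASTA export", {
    ls1 <- bench_landscape()
    camp <- runCampaign(list(bench = ls1),
                        designObjective("single", "bench"),
                        annealSchedule(steps = 200L), nRuns = 2L,
                        baseSeed = 3L)
    tsv <- withr::local_tempfile(fileext = ".tsv")
    fa <- withr::local_tempfile(fileext = ".fa")
    writeArchiveTSV(camp, tsv, scorers = list(bench = ls1), fasta = fa)
    df <- read.delim(tsv)
    expect_identical(df$rank, seq_len(nrow(df)))
    expect_equal(df$score_bench, oracleScore(ls1, df$sequence))
    expect_identical(readPeptideFasta(fa, length = 12)[[1L]],
                     df$sequence[1L])
})
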