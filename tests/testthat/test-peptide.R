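test_that("peptide validation accepts canonical 12-mers and normalizes case", {
    expect_identical(validatePeptide("YWYERIFWRRMW"), "YWYERIFWRRMW")
    expect_identical(validatePeptide("TAFMFRRGLIFW"), "TAFMFRRGLIFW")
    expect_identical(validatePeptide("tafmfrrglifw"), "TAFMFRRGLIFW")
})

test_that("peptide validation rejects wrong length and non-canonical letters", {
    expect_error(validatePeptide("TAFMFRRGLIF"), "length 11, expected 12")
    expect_error(validatePeptide("TAFMFRRGLIFX"), "'X' at position 12")
    for (bad in c("B", "J", "O", "U", "X", "Z"))
        expect_error(validatePeptide(paste0(bad, "AFMFRRGLIFW")), "position 1")
})

test_that("one-hot encoding has exactly one 1 per row at the alphabet index", {
    m <- oneHotEncode("YWYERIFWRRMW")
    expect_equal(dim(m), c(12L, 20L))
    expect_true(all(rowSums(m) == 1L))
    # alphabetical ordering pins the columns
    expect_equal(which(oneHotEncode("AAAAAAAAAAAA")[1L, ] == 1L), c(A = 1L))
    expect_equal(which(oneHotEncode("YYYYYYYYYYYY")[1L, ] == 1L), c(Y = 20L))
})

test_that("one-hot encode/decode round-trips random peptides", {
    for (p in random_peptides(100, seed = 5))
        expect_identical(oneHotDecode(oneHotEncode(p)), p)
    expect_error(oneHotDecode(matrix(1, 2, 20)), "one-hot")
})

test_that("hamming distance matches hand-counted table sequences", {
    # NDLMFRRGLIFW vs SNMMFRRGLIHW differ at positions 1, 2, 3, 11
    expect_identical(hammingDist("NDLMFRRGLIFW", "SNMMFRRGLIHW"), 4L)
    expect_identical(hammingDist("TAFMFRRGLIFW", "SNMMFRRGLIHW"),
                     hammingDist("SNMMFRRGLIHW", "TAFMFRRGLIFW"))
    expect_error(hammingDist("AAA", "AAAA"), "equal-length")
})

test_that("hamming distance is a metric on random triples", {
    ps <- random_peptides(60, seed = 9)
    trip <- matrix(ps, ncol = 3)
    for (i in seq_len(nrow(trip))) {
        a <- trip[i, 1]; b <- trip[i, 2]; c <- trip[i, 3]
        expect_identical(hammingDist(a, a), 0L)
        dab <- hammingDist(a, b)
        expect_gte(dab, 0L)
        expect_identical(dab, hammingDist(b, a))
        expect_lte(hammingDist(a, c), dab + hammingDist(b, c))
        if (a != b) expect_gt(dab, 0L)
    }
})

test_that("substitution proposals are uniform over the 19 alternatives", {
    withr::with_seed(21, {
        n <- 10000L
        muts <- vapply(seq_len(n), function(i)
            proposeMutation("AAAAAAAAAAAA", subProb = 1), character(1L))
        expect_true(all(hammingDist(muts, "AAAAAAAAAAAA") == 1L))
        # pool the substituted letters over all positions
        letters_hit <- vapply(muts, function(m) {
            ch <- strsplit(m, "")[[1L]]
            ch[ch != "A"][1L]
        }, character(1L))
        counts <- table(factor(letters_hit, levels = setdiff(aaAlphabet(), "A")))
        p <- 1 / 19
        se <- sqrt(p * (1 - p) / n)
        expect_true(all(abs(counts / n - p) < 4 * se))
    })
})

test_that("swap proposals permute the composition and never no-op", {
    withr::with_seed(22, {
        # all-distinct residues: no swap can degenerate into a substitution
        p <- "ACDEFGHIKLMN"
        for (i in 1:200) {
            q <- proposeMutation(p, subProb = 0)
            expect_false(identical(p, q))
            expect_identical(sort(strsplit(p, "")[[1L]]),
                             sort(strsplit(q, "")[[1L]]))
        }
        # homopolymer: every swap degenerates and is resampled as substitution
        for (i in 1:50) {
            q <- proposeMutation("AAAAAAAAAAAA", subProb = 0)
            expect_identical(hammingDist(q, "AAAAAAAAAAAA"), 1L)
        }
    })
})

test_that("FASTA round trip preserves order, ids and sequences", {
    path <- withr::local_tempfile(fileext = ".fa")
    ps <- setNames(random_peptides(10, seed = 3), sprintf("id_%02d", 1:10))
    writePeptideFasta(ps, path)
    back <- readPeptideFasta(path)
    expect_identical(back, ps)
})

test_that("FASTA reader normalizes case and handles empty/invalid input", {
    path <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">lc", "ywyerifwrrmw", ">bad", "XXXXXXXXXXXX"), path)
    expect_warning(kept <- readPeptideFasta(path, strict = FALSE), "dropped 1")
    expect_identical(unname(kept), "YWYERIFWRRMW")
    expect_error(readPeptideFasta(path, strict = TRUE), "non-canonical")
    empty <- withr::local_tempfile(fileext = ".fa")
    file.create(empty)
    expect_length(readPeptideFasta(empty), 0L)
})

test_that("plain-line reader ignores blanks and comments", {
    path <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("# panel", "YWYERIFWRRMW", "", "tafmfrrglifw"), path)
    expect_identical(readPeptideLines(path),
                     c("YWYERIFWRRMW", "TAFMFRRGLIFW"))
})
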