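#' Construct a ScoreTable
#'
#' @param sequences Character vector of peptide sequences (validated,
#'   uppercased).
#' @param scores Numeric vector of finite affinity scores (lower = stronger
#'   predicted binding).
#' @param material Material label.
#' @param peptideLength Expected peptide length (default: length of the first
#'   sequence).
#' @return A [ScoreTable-class].
#' @examples
#' ScoreTable(c("YWYERIFWRRMW", "TAFMFRRGLIFW"), c(-55.2, -48.9), "PP")
#' @export
ScoreTable <- function(sequences, scores, material,
                       peptideLength = nchar(sequences[1L])) {
    sequences <- validatePeptide(sequences, peptideLength)
    new("ScoreTable", material = as.character(material),
        sequence = as.character(sequences), score = as.numeric(scores))
}

#' Read a sequence-score table from delimited text
#'
#' Ingests flat tables with a sequence column and a numeric score column
#' (the layout of biophysical score dumps and of [writeScoreTable()] output).
#' The delimiter is auto-detected (tab or comma) unless given; a header is
#' auto-detected from the first line.
#'
#' @param path Path to a CSV/TSV file.
#' @param material Material label for the table.
#' @param seqCol,scoreCol Column names when the file has a header (defaults
#'   `"sequence"`, `"score"`); ignored for headerless files, which must have
#'   the sequence in column 1 and the score in column 2.
#' @param sep Field delimiter, or `NULL` to auto-detect.
#' @param dedup Deduplicate repeated sequences keeping the best (lowest)
#'   score (default `TRUE`).
#' @param peptideLength Expected peptide length (default: from first row).
#' @return A [ScoreTable-class].
#' @export
readScoreTable <- function(path, material, seqCol = "sequence",
                           scoreCol = "score", sep = NULL, dedup = TRUE,
                           peptideLength = NULL) {
    first <- readLines(path, n = 1L, warn = FALSE)
    if (length(first) == 0L) stop("empty table: ", path)
    if (is.null(sep)) sep <- if (grepl("\t", first)) "\t" else ","
    fields <- strsplit(first, sep, fixed = TRUE)[[1L]]
    has_header <- seqCol %in% fields ||
        (length(fields) >= 2L && is.na(suppressWarnings(as.numeric(fields[2L]))))
    df <- utils::read.table(path, sep = sep, header = has_header,
                            stringsAsFactors = FALSE, colClasses = "character",
                            comment.char = "", quote = "\"")
    if (has_header) {
        if (!all(c(seqCol, scoreCol) %in% names(df)))
            stop(sprintf("columns '%s'/'%s' not found in %s", seqCol, scoreCol, path))
        seqs <- df[[seqCol]]; raw <- df[[scoreCol]]
    } else {
        if (ncol(df) < 2L) stop("need at least two columns in ", path)
        seqs <- df[[1L]]; raw <- df[[2L]]
    }
    if (length(seqs) == 0L) stop("empty table: ", path)
    sc <- suppressWarnings(as.numeric(raw))
    if (anyNA(sc)) {
        row <- which(is.na(sc))[1L] + has_header
        stop(sprintf("unparseable score '%s' at row %d of %s", raw[which(is.na(sc))[1L]], row, path))
    }
    if (is.null(peptideLength)) peptideLength <- nchar(seqs[1L])
    seqs <- tryCatch(validatePeptide(seqs, peptideLength),
                     error = function(e) stop("in ", path, ": ", conditionMessage(e)))
    tab <- new("ScoreTable", material = as.character(material),
               sequence = seqs, score = sc)
    if (dedup) dedupBest(tab) else tab
}

#' Write a ScoreTable as TSV
#'
#' @param x A [ScoreTable-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeScoreTable <- function(x, path) {
    stopifnot(is(x, "ScoreTable"))
    utils::write.table(data.frame(sequence = x@sequence, score = x@score),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Deduplicate a ScoreTable keeping the best score per sequence
#'
#' Biophysical score datasets derived from optimization trajectories revisit
#' sequences; a surrogate needs one target per sequence, and keep-best matches
#' the lower-is-better convention. Retained scores are never larger than any
#' dropped duplicate's score.
#'
#' @param x A [ScoreTable-class].
#' @return A deduplicated [ScoreTable-class] (input order of first
#'   occurrences preserved).
#' @export
dedupBest <- function(x) {
    stopifnot(is(x, "ScoreTable"))
    if (length(x) == 0L || !anyDuplicated(x@sequence)) return(x)
    best <- tapply(x@score, x@sequence, min)
    keep <- !duplicated(x@sequence)
    seqs <- x@sequence[keep]
    new("ScoreTable", material = x@material, sequence = seqs,
        score = as.numeric(best[seqs]))
}

#' Split a ScoreTable into train/validation/test parts
#'
#' Uniform random split by record with a stored seed: identical inputs and
#' seed give byte-identical splits; the three parts form a partition of the
#' input records. Sizes are the rounded fractions (train gets the remainder).
#'
#' @param x A non-empty [ScoreTable-class].
#' @param fractions Numeric of length 3 `(train, validation, test)`, each in
#'   (0,1), summing to 1 (tolerance 1e-9). Default `c(0.8, 0.1, 0.1)`.
#' @param seed Integer seed for the permutation.
#' @return Named list of three `ScoreTable`s: `train`, `validation`, `test`.
#' @export
splitScoreTable <- function(x, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
    stopifnot(is(x, "ScoreTable"), length(x) > 0L, length(fractions) == 3L)
    if (any(fractions <= 0) || any(fractions >= 1))
        stop("each fraction must lie in (0, 1)")
    if (abs(sum(fractions) - 1) > 1e-9)
        stop("fractions must sum to 1")
    n <- length(x)
    n_val <- round(fractions[2L] * n)
    n_test <- round(fractions[3L] * n)
    n_train <- n - n_val - n_test
    if (min(n_train, n_val, n_test) < 1L)
        stop("table too small for the requested fractions")
    perm <- .with_seed(seed, sample.int(n))
    idx <- list(train = perm[seq_len(n_train)],
                validation = perm[n_train + seq_len(n_val)],
                test = perm[n_train + n_val + seq_len(n_test)])
    lapply(idx, function(i)
        new("ScoreTable", material = x@material,
            sequence = x@sequence[i], score = x@score[i]))
}

#' The k best-scoring records of a table
#'
#' @param x A [ScoreTable-class] (or a data.frame with `sequence` and a
#'   numeric value column).
#' @param k Number of records (lowest scores first). Ties at the k-th rank
#'   are broken by lexicographic sequence order so the selection is
#'   deterministic.
#' @return A data.frame `sequence`, `score`, sorted ascending.
#' @export
topRecords <- function(x, k) {
    stopifnot(is(x, "ScoreTable"))
    k <- as.integer(k)
    if (k < 1L || k > length(x)) stop("k must lie in [1, number of records]")
    ord <- order(x@score, x@sequence)[seq_len(k)]
    data.frame(sequence = x@sequence[ord], score = x@score[ord],
               stringsAsFactors = FALSE)
}

#' Summarize the k best scores of a table
#'
#' The campaign-bookkeeping summary "mean +/- std (minimum)" over the top-k
#' records by score (lowest = best). `std` is the sample standard deviation
#' (n-1 denominator); for `k = 1` it is reported as 0.
#'
#' @inheritParams topRecords
#' @return A one-row data.frame: `label`, `k`, `mean`, `std`, `minimum`.
#' @examples
#' t <- ScoreTable(randomPeptide(5, 12), c(-3, -2, -1, -4, -5), "toy")
#' summarizeTop(t, 2)  # mean -4.5, min -5
#' @export
summarizeTop <- function(x, k = 100L) {
    top <- topRecords(x, k)
    s <- top$score
    data.frame(label = x@material, k = as.integer(k), mean = mean(s),
               std = if (length(s) > 1L) stats::sd(s) else 0,
               minimum = min(s), stringsAsFactors = FALSE)
}

#' Write campaign score summaries as TSV
#'
#' Mirrors the bookkeeping table of a design campaign: one row per label with
#' columns `label`, `novelty`, `mean`, `std`, `minimum`.
#'
#' @param summaries data.frame as produced by rbind-ing [summarizeTop()]
#'   rows, optionally with a `novelty` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeScoreSummary <- function(summaries, path) {
    if (!"novelty" %in% names(summaries)) summaries$novelty <- NA_real_
    cols <- c("label", "novelty", "mean", "std", "minimum")
    utils::write.table(summaries[, cols], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
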