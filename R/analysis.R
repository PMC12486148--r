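#' Novelty of top-ranked designs against a reference set
#'
#' Fraction of the top-`k` designed sequences that do not occur in the
#' reference set (exact string match, no similarity threshold). A campaign
#' whose designs never revisit the training data has novelty 1.
#'
#' @param designs Character vector of designed sequences, pre-sorted
#'   best-first.
#' @param reference Character vector (or anything coercible) of reference
#'   sequences; may be empty.
#' @param k Number of top designs to check (`k <= length(designs)`).
#' @return A fraction in \[0, 1\].
#' @examples
#' noveltyFraction(c("AAAAAAAAAAAA", "WWWWWWWWWWWW"), "AAAAAAAAAAAA", k = 2)
#' @export
noveltyFraction <- function(designs, reference, k = length(designs)) {
    k <- as.integer(k)
    if (k < 1L || k > length(designs))
        stop("k must lie in [1, length(designs)]")
    top <- designs[seq_len(k)]
    mean(!top %in% as.character(reference))
}

#' Greedy diversity selection of a candidate panel
#'
#' Scans an objective-sorted candidate list in rank order and selects a
#' candidate iff its Hamming distance to every already-selected peptide is at
#' least `minDistance`, stopping after `k` selections or at the end of the
#' list. This is the panel-selection rule used to pick diverse designs for
#' downstream validation (defaults: panel of 12 at distance >= 3).
#'
#' @param candidates A [DesignArchive-class], [DesignRun-class], or a
#'   data.frame with columns `sequence` and `value` sorted ascending by
#'   `value`.
#' @param k Panel size (default 12).
#' @param minDistance Minimum pairwise Hamming distance (default 3;
#'   `0` makes the constraint vacuous).
#' @return Character vector of selected sequences in selection order, with
#'   attribute `shortfall` (`TRUE` if fewer than `k` candidates satisfied
#'   the constraint) and attribute `values` (their objective values).
#' @export
selectDiverse <- function(candidates, k = 12L, minDistance = 3L) {
    if (is(candidates, "DesignArchive") || is(candidates, "DesignRun"))
        candidates <- archive(candidates)
    stopifnot(is.data.frame(candidates),
              all(c("sequence", "value") %in% names(candidates)))
    if (is.unsorted(candidates$value))
        stop("candidates must be sorted ascending by value")
    k <- as.integer(k); minDistance <- as.integer(minDistance)
    L <- if (nrow(candidates) > 0L) nchar(candidates$sequence[1L]) else 0L
    stopifnot(k >= 1L, minDistance >= 0L, minDistance <= L)
    sel <- character(0)
    vals <- numeric(0)
    for (i in seq_len(nrow(candidates))) {
        s <- candidates$sequence[i]
        if (length(sel) == 0L || all(hammingDist(s, sel) >= minDistance)) {
            sel <- c(sel, s)
            vals <- c(vals, candidates$value[i])
            if (length(sel) == k) break
        }
    }
    structure(sel, shortfall = length(sel) < k, values = vals)
}

#' Amino-acid composition of a peptide set
#'
#' Pooled residue counts over all peptides divided by the total residue
#' count, indexed by [aaAlphabet()] order. Frequencies sum to 1.
#'
#' @param peptides Non-empty character vector of equal-length peptides.
#' @return Named numeric vector of 20 frequencies with attributes
#'   `nPeptides` and `nResidues`.
#' @examples
#' compositionFrequencies("YWYERIFWRRMW")[c("W", "R", "Y")]  # 3/12 3/12 2/12
#' @export
compositionFrequencies <- function(peptides) {
    if (length(peptides) == 0L) stop("empty peptide list")
    if (length(unique(nchar(peptides))) != 1L)
        stop("all peptides must have equal length")
    idx <- .seq_index_matrix(peptides) + 1L
    counts <- tabulate(idx, nbins = 20L)
    structure(setNames(counts / sum(counts), aaAlphabet()),
              nPeptides = length(peptides), nResidues = sum(counts))
}

#' Squared Pearson correlation between two frequency vectors
#'
#' Returns the squared Pearson correlation r^2 of two composition profiles
#' (or any equal-length numeric vectors) and the two-sided p-value of the
#' t-transform with n - 2 degrees of freedom, the statistic used to compare
#' amino-acid usage between design goals.
#'
#' @param a,b Numeric vectors of equal length, each with nonzero variance
#'   (e.g. two [compositionFrequencies()] outputs).
#' @return A list with `rSquared` and `pValue`.
#' @export
frequencyCorrelation <- function(a, b) {
    a <- as.numeric(a); b <- as.numeric(b)
    if (length(a) != length(b)) stop("vectors must have equal length")
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
        stop("zero variance: correlation undefined")
    ct <- stats::cor.test(a, b, method = "pearson", alternative = "two.sided")
    list(rSquared = unname(ct$estimate)^2, pValue = ct$p.value)
}

#' Elementwise ratio of two composition profiles
#'
#' Computes `(a + pseudocount) / (b + pseudocount)` per amino acid, the
#' enrichment ratio used to relate single-material designs for two
#' materials. A positive pseudocount keeps ratios finite when a residue is
#' absent from the denominator profile.
#'
#' @param a,b Composition profiles over the same alphabet (numeric vectors
#'   of equal length).
#' @param pseudocount Non-negative value added to both profiles (default 0).
#' @return Named numeric vector of ratios.
#' @export
compositionRatio <- function(a, b, pseudocount = 0) {
    stopifnot(length(a) == length(b), pseudocount >= 0)
    out <- (as.numeric(a) + pseudocount) / (as.numeric(b) + pseudocount)
    names(out) <- names(a)
    out
}
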