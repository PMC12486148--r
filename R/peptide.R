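#' The canonical amino-acid alphabet
#'
#' The 20 canonical one-letter amino-acid codes in fixed alphabetical order
#' (`"ACDEFGHIKLMNPQRSTVWY"`). This ordering defines the column order of every
#' one-hot encoding produced by the package and is stored inside every trained
#' surrogate artifact, so encodings are reproducible across sessions.
#'
#' @return A character vector of length 20.
#' @examples
#' aaAlphabet()
#' @export
aaAlphabet <- function() {
    c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

## fast lookup table: UTF-8 code -> 1-based alphabet index (NA = non-canonical)
.aa_index_table <- local({
    tab <- rep(NA_integer_, 127L)
    tab[utf8ToInt(paste(aaAlphabet(), collapse = ""))] <- seq_len(20L)
    tab
})

## sequence string -> integer vector of 1-based alphabet indices (NA where invalid)
.seq_to_idx <- function(x) {
    codes <- utf8ToInt(x)
    codes[codes > 127L | codes < 1L] <- 1L  # map exotic codepoints to an invalid slot
    .aa_index_table[codes]
}

## integer indices -> sequence string
.idx_to_seq <- function(idx) {
    paste(aaAlphabet()[idx], collapse = "")
}

#' Validate peptide sequences
#'
#' Checks that each sequence has the required design length and contains only
#' canonical amino-acid letters. Lowercase input is accepted and normalized to
#' uppercase; the non-canonical letters B, J, O, U, X and Z (and anything else
#' outside the 20-letter alphabet) are always rejected, with the first
#' offending position reported.
#'
#' @param x Character vector of raw peptide sequences.
#' @param length Required peptide length (default 12, the design length used
#'   throughout the package).
#' @return The validated, uppercased character vector (names preserved).
#' @examples
#' validatePeptide("YWYERIFWRRMW")
#' validatePeptide("tafmfrrglifw")
#' @export
validatePeptide <- function(x, length = 12L) {
    if (!is.character(x) || anyNA(x))
        stop("peptide sequences must be a character vector without NA")
    length <- as.integer(length)
    if (length(x) == 0L) return(x)
    x <- toupper(x)
    nc <- nchar(x)
    bad_len <- which(nc != length)
    if (length(bad_len) > 0L)
        stop(sprintf("sequence %d ('%s') has length %d, expected %d",
                     bad_len[1L], x[bad_len[1L]], nc[bad_len[1L]], length))
    for (i in seq_along(x)) {
        idx <- .seq_to_idx(x[i])
        if (anyNA(idx)) {
            pos <- which(is.na(idx))[1L]
            stop(sprintf(
                "sequence %d ('%s') has non-canonical letter '%s' at position %d",
                i, x[i], substr(x[i], pos, pos), pos))
        }
    }
    x
}

## quiet vectorized validity check (no error), used by lenient readers
.is_valid_peptide <- function(x, length) {
    nchar(x) == length & !vapply(x, function(s) anyNA(.seq_to_idx(s)), logical(1L))
}

#' One-hot encode a peptide
#'
#' Encodes a peptide as an L x 20 binary matrix: row i carries a single 1 in
#' the column of residue i, with columns ordered by [aaAlphabet()].
#'
#' @param p A single validated peptide string.
#' @return An L x 20 integer matrix with rownames the residues and colnames
#'   the alphabet letters. Every row sums to exactly 1.
#' @seealso [oneHotDecode()]
#' @examples
#' m <- oneHotEncode("YWYERIFWRRMW")
#' rowSums(m)
#' @export
oneHotEncode <- function(p) {
    stopifnot(is.character(p), length(p) == 1L)
    idx <- .seq_to_idx(p)
    if (anyNA(idx)) stop("non-canonical letter in '", p, "'")
    L <- length(idx)
    m <- matrix(0L, nrow = L, ncol = 20L,
                dimnames = list(strsplit(p, "")[[1L]], aaAlphabet()))
    m[cbind(seq_len(L), idx)] <- 1L
    m
}

#' Decode a one-hot matrix back to a peptide string
#'
#' @param m An L x 20 one-hot matrix as produced by [oneHotEncode()].
#' @return The peptide string.
#' @export
oneHotDecode <- function(m) {
    stopifnot(is.matrix(m), ncol(m) == 20L)
    if (any(rowSums(m != 0) != 1L) || any(m != 0 & m != 1))
        stop("not a one-hot matrix: every row must contain exactly one 1")
    .idx_to_seq(max.col(m))
}

#' Hamming distance between equal-length peptides
#'
#' Number of positions at which two sequences differ; the distance underlying
#' the diversity-selection step of a design campaign.
#'
#' @param a,b Character vectors of equal-length sequences (recycled to a
#'   common length).
#' @return Integer vector of distances.
#' @examples
#' hammingDist("NDLMFRRGLIFW", "SNMMFRRGLIHW")  # 4
#' @export
hammingDist <- function(a, b) {
    n <- max(length(a), length(b))
    a <- rep_len(a, n); b <- rep_len(b, n)
    if (any(nchar(a) != nchar(b)))
        stop("hamming distance requires equal-length sequences")
    vapply(seq_len(n), function(i) {
        sum(utf8ToInt(a[i]) != utf8ToInt(b[i]))
    }, integer(1L))
}

#' Generate random peptides
#'
#' Draws sequences uniformly over the given alphabet, using R's current RNG
#' stream (seed with [set.seed()] for reproducibility).
#'
#' @param n Number of peptides.
#' @param length Peptide length (default 12).
#' @param letters Alphabet to draw from (default the full 20-letter alphabet;
#'   a subset gives reduced-alphabet designs).
#' @return Character vector of `n` sequences.
#' @export
randomPeptide <- function(n, length = 12L, letters = aaAlphabet()) {
    stopifnot(n >= 1L, length >= 1L, all(letters %in% aaAlphabet()))
    m <- matrix(sample(letters, n * length, replace = TRUE), nrow = n)
    apply(m, 1L, paste, collapse = "")
}

#' Propose a single mutation of a peptide
#'
#' The elementary move of the simulated-annealing designer: with probability
#' `subProb` a substitution (one position changed to one of the 19 other
#' letters, position and letter uniform), otherwise a swap of the residues at
#' two distinct positions. A swap that would leave the sequence unchanged
#' (equal residues at the two positions) is resampled as a substitution, so
#' every proposal differs from its parent. Draws from R's current RNG stream.
#'
#' @param p A single peptide string.
#' @param subProb Probability of a substitution move (default 0.5).
#' @param letters Alphabet used for substitutions (default full alphabet).
#' @return A mutated peptide string, never identical to `p`.
#' @export
proposeMutation <- function(p, subProb = 0.5, letters = aaAlphabet()) {
    chars <- strsplit(p, "")[[1L]]
    L <- length(chars)
    do_sub <- runif(1L) < subProb
    if (!do_sub) {
        ij <- sample.int(L, 2L)
        if (chars[ij[1L]] != chars[ij[2L]]) {
            chars[ij] <- chars[c(ij[2L], ij[1L])]
            return(paste(chars, collapse = ""))
        }
        # degenerate swap: fall through to a substitution
    }
    pos <- sample.int(L, 1L)
    alt <- setdiff(letters, chars[pos])
    chars[pos] <- alt[sample.int(length(alt), 1L)]
    paste(chars, collapse = "")
}
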