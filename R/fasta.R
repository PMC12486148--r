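#' Read peptides from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()]. In strict mode every
#' record must be a valid peptide of the requested length; in lenient mode
#' invalid records are dropped with a warning (lowercase letters are always
#' uppercased first).
#'
#' @param path Path to a FASTA file.
#' @param length Required peptide length, or `NULL` to accept any length.
#' @param strict If `TRUE` (default) invalid records raise an error; if
#'   `FALSE` they are dropped with a warning naming the offending records.
#' @return Named character vector of peptide sequences (names = FASTA ids).
#'   An empty file yields an empty vector.
#' @export
readPeptideFasta <- function(path, length = 12L, strict = TRUE) {
    if (file.info(path)$size == 0) return(setNames(character(0), character(0)))
    set <- Biostrings::readAAStringSet(path)
    seqs <- toupper(as.character(set))
    ids <- names(set)
    if (is.null(length)) return(setNames(seqs, ids))
    if (strict) {
        seqs <- setNames(validatePeptide(seqs, length), ids)
        return(seqs)
    }
    ok <- .is_valid_peptide(seqs, length)
    if (!all(ok))
        warning(sprintf("dropped %d invalid record(s): %s", sum(!ok),
                        paste(utils::head(ids[!ok], 5L), collapse = ", ")))
    setNames(seqs[ok], ids[ok])
}

#' Write peptides to a FASTA file
#'
#' @param x Character vector of peptide sequences; names (if any) become the
#'   FASTA ids, otherwise ids `pep_1 ... pep_n` are generated.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePeptideFasta <- function(x, path) {
    ids <- names(x)
    if (is.null(ids) || any(!nzchar(ids)))
        ids <- sprintf("pep_%d", seq_along(x))
    set <- Biostrings::AAStringSet(setNames(as.character(x), ids))
    Biostrings::writeXStringSet(set, path)
    invisible(path)
}

#' Read peptides from a plain one-sequence-per-line file
#'
#' Convenience dialect: one sequence per line, blank lines ignored, `#`
#' comment lines ignored.
#'
#' @inheritParams readPeptideFasta
#' @return Character vector of sequences.
#' @export
readPeptideLines <- function(path, length = 12L, strict = TRUE) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0L) return(character(0))
    lines <- toupper(lines)
    if (is.null(length)) return(lines)
    if (strict) return(validatePeptide(lines, length))
    ok <- .is_valid_peptide(lines, length)
    if (!all(ok)) warning(sprintf("dropped %d invalid line(s)", sum(!ok)))
    lines[ok]
}
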