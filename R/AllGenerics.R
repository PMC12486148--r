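#' Accessor generics
#'
#' Small accessor family used across the package's S4 classes: `material()`
#' returns the material label, `peptides()` the peptide sequences, `scores()`
#' the numeric scores, `archive()` the result table of a design run or
#' campaign, and `asScorer()` turns an object into a plain scoring function
#' `function(sequences) -> numeric` usable by the annealer.
#'
#' @param x An object of one of the package's classes.
#' @param ... Passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("material", function(x) standardGeneric("material"))

#' @rdname accessors
#' @export
setGeneric("peptides", function(x, ...) standardGeneric("peptides"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("archive", function(x) standardGeneric("archive"))

#' @rdname accessors
#' @export
setGeneric("asScorer", function(x, ...) standardGeneric("asScorer"))

#' Score peptides under a synthetic landscape
#'
#' @param ls A [SyntheticLandscape-class].
#' @param peptides Character vector of peptides of the landscape's length.
#' @param withNoise Add Gaussian observation noise (`noiseSigma`) drawn from
#'   R's current RNG stream.
#' @return Numeric vector of scores.
#' @export
setGeneric("oracleScore",
    function(ls, peptides, withNoise = FALSE) standardGeneric("oracleScore"))

#' Predict affinity scores with a trained surrogate
#'
#' @param object A [PeptideSurrogate-class].
#' @param peptides Character vector of peptides at the trained length.
#' @param batchSize Internal prediction batch size.
#' @return Numeric vector of predicted scores (one per peptide, finite).
#' @export
setGeneric("predictScores",
    function(object, peptides, ...) standardGeneric("predictScores"))

## ---- ScoreTable methods ----

#' @rdname accessors
#' @export
setMethod("material", "ScoreTable", function(x) x@material)

#' @rdname accessors
#' @export
setMethod("peptides", "ScoreTable", function(x, ...) x@sequence)

#' @rdname accessors
#' @export
setMethod("scores", "ScoreTable", function(x) x@score)

#' @describeIn ScoreTable Number of records.
#' @param x A `ScoreTable`.
#' @export
setMethod("length", "ScoreTable", function(x) length(x@sequence))

setMethod("show", "ScoreTable", function(object) {
    cat(sprintf("ScoreTable for material '%s': %d records\n",
                object@material, length(object@sequence)))
    if (length(object@sequence) > 0L) {
        cat(sprintf("  peptide length: %d\n", nchar(object@sequence[1L])))
        cat(sprintf("  score range: [%.2f, %.2f], mean %.2f\n",
                    min(object@score), max(object@score), mean(object@score)))
    }
})

setMethod("show", "SyntheticLandscape", function(object) {
    cat(sprintf("SyntheticLandscape '%s': L = %d, %d coupling pair(s), offset %.1f, noise sd %.2f (seed %d)\n",
                object@label, nrow(object@positionWeights),
                length(object@couplings), object@offset, object@noiseSigma,
                object@seed))
})

#' @rdname accessors
#' @export
setMethod("material", "SyntheticLandscape", function(x) x@label)

#' Landscapes of a family
#' @param x A [LandscapeFamily-class].
#' @return Named list of [SyntheticLandscape-class] objects.
#' @export
landscapes <- function(x) {
    stopifnot(is(x, "LandscapeFamily"))
    setNames(x@landscapes, vapply(x@landscapes, material, character(1L)))
}

setMethod("show", "LandscapeFamily", function(object) {
    cat(sprintf("LandscapeFamily: %d landscapes (target correlation %.2f): %s\n",
                length(object@landscapes), object@targetCorrelation,
                paste(vapply(object@landscapes, material, character(1L)),
                      collapse = ", ")))
})

setMethod("show", "PeptideSurrogate", function(object) {
    cfg <- object@config
    cat(sprintf("PeptideSurrogate for '%s': %s, %d layer(s), hidden %d, L = %d\n",
                object@material, cfg$architecture, cfg$numLayers, cfg$hiddenDim,
                object@peptideLength))
    if (nrow(object@history) > 0L)
        cat(sprintf("  trained %d epoch(s); best validation MSE %.4f\n",
                    nrow(object@history), min(object@history$val_loss)))
})

#' @rdname accessors
#' @export
setMethod("material", "PeptideSurrogate", function(x) x@material)

#' @rdname accessors
#' @export
setMethod("archive", "DesignRun", function(x) x@archive)

#' @rdname accessors
#' @export
setMethod("archive", "DesignArchive", function(x) x@archive)

#' @rdname accessors
#' @export
setMethod("peptides", "DesignRun", function(x, ...) x@archive$sequence)

#' @rdname accessors
#' @export
setMethod("peptides", "DesignArchive", function(x, ...) x@archive$sequence)

#' Trajectory of a design run
#' @param x A [DesignRun-class].
#' @return data.frame with columns `step`, `temperature`, `objective`,
#'   `accepted`.
#' @export
trajectory <- function(x) {
    stopifnot(is(x, "DesignRun"))
    x@trajectory
}

#' Running best objective value of a design run
#' @param x A [DesignRun-class].
#' @return Numeric vector (non-increasing), one entry per attempted mutation.
#' @export
bestSoFar <- function(x) {
    stopifnot(is(x, "DesignRun"))
    x@bestSoFar
}

setMethod("show", "DesignRun", function(object) {
    cat(sprintf("DesignRun (%s objective, %d steps, seed %d)\n",
                object@objective$mode, nrow(object@trajectory), object@seed))
    if (nrow(object@archive) > 0L)
        cat(sprintf("  best: %s (%.3f); archive: %d unique sequences\n",
                    object@archive$sequence[1L], object@archive$value[1L],
                    nrow(object@archive)))
})

setMethod("show", "DesignArchive", function(object) {
    cat(sprintf("DesignArchive (%s objective): %d runs, %d unique sequences\n",
                object@objective$mode, length(object@runBest),
                nrow(object@archive)))
    if (nrow(object@archive) > 0L)
        cat(sprintf("  best: %s (%.3f)\n",
                    object@archive$sequence[1L], object@archive$value[1L]))
})
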