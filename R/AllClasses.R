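#' @import methods
NULL

#' ScoreTable: a sequence-score table for one material
#'
#' Container for (peptide sequence, affinity score) records for a single
#' material. Scores follow the lower-is-better convention of biophysical
#' affinity scores (more negative = stronger predicted binding).
#'
#' @slot material Single non-empty material label (e.g. `"PET"`, `"PP"`, or a
#'   synthetic label).
#' @slot sequence Character vector of validated peptide sequences, all of one
#'   length.
#' @slot score Numeric vector of finite scores, parallel to `sequence`.
#' @aliases ScoreTable-class
#' @exportClass ScoreTable
setClass("ScoreTable",
    representation(material = "character",
                   sequence = "character",
                   score = "numeric"))

setValidity("ScoreTable", function(object) {
    if (length(object@material) != 1L || !nzchar(object@material))
        return("material must be a single non-empty string")
    if (length(object@sequence) != length(object@score))
        return("sequence and score must have equal length")
    if (length(object@sequence) > 0L) {
        if (length(unique(nchar(object@sequence))) != 1L)
            return("all peptides must share one length")
        if (any(!is.finite(object@score)))
            return("all scores must be finite")
    }
    TRUE
})

#' SyntheticLandscape: a ground-truth sequence-score function
#'
#' An additive-plus-pairwise score landscape over fixed-length peptides,
#' emulating the statistical structure (location, scale, mild epistasis) of a
#' biophysical affinity-score dataset. Score of peptide a =
#' `offset + sum_i W[i, a_i] + sum_(i,j) C[(i,j)][a_i, a_j]`, optionally plus
#' Gaussian noise.
#'
#' @slot label Material-style label.
#' @slot positionWeights L x 20 matrix of per-position residue weights
#'   (score units), columns in [aaAlphabet()] order.
#' @slot couplings List of pairwise terms, each `list(i =, j =, mat = 20x20)`.
#' @slot offset Scalar added to every score.
#' @slot noiseSigma Standard deviation of optional Gaussian observation noise.
#' @slot seed Seed the landscape was built from.
#' @aliases SyntheticLandscape-class
#' @exportClass SyntheticLandscape
setClass("SyntheticLandscape",
    representation(label = "character",
                   positionWeights = "matrix",
                   couplings = "list",
                   offset = "numeric",
                   noiseSigma = "numeric",
                   seed = "integer"))

setValidity("SyntheticLandscape", function(object) {
    if (ncol(object@positionWeights) != 20L)
        return("positionWeights must have 20 columns")
    if (any(!is.finite(object@positionWeights)))
        return("positionWeights must be finite")
    if (length(object@noiseSigma) != 1L || object@noiseSigma < 0)
        return("noiseSigma must be a single value >= 0")
    L <- nrow(object@positionWeights)
    for (cp in object@couplings) {
        if (!all(c("i", "j", "mat") %in% names(cp)))
            return("each coupling needs fields i, j, mat")
        if (cp$i >= cp$j || cp$i < 1L || cp$j > L)
            return("coupling positions must satisfy 1 <= i < j <= L")
        if (!all(dim(cp$mat) == c(20L, 20L)))
            return("coupling matrices must be 20 x 20")
    }
    TRUE
})

#' LandscapeFamily: correlated landscapes for several pseudo-materials
#'
#' A set of [SyntheticLandscape-class] objects sharing length and alphabet,
#' whose additive components were built with a controlled pairwise
#' correlation, so that promiscuous (correlated) and selective
#' (anti-correlated) design problems are well-posed.
#'
#' @slot landscapes List of `SyntheticLandscape` objects.
#' @slot targetCorrelation The correlation the additive components were
#'   constructed to have.
#' @aliases LandscapeFamily-class
#' @exportClass LandscapeFamily
setClass("LandscapeFamily",
    representation(landscapes = "list",
                   targetCorrelation = "numeric"))

setValidity("LandscapeFamily", function(object) {
    if (length(object@landscapes) < 2L)
        return("a family needs at least two landscapes")
    if (!all(vapply(object@landscapes, is, logical(1L), "SyntheticLandscape")))
        return("landscapes must all be SyntheticLandscape objects")
    Ls <- vapply(object@landscapes, function(x) nrow(x@positionWeights), integer(1L))
    if (length(unique(Ls)) != 1L)
        return("all landscapes must share one peptide length")
    if (abs(object@targetCorrelation) > 1)
        return("targetCorrelation must lie in [-1, 1]")
    TRUE
})

#' PeptideSurrogate: a trained sequence-to-score regressor
#'
#' A fitted neural surrogate (recurrent by default) that predicts the affinity
#' score of a peptide from its sequence alone. Prediction is deterministic
#' after training.
#'
#' @slot material Material label the model was trained for.
#' @slot config Training configuration (see [surrogateConfig()]).
#' @slot alphabet Alphabet ordering the one-hot encoding used (stored so the
#'   artifact is self-describing).
#' @slot peptideLength Trained peptide length.
#' @slot params Learned parameters (opaque list of matrices).
#' @slot normalization Either an empty list (raw scores) or
#'   `list(mean =, sd =)` for z-scored training targets.
#' @slot history Per-epoch data.frame with columns `epoch`, `train_loss`,
#'   `val_loss` (mean squared error, score units squared).
#' @aliases PeptideSurrogate-class
#' @exportClass PeptideSurrogate
setClass("PeptideSurrogate",
    representation(material = "character",
                   config = "list",
                   alphabet = "character",
                   peptideLength = "integer",
                   params = "list",
                   normalization = "list",
                   history = "data.frame"))

#' DesignRun: one simulated-annealing design trajectory
#'
#' @slot objective The design objective (see [designObjective()]).
#' @slot schedule The annealing schedule used (see [annealSchedule()]).
#' @slot trajectory data.frame with one row per attempted mutation: `step`,
#'   `temperature`, `objective`, `accepted`.
#' @slot bestSoFar Numeric vector: running best objective value per step
#'   (non-increasing).
#' @slot archive data.frame of the best unique sequences encountered:
#'   `sequence`, `value`, `step`; sorted ascending by `value`.
#' @slot seed Seed of the run.
#' @aliases DesignRun-class
#' @exportClass DesignRun
setClass("DesignRun",
    representation(objective = "list",
                   schedule = "list",
                   trajectory = "data.frame",
                   bestSoFar = "numeric",
                   archive = "data.frame",
                   seed = "integer"))

setValidity("DesignRun", function(object) {
    if (is.unsorted(-object@bestSoFar))
        return("bestSoFar must be non-increasing")
    a <- object@archive
    if (nrow(a) > 0L) {
        if (anyDuplicated(a$sequence)) return("archive sequences must be unique")
        if (is.unsorted(a$value)) return("archive must be sorted ascending by value")
    }
    TRUE
})

#' DesignArchive: merged, deduplicated results of a design campaign
#'
#' @slot archive data.frame `sequence`, `value`, `run`, `step`; unique
#'   sequences sorted ascending by `value` (best value kept per sequence).
#' @slot runBest Numeric vector of each run's best objective value.
#' @slot objective,schedule As for [DesignRun-class].
#' @slot baseSeed Base seed of the campaign (run r uses baseSeed + r - 1).
#' @aliases DesignArchive-class
#' @exportClass DesignArchive
setClass("DesignArchive",
    representation(archive = "data.frame",
                   runBest = "numeric",
                   objective = "list",
                   schedule = "list",
                   baseSeed = "integer"))

setValidity("DesignArchive", function(object) {
    a <- object@archive
    if (nrow(a) > 0L) {
        if (anyDuplicated(a$sequence)) return("archive sequences must be unique")
        if (is.unsorted(a$value)) return("archive must be sorted ascending by value")
    }
    TRUE
})
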