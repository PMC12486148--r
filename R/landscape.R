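#' Build a synthetic score landscape
#'
#' Constructs a ground-truth sequence-to-score function emulating the
#' statistical structure of a biophysical affinity-score dataset: an additive
#' per-position term plus a small number of pairwise (epistatic) couplings,
#' with optional Gaussian observation noise. Per-position weight rows and
#' coupling matrices are mean-centered, so random-peptide scores have mean
#' `offset` (default -40, the middle of the typical affinity-score band) and
#' standard deviation approximately `weightScale * sqrt(L)`.
#'
#' @param seed Integer seed; the landscape is a pure function of its
#'   arguments.
#' @param length Peptide length L (default 12).
#' @param nCouplings Number of random position pairs with pairwise terms
#'   (default 6; must be at most `L*(L-1)/2`). Coupling entries have standard
#'   deviation `weightScale / 4`: mild epistasis that distinguishes sequence
#'   models from purely additive fits without making the landscape
#'   unlearnable.
#' @param weightScale Standard deviation of the additive per-position weights
#'   (score units; default 2, giving random-peptide score sd of about 7).
#' @param offset Mean score of random peptides (default -40).
#' @param noiseSigma Observation-noise standard deviation (default 0.5).
#' @param label Material-style label.
#' @return A [SyntheticLandscape-class].
#' @examples
#' ls <- makeLandscape(seed = 1)
#' oracleScore(ls, "YWYERIFWRRMW")
#' @export
makeLandscape <- function(seed, length = 12L, nCouplings = 6L,
                          weightScale = 2, offset = -40, noiseSigma = 0.5,
                          label = sprintf("synth%d", seed)) {
    length <- as.integer(length)
    nCouplings <- as.integer(nCouplings)
    stopifnot(length >= 1L, nCouplings >= 0L, weightScale >= 0,
              is.finite(offset), noiseSigma >= 0)
    if (nCouplings > length * (length - 1L) / 2L)
        stop("nCouplings exceeds the number of position pairs")
    .with_seed(seed, {
        W <- matrix(stats::rnorm(length * 20L, sd = max(weightScale, 1e-12)),
                    nrow = length, ncol = 20L)
        if (weightScale == 0) W[] <- 0
        W <- W - rowMeans(W)  # zero mean per position over letters
        colnames(W) <- aaAlphabet()
        couplings <- list()
        if (nCouplings > 0L) {
            pairs <- utils::combn(length, 2L)
            sel <- sample.int(ncol(pairs), nCouplings)
            cscale <- weightScale / 4
            for (s in sel) {
                m <- matrix(stats::rnorm(400L, sd = max(cscale, 1e-12)), 20L, 20L)
                if (cscale == 0) m[] <- 0
                m <- m - mean(m)
                couplings[[base::length(couplings) + 1L]] <-
                    list(i = pairs[1L, s], j = pairs[2L, s], mat = m)
            }
        }
        new("SyntheticLandscape", label = as.character(label),
            positionWeights = W, couplings = couplings,
            offset = as.numeric(offset), noiseSigma = as.numeric(noiseSigma),
            seed = as.integer(seed))
    })
}

## score a 1-based n x L index matrix under a landscape (no noise)
.landscape_score_idx <- function(ls, idx) {
    n <- nrow(idx); L <- ncol(idx)
    stopifnot(L == nrow(ls@positionWeights))
    sc <- rep(ls@offset, n)
    W <- ls@positionWeights
    for (t in seq_len(L)) sc <- sc + W[t, idx[, t]]
    for (cp in ls@couplings) sc <- sc + cp$mat[cbind(idx[, cp$i], idx[, cp$j])]
    unname(sc)
}

#' @rdname oracleScore
#' @export
setMethod("oracleScore", "SyntheticLandscape",
    function(ls, peptides, withNoise = FALSE) {
        if (length(peptides) == 0L) return(numeric(0))
        idx <- .seq_index_matrix(peptides) + 1L
        sc <- .landscape_score_idx(ls, idx)
        if (withNoise && ls@noiseSigma > 0)
            sc <- sc + stats::rnorm(length(sc), sd = ls@noiseSigma)
        sc
    })

#' Generate a synthetic sequence-score dataset
#'
#' Samples `n` unique sequences and scores them under the landscape with
#' observation noise. `"uniform"` sampling draws sequences uniformly at
#' random; `"biased"` sampling enriches low-score sequences by following a
#' short greedy substitution walk (5 steps, improvements only, judged on the
#' noiseless score) from each uniform start, mimicking datasets that come
#' from score-optimizing trajectories.
#'
#' @param ls A [SyntheticLandscape-class].
#' @param n Number of records (must not exceed the sequence space).
#' @param seed Integer seed.
#' @param sampling `"uniform"` (default) or `"biased"`.
#' @return A [ScoreTable-class] with `n` unique sequences.
#' @export
generateDataset <- function(ls, n, seed, sampling = c("uniform", "biased")) {
    sampling <- match.arg(sampling)
    n <- as.integer(n)
    stopifnot(n >= 1L)
    L <- nrow(ls@positionWeights)
    if (L * log(20) < log(.Machine$integer.max) && n > 20^L)
        stop("n exceeds the number of distinct sequences")
    .with_seed(seed, {
        seqs <- character(0)
        while (length(seqs) < n) {
            need <- n - length(seqs)
            batch <- randomPeptide(ceiling(need * 1.1) + 8L, length = L)
            if (sampling == "biased") batch <- .greedy_walk(ls, batch, steps = 5L)
            seqs <- unique(c(seqs, batch))
        }
        seqs <- seqs[seq_len(n)]
        sc <- .landscape_score_idx(ls, .seq_index_matrix(seqs) + 1L)
        if (ls@noiseSigma > 0) sc <- sc + stats::rnorm(n, sd = ls@noiseSigma)
        new("ScoreTable", material = ls@label, sequence = seqs, score = sc)
    })
}

## vectorized greedy improvement walk: `steps` single-substitution proposals
## per sequence, accepting only score decreases (noiseless)
.greedy_walk <- function(ls, sequences, steps = 5L) {
    idx <- .seq_index_matrix(sequences) + 1L
    n <- nrow(idx); L <- ncol(idx)
    W <- ls@positionWeights
    for (s in seq_len(steps)) {
        pos <- sample.int(L, n, replace = TRUE)
        old <- idx[cbind(seq_len(n), pos)]
        shift <- sample.int(19L, n, replace = TRUE)
        newl <- ((old - 1L + shift) %% 20L) + 1L  # uniform over the 19 others
        delta <- W[cbind(pos, newl)] - W[cbind(pos, old)]
        for (cp in ls@couplings) {
            at_i <- pos == cp$i
            if (any(at_i)) {
                aj <- idx[at_i, cp$j]
                delta[at_i] <- delta[at_i] +
                    cp$mat[cbind(newl[at_i], aj)] - cp$mat[cbind(old[at_i], aj)]
            }
            at_j <- pos == cp$j
            if (any(at_j)) {
                ai <- idx[at_j, cp$i]
                delta[at_j] <- delta[at_j] +
                    cp$mat[cbind(ai, newl[at_j])] - cp$mat[cbind(ai, old[at_j])]
            }
        }
        acc <- delta < 0
        sel <- cbind(seq_len(n), pos)[acc, , drop = FALSE]
        idx[sel] <- newl[acc]
    }
    apply(idx, 1L, function(r) paste(aaAlphabet()[r], collapse = ""))
}

#' Build a family of correlated landscapes
#'
#' Constructs `k` landscapes whose additive components have a controlled
#' pairwise correlation `targetCorrelation`, so that multi-material
#' (promiscuous) and two-material (selective) design problems are well-posed.
#' For `k = 2` the second member is `rho * shared + sqrt(1 - rho^2) *
#' independent`, giving pairwise correlation `rho` for any `rho` in
#' `[-1, 1]`; for `k > 2` members share a common factor with loading
#' `sqrt(rho)`, which requires `rho >= 0`. Couplings and noise are drawn
#' independently per member.
#'
#' @param k Number of pseudo-materials (default 5, one per plastic in a
#'   typical multi-plastic campaign).
#' @param targetCorrelation Desired pairwise correlation of the additive
#'   components.
#' @param seed Integer seed.
#' @param length,nCouplings,weightScale,offset,noiseSigma As in
#'   [makeLandscape()].
#' @param labels Labels for the members (default `mat1 ... matk`).
#' @return A [LandscapeFamily-class].
#' @export
makeFamily <- function(k = 5L, targetCorrelation = 0.5, seed = 1L,
                       length = 12L, nCouplings = 6L, weightScale = 2,
                       offset = -40, noiseSigma = 0.5,
                       labels = sprintf("mat%d", seq_len(k))) {
    k <- as.integer(k); rho <- targetCorrelation
    stopifnot(k >= 2L, abs(rho) <= 1, base::length(labels) == k)
    if (k > 2L && rho < 0)
        stop("negative pairwise correlation for k > 2 members is not supported")
    length <- as.integer(length)
    members <- .with_seed(seed, {
        shared <- matrix(stats::rnorm(length * 20L), nrow = length)
        lapply(seq_len(k), function(m) {
            indep <- matrix(stats::rnorm(length * 20L), nrow = length)
            A <- if (k == 2L) {
                if (m == 1L) shared else rho * shared + sqrt(1 - rho^2) * indep
            } else {
                sqrt(max(rho, 0)) * shared + sqrt(1 - max(rho, 0)) * indep
            }
            A * weightScale
        })
    })
    landscapes <- lapply(seq_len(k), function(m) {
        # per-member couplings/noise come from a member-specific seed
        base <- makeLandscape(seed = seed + 1000L * m, length = length,
                              nCouplings = nCouplings,
                              weightScale = weightScale, offset = offset,
                              noiseSigma = noiseSigma, label = labels[m])
        W <- members[[m]] - rowMeans(members[[m]])
        colnames(W) <- aaAlphabet()
        base@positionWeights <- W
        base
    })
    new("LandscapeFamily", landscapes = landscapes,
        targetCorrelation = as.numeric(rho))
}

#' Serialize landscapes to JSON
#'
#' Writes a [SyntheticLandscape-class] (or every member of a
#' [LandscapeFamily-class]) to a JSON file at full precision, so any fixture
#' is regenerable bit-exactly.
#'
#' @param x A `SyntheticLandscape` or `LandscapeFamily`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeLandscapeJSON <- function(x, path) {
    enc1 <- function(ls) list(
        label = ls@label, offset = ls@offset, noiseSigma = ls@noiseSigma,
        seed = ls@seed, alphabet = paste(aaAlphabet(), collapse = ""),
        positionWeights = unclass(ls@positionWeights),
        couplings = lapply(ls@couplings, function(cp)
            list(i = cp$i, j = cp$j, mat = unclass(cp$mat))))
    obj <- if (is(x, "LandscapeFamily"))
        list(targetCorrelation = x@targetCorrelation,
             landscapes = lapply(x@landscapes, enc1))
    else enc1(x)
    jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
    invisible(path)
}

#' Read landscapes back from JSON
#'
#' @param path Path written by [writeLandscapeJSON()].
#' @return A [SyntheticLandscape-class] or [LandscapeFamily-class].
#' @export
readLandscapeJSON <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyMatrix = TRUE,
                               simplifyDataFrame = FALSE)
    dec1 <- function(o) {
        W <- as.matrix(o$positionWeights)
        colnames(W) <- aaAlphabet()
        cps <- list()
        if (!is.null(o$couplings) && base::length(o$couplings) > 0L) {
            raw <- o$couplings
            if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
            cps <- lapply(raw, function(cp) {
                cp <- as.list(cp)
                m <- cp$mat
                if (is.list(m) && !is.matrix(m))
                    m <- do.call(rbind, lapply(m, unlist))
                if (is.list(m)) m <- matrix(as.numeric(unlist(m)), 20L, 20L)
                list(i = as.integer(cp$i), j = as.integer(cp$j),
                     mat = matrix(as.numeric(m), 20L, 20L))
            })
            names(cps) <- NULL
        }
        new("SyntheticLandscape", label = o$label, positionWeights = W,
            couplings = cps, offset = as.numeric(o$offset),
            noiseSigma = as.numeric(o$noiseSigma), seed = as.integer(o$seed))
    }
    if (!is.null(obj$landscapes))
        new("LandscapeFamily",
            landscapes = lapply(obj$landscapes, dec1),
            targetCorrelation = as.numeric(obj$targetCorrelation))
    else dec1(obj)
}
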