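#' Annealing schedule
#'
#' Temperature program of a simulated-annealing design run. The default
#' attempts 21 525 mutations and cools exponentially from `tInitial` to
#' `tFinal`: `T_k = T0 * (Tf/T0)^((k-1)/(steps-1))`. The defaults T0 = 5 and
#' Tf = 0.05 score units put the starting temperature at roughly the
#' landscape's score standard deviation (free early exploration) and freeze
#' the chain at the end; a linear program is available as an alternative.
#'
#' @param steps Number of attempted mutations (default 21525).
#' @param tInitial,tFinal Start and end temperatures (score units;
#'   `0 < tFinal <= tInitial`).
#' @param decay `"exponential"` (default) or `"linear"`.
#' @return A list of class `"annealSchedule"`.
#' @export
annealSchedule <- function(steps = 21525L, tInitial = 5, tFinal = 0.05,
                           decay = c("exponential", "linear")) {
    decay <- match.arg(decay)
    steps <- as.integer(steps)
    stopifnot(steps >= 1L, tInitial > 0, tFinal > 0, tFinal <= tInitial)
    structure(list(steps = steps, tInitial = tInitial, tFinal = tFinal,
                   decay = decay), class = "annealSchedule")
}

## temperature at steps 1..steps
.schedule_temps <- function(s) {
    if (s$steps == 1L) return(s$tInitial)
    f <- (seq_len(s$steps) - 1) / (s$steps - 1)
    if (s$decay == "exponential") s$tInitial * (s$tFinal / s$tInitial)^f
    else s$tInitial + (s$tFinal - s$tInitial) * f
}

#' Design objective
#'
#' The three design goals, all minimized (lower affinity score = stronger
#' predicted binding): `"single"` minimizes one material's score,
#' `"promiscuous"` minimizes the mean score over a material set (high average
#' affinity), and `"selective"` minimizes the difference target minus
#' off-target (large affinity gap in favour of the target).
#'
#' @param mode One of `"single"`, `"promiscuous"`, `"selective"`.
#' @param materials Character vector of material labels: exactly 1 for
#'   single, at least 2 for promiscuous, exactly 2 (target, off-target) for
#'   selective.
#' @return A list of class `"designObjective"`.
#' @export
designObjective <- function(mode = c("single", "promiscuous", "selective"),
                            materials) {
    mode <- match.arg(mode)
    materials <- as.character(materials)
    n <- length(materials)
    if (mode == "single" && n != 1L)
        stop("single objective needs exactly one material")
    if (mode == "promiscuous" && n < 2L)
        stop("promiscuous objective needs at least two materials")
    if (mode == "selective" && n != 2L)
        stop("selective objective needs exactly [target, off_target]")
    structure(list(mode = mode, materials = materials),
              class = "designObjective")
}

#' @rdname accessors
#' @export
setMethod("asScorer", "PeptideSurrogate", function(x, ...) {
    handle <- .nn_handle(x@config$architecture, x@params,
                         x@config$numLayers, x@config$hiddenDim)
    len <- x@peptideLength
    norm <- x@normalization
    function(sequences) {
        out <- .nn_predict_handle(handle, .seq_index_matrix(sequences))
        if (length(norm) > 0L) out <- out * norm$sd + norm$mean
        out
    }
})

#' @rdname accessors
#' @export
setMethod("asScorer", "SyntheticLandscape", function(x, ...) {
    function(sequences) oracleScore(x, sequences, withNoise = FALSE)
})

#' @rdname accessors
#' @export
setMethod("asScorer", "function", function(x, ...) x)

## resolve the objective's scorers once; returns list(fns, value(seqs))
.resolve_objective <- function(scorers, objective) {
    stopifnot(inherits(objective, "designObjective"))
    if (is.null(names(scorers)) || any(!nzchar(names(scorers))))
        stop("scorers must be a named list keyed by material label")
    fns <- lapply(objective$materials, function(mlab) {
        if (!mlab %in% names(scorers))
            stop("no scorer available for material '", mlab, "'")
        asScorer(scorers[[mlab]])
    })
    value <- switch(objective$mode,
        single = function(s) fns[[1L]](s),
        promiscuous = function(s) {
            acc <- fns[[1L]](s)
            for (i in seq_along(fns)[-1L]) acc <- acc + fns[[i]](s)
            acc / length(fns)
        },
        selective = function(s) fns[[1L]](s) - fns[[2L]](s))
    list(fns = fns, value = value)
}

#' Objective value of peptides under a set of scorers
#'
#' Single-material: the scorer's own score. Promiscuous: the arithmetic mean
#' score over the objective's materials. Selective: score(target) minus
#' score(off-target). All are minimized (lower is better).
#'
#' @param scorers Named list of scorers (anything accepted by [asScorer()]:
#'   a [PeptideSurrogate-class], a [SyntheticLandscape-class], or a plain
#'   `function(sequences) -> numeric`), keyed by material label.
#' @param objective A [designObjective()].
#' @param peptides Character vector of peptide sequences.
#' @return Numeric vector of objective values.
#' @export
objectiveValue <- function(scorers, objective, peptides) {
    .resolve_objective(scorers, objective)$value(peptides)
}

#' Metropolis acceptance
#'
#' Accepts a proposed change in objective value `delta` at temperature `T`
#' with probability 1 if `delta <= 0` and `exp(-delta/T)` otherwise. Draws
#' from R's current RNG stream; vectorized over `delta`.
#'
#' @param delta Numeric vector of objective changes (candidate minus
#'   current).
#' @param temperature Positive temperature (scalar or vector).
#' @return Logical vector of acceptances.
#' @export
metropolisAccept <- function(delta, temperature) {
    if (any(temperature <= 0)) stop("temperature must be positive")
    n <- max(length(delta), length(temperature))
    delta <- rep_len(delta, n)
    temperature <- rep_len(temperature, n)
    accept <- delta <= 0
    up <- which(!accept)
    if (length(up) > 0L)
        accept[up] <- stats::runif(length(up)) <
            exp(-delta[up] / temperature[up])
    accept
}

#' Run one simulated-annealing design
#'
#' Starts from a random sequence (or a given one), proposes
#' substitution/swap mutations, scores each candidate through the objective,
#' and accepts or rejects by the Metropolis criterion under the schedule's
#' cooling program. Every scored sequence enters the run's archive, which
#' keeps the best `archiveSize` unique sequences.
#'
#' @inheritParams objectiveValue
#' @param schedule An [annealSchedule()].
#' @param seed Integer seed; the run is fully reproducible given its inputs.
#' @param start Optional start peptide (default: uniform random).
#' @param length Peptide length when `start` is random (default 12).
#' @param letters Design alphabet (default the full 20 letters; a subset
#'   restricts the search to a reduced alphabet).
#' @param subProb Substitution-vs-swap mix passed to [proposeMutation()].
#' @param archiveSize Archive capacity per run (default 1000).
#' @return A [DesignRun-class].
#' @export
runAnnealing <- function(scorers, objective, schedule = annealSchedule(),
                         seed = 1L, start = NULL, length = 12L,
                         letters = aaAlphabet(), subProb = 0.5,
                         archiveSize = 1000L) {
    stopifnot(inherits(schedule, "annealSchedule"))
    obj <- .resolve_objective(scorers, objective)
    temps <- .schedule_temps(schedule)
    .with_seed(seed, {
        current <- if (is.null(start)) randomPeptide(1L, length, letters)
                   else validatePeptide(start, length)
        score1 <- function(s, k) {
            v <- tryCatch(obj$value(s), error = function(e)
                stop("scorer failed at step ", k, ": ", conditionMessage(e)))
            if (!is.finite(v)) stop("non-finite objective at step ", k)
            v
        }
        cur_val <- score1(current, 0L)
        arc <- new.env(hash = TRUE, parent = emptyenv())
        note <- function(s, v, k) {
            old <- get0(s, envir = arc, inherits = FALSE)
            if (is.null(old) || v < old[1L]) arc[[s]] <- c(v, k)
        }
        note(current, cur_val, 0L)
        steps <- schedule$steps
        obj_trace <- numeric(steps)
        acc_trace <- logical(steps)
        best_trace <- numeric(steps)
        best <- cur_val
        for (k in seq_len(steps)) {
            cand <- proposeMutation(current, subProb, letters)
            cval <- score1(cand, k)
            note(cand, cval, k)
            if (metropolisAccept(cval - cur_val, temps[k])) {
                current <- cand
                cur_val <- cval
                acc_trace[k] <- TRUE
            }
            if (cval < best) best <- cval
            obj_trace[k] <- cval
            best_trace[k] <- best
        }
        seqs <- ls(arc)
        vals <- vapply(seqs, function(s) arc[[s]][1L], numeric(1L))
        at <- vapply(seqs, function(s) arc[[s]][2L], numeric(1L))
        ord <- order(vals, seqs)[seq_len(min(base::length(seqs), archiveSize))]
        new("DesignRun", objective = unclass(objective),
            schedule = unclass(schedule),
            trajectory = data.frame(step = seq_len(steps),
                                    temperature = temps,
                                    objective = obj_trace,
                                    accepted = acc_trace),
            bestSoFar = best_trace,
            archive = data.frame(sequence = seqs[ord], value = vals[ord],
                                 step = as.integer(at[ord]),
                                 row.names = NULL,
                                 stringsAsFactors = FALSE),
            seed = as.integer(seed))
    })
}

#' Run a design campaign of independent annealing runs
#'
#' Runs `nRuns` independent designs with seeds `baseSeed + 0:(nRuns-1)`,
#' merges the run archives keeping the best value per unique sequence, and
#' sorts ascending. Per-run best values are retained as campaign metadata.
#'
#' @inheritParams runAnnealing
#' @param nRuns Number of independent runs (a full-scale campaign uses 55).
#' @param baseSeed Base seed.
#' @return A [DesignArchive-class].
#' @export
runCampaign <- function(scorers, objective, schedule = annealSchedule(),
                        nRuns = 55L, baseSeed = 1L, ...) {
    nRuns <- as.integer(nRuns)
    stopifnot(nRuns >= 1L)
    runs <- lapply(seq_len(nRuns), function(r) {
        tryCatch(runAnnealing(scorers, objective, schedule,
                              seed = baseSeed + r - 1L, ...),
                 error = function(e)
                     stop("run ", r, " failed: ", conditionMessage(e)))
    })
    merged <- do.call(rbind, lapply(seq_len(nRuns), function(r) {
        a <- runs[[r]]@archive
        if (nrow(a) == 0L) return(NULL)
        a$run <- r
        a
    }))
    merged <- merged[order(merged$value, merged$sequence), , drop = FALSE]
    merged <- merged[!duplicated(merged$sequence), , drop = FALSE]
    rownames(merged) <- NULL
    new("DesignArchive",
        archive = merged[, c("sequence", "value", "run", "step")],
        runBest = vapply(runs, function(r) r@archive$value[1L], numeric(1L)),
        objective = unclass(objective), schedule = unclass(schedule),
        baseSeed = as.integer(baseSeed))
}

#' Write a design archive as TSV (and optionally FASTA)
#'
#' Columns: `rank`, `sequence`, `value`, per-material predicted scores (one
#' column per scorer, if given), `run`, `step`.
#'
#' @param x A [DesignArchive-class] or [DesignRun-class].
#' @param path Output TSV path.
#' @param scorers Optional named list of scorers used to add per-material
#'   score columns.
#' @param fasta Optional FASTA path; headers carry rank and objective value.
#' @return `path`, invisibly.
#' @export
writeArchiveTSV <- function(x, path, scorers = NULL, fasta = NULL) {
    a <- archive(x)
    df <- data.frame(rank = seq_len(nrow(a)), sequence = a$sequence,
                     value = a$value, stringsAsFactors = FALSE)
    if (!is.null(scorers))
        for (mlab in names(scorers))
            df[[paste0("score_", mlab)]] <- asScorer(scorers[[mlab]])(a$sequence)
    if (!is.null(a$run)) df$run <- a$run
    df$step <- a$step
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(fasta))
        writePeptideFasta(
            setNames(a$sequence,
                     sprintf("design_%d value=%.4f", seq_len(nrow(a)), a$value)),
            fasta)
    invisible(path)
}
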