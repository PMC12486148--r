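#' Surrogate training configuration
#'
#' Bundles the architecture and training hyperparameters of a sequence-to-
#' score regressor. The default architecture is the LSTM with 2 layers and
#' hidden dimension 512, the optimum of the layers-by-hidden grid search; a
#' desk-scale "toy profile" (1 layer, hidden 128) is convenient for tests and
#' small benchmarks and is what the packaged examples use.
#'
#' @param architecture One of `"lstm"`, `"bilstm"`, `"gru"`, `"rnn"`,
#'   `"transformer"`.
#' @param numLayers Number of stacked layers (>= 1).
#' @param hiddenDim Hidden dimension per layer (>= 1).
#' @param epochs Maximum training epochs (default 100).
#' @param batchSize Minibatch size (default 256).
#' @param learningRate Adam learning rate (default 1e-3).
#' @param patience Early-stopping patience in epochs on validation loss
#'   (default 10). The learning rate is additionally halved whenever the
#'   validation loss fails to improve for `ceiling(patience / 3)` consecutive
#'   epochs (reduce-on-plateau), which lets a single run both explore and
#'   fine-tune.
#' @param weightDecay Decoupled (AdamW-style) weight-decay coefficient
#'   applied to all weight matrices (default 1e-4); biases and layer-norm
#'   parameters are exempt.
#' @param emaDecay Polyak averaging coefficient: validation and the final
#'   model use an exponential moving average of the weights with this decay
#'   per minibatch (default 0.999; 0 disables averaging). Averaged weights
#'   smooth out minibatch noise and usually generalize better than the last
#'   iterate.
#' @param normalize Z-score the training targets (parameters stored in the
#'   artifact and inverted at prediction time). Default `FALSE`: scores are
#'   used raw.
#' @param seed Integer seed controlling initialization and batch order.
#' @return A list of class `"surrogateConfig"`.
#' @examples
#' surrogateConfig("lstm", numLayers = 1, hiddenDim = 128, seed = 7)
#' @export
surrogateConfig <- function(architecture = c("lstm", "bilstm", "gru", "rnn",
                                             "transformer"),
                            numLayers = 2L, hiddenDim = 512L, epochs = 100L,
                            batchSize = 256L, learningRate = 1e-3,
                            patience = 10L, weightDecay = 1e-4,
                            emaDecay = 0.999, normalize = FALSE, seed = 1L) {
    architecture <- match.arg(architecture)
    numLayers <- as.integer(numLayers); hiddenDim <- as.integer(hiddenDim)
    stopifnot(numLayers >= 1L, hiddenDim >= 1L, epochs >= 1L, batchSize >= 1L,
              learningRate > 0, patience >= 1L, weightDecay >= 0,
              emaDecay >= 0, emaDecay < 1)
    structure(list(architecture = architecture, numLayers = numLayers,
                   hiddenDim = hiddenDim, epochs = as.integer(epochs),
                   batchSize = as.integer(batchSize),
                   learningRate = learningRate, patience = as.integer(patience),
                   weightDecay = weightDecay, emaDecay = emaDecay,
                   normalize = isTRUE(normalize), seed = as.integer(seed)),
              class = "surrogateConfig")
}

## parameter initialization; call inside .with_seed
.init_params <- function(arch, nlayers, H, L) {
    U <- function(nr, nc, k) matrix(stats::runif(nr * nc, -k, k), nr, nc)
    Uv <- function(n, k) stats::runif(n, -k, k)
    p <- list()
    kh <- 1 / sqrt(H)
    if (arch %in% c("lstm", "gru", "rnn")) {
        for (l in seq_len(nlayers)) {
            D <- if (l == 1L) 20L else H
            if (arch == "lstm") {
                p[[sprintf("Wx_%d", l)]] <- U(D, 4L * H, kh)
                p[[sprintf("Wh_%d", l)]] <- U(H, 4L * H, kh)
                b <- numeric(4L * H)
                b[(H + 1L):(2L * H)] <- 1  # forget-gate bias 1: remember early
                p[[sprintf("b_%d", l)]] <- b
            } else if (arch == "gru") {
                p[[sprintf("Wx_%d", l)]] <- U(D, 3L * H, kh)
                p[[sprintf("Whzr_%d", l)]] <- U(H, 2L * H, kh)
                p[[sprintf("Whn_%d", l)]] <- U(H, H, kh)
                p[[sprintf("b_%d", l)]] <- numeric(3L * H)
            } else {
                p[[sprintf("Wx_%d", l)]] <- U(D, H, kh)
                p[[sprintf("Wh_%d", l)]] <- U(H, H, kh)
                p[[sprintf("b_%d", l)]] <- numeric(H)
            }
        }
        p$w_out <- Uv(H, kh)
    } else if (arch == "bilstm") {
        for (l in seq_len(nlayers)) {
            D <- if (l == 1L) 20L else 2L * H
            for (side in c("f", "b")) {
                p[[sprintf("Wx%s_%d", side, l)]] <- U(D, 4L * H, kh)
                p[[sprintf("Wh%s_%d", side, l)]] <- U(H, 4L * H, kh)
                b <- numeric(4L * H)
                b[(H + 1L):(2L * H)] <- 1
                p[[sprintf("b%s_%d", side, l)]] <- b
            }
        }
        p$w_out <- Uv(2L * H, 1 / sqrt(2 * H))
    } else { # transformer
        Fdim <- 2L * H
        p$We <- U(20L, H, sqrt(3 / H))
        for (l in seq_len(nlayers)) {
            p[[sprintf("ln1g_%d", l)]] <- rep(1, H)
            p[[sprintf("ln1b_%d", l)]] <- numeric(H)
            for (w in c("Wq", "Wk", "Wv", "Wo"))
                p[[sprintf("%s_%d", w, l)]] <- U(H, H, sqrt(3 / H))
            p[[sprintf("ln2g_%d", l)]] <- rep(1, H)
            p[[sprintf("ln2b_%d", l)]] <- numeric(H)
            p[[sprintf("W1_%d", l)]] <- U(H, Fdim, sqrt(3 / H))
            p[[sprintf("b1_%d", l)]] <- numeric(Fdim)
            p[[sprintf("W2_%d", l)]] <- U(Fdim, H, sqrt(3 / Fdim))
            p[[sprintf("b2_%d", l)]] <- numeric(H)
        }
        p$lnfg <- rep(1, H)
        p$lnfb <- numeric(H)
        p$w_out <- Uv(H, kh)
    }
    p$b_out <- 0
    p
}

## Adam with global-norm gradient clipping; state updated in place by value
.adam_step <- function(params, grads, state, lr, wd = 0, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8, clip = 5) {
    gn2 <- sum(vapply(grads, function(g) sum(as.numeric(g)^2), numeric(1L)))
    scale <- if (sqrt(gn2) > clip) clip / sqrt(gn2) else 1
    state$t <- state$t + 1L
    bc1 <- 1 - beta1^state$t
    bc2 <- 1 - beta2^state$t
    for (k in names(params)) {
        g <- as.numeric(grads[[k]]) * scale
        state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
        state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
        upd <- lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
        pv <- as.numeric(params[[k]]) - upd
        # decoupled weight decay on weight matrices only
        if (wd > 0 && !is.null(dim(params[[k]])) && startsWith(k, "W"))
            pv <- pv - lr * wd * pv
        dp <- dim(params[[k]])
        if (!is.null(dp)) dim(pv) <- dp
        params[[k]] <- pv
    }
    list(params = params, state = state)
}

.predict_idx <- function(arch, params, idx0, nlayers, hidden,
                         chunk = 4096L) {
    n <- nrow(idx0)
    out <- numeric(n)
    start <- 1L
    while (start <= n) {
        end <- min(start + chunk - 1L, n)
        out[start:end] <- .nn_predict(arch, params,
                                      idx0[start:end, , drop = FALSE],
                                      nlayers, hidden)
        start <- end + 1L
    }
    out
}

#' Train a sequence-to-score surrogate
#'
#' Fits the configured regressor to a training [ScoreTable-class] by
#' minibatch gradient descent on mean squared error (Adam optimizer,
#' gradient-norm clipping), monitoring loss on a validation table after every
#' epoch. The parameters with the best validation loss are retained (early
#' stopping with the configured patience). Training is fully reproducible
#' under a fixed `config$seed` and single-threaded numerics.
#'
#' @param train,validation Non-empty [ScoreTable-class] objects of one
#'   peptide length.
#' @param config A [surrogateConfig()].
#' @return A [PeptideSurrogate-class].
#' @export
trainSurrogate <- function(train, validation, config = surrogateConfig()) {
    stopifnot(is(train, "ScoreTable"), is(validation, "ScoreTable"),
              inherits(config, "surrogateConfig"))
    if (length(train) == 0L || length(validation) == 0L)
        stop("train and validation tables must be non-empty")
    L <- nchar(peptides(train)[1L])
    if (nchar(peptides(validation)[1L]) != L)
        stop("train and validation peptide lengths differ")
    Xtr <- .seq_index_matrix(peptides(train))
    Xva <- .seq_index_matrix(peptides(validation))
    ytr <- scores(train)
    yva <- scores(validation)
    norm <- list()
    if (config$normalize) {
        norm <- list(mean = mean(ytr), sd = max(stats::sd(ytr), 1e-12))
        ytr <- (ytr - norm$mean) / norm$sd
        yva <- (yva - norm$mean) / norm$sd
    }
    fit <- .with_seed(config$seed, {
        params <- .init_params(config$architecture, config$numLayers,
                               config$hiddenDim, L)
        params$b_out <- mean(ytr)  # start at the target mean
        state <- list(t = 0L,
                      m = lapply(params, function(p) numeric(length(p))),
                      v = lapply(params, function(p) numeric(length(p))))
        ema_d <- config$emaDecay %||% 0
        # zero-initialized EMA with bias correction (so short runs are not
        # dragged toward the random initialization)
        ema <- lapply(params, function(p) p * 0)
        ema_t <- 0L
        n <- nrow(Xtr)
        bs <- min(config$batchSize, n)
        history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                              val_loss = numeric(0))
        best <- list(loss = Inf, params = params)
        wait <- 0L
        lr <- config$learningRate
        lr_wait <- 0L
        lr_patience <- max(1L, as.integer(ceiling(config$patience / 3)))
        for (epoch in seq_len(config$epochs)) {
            perm <- sample.int(n)
            tot <- 0
            nb <- 0L
            for (start in seq(1L, n, by = bs)) {
                take <- perm[start:min(start + bs - 1L, n)]
                res <- .nn_loss_grad(config$architecture, params,
                                     Xtr[take, , drop = FALSE], ytr[take],
                                     config$numLayers, config$hiddenDim)
                if (!is.finite(res$loss))
                    stop("non-finite training loss at epoch ", epoch)
                st <- .adam_step(params, res$grads, state, lr = lr,
                                 wd = config$weightDecay %||% 0)
                params <- st$params
                state <- st$state
                if (ema_d > 0) {
                    ema_t <- ema_t + 1L
                    for (k in names(ema))
                        ema[[k]] <- ema_d * ema[[k]] +
                            (1 - ema_d) * params[[k]]
                }
                tot <- tot + res$loss * length(take)
                nb <- nb + length(take)
            }
            eval_params <- if (ema_d > 0) {
                corr <- 1 - ema_d^ema_t
                lapply(ema, function(p) p / corr)
            } else params
            pv <- .predict_idx(config$architecture, eval_params, Xva,
                               config$numLayers, config$hiddenDim)
            vloss <- mean((pv - yva)^2)
            if (!is.finite(vloss))
                stop("non-finite validation loss at epoch ", epoch)
            history <- rbind(history,
                             data.frame(epoch = epoch, train_loss = tot / nb,
                                        val_loss = vloss))
            if (vloss < best$loss - 1e-12) {
                best <- list(loss = vloss, params = eval_params)
                wait <- 0L
                lr_wait <- 0L
            } else {
                wait <- wait + 1L
                lr_wait <- lr_wait + 1L
                if (wait >= config$patience) break
                if (lr_wait >= lr_patience) {
                    lr <- lr / 2
                    lr_wait <- 0L
                }
            }
        }
        list(params = best$params, history = history)
    })
    new("PeptideSurrogate", material = material(train),
        config = unclass(config), alphabet = aaAlphabet(),
        peptideLength = as.integer(L), params = fit$params,
        normalization = norm, history = fit$history)
}

#' @rdname predictScores
#' @param ... Unused.
#' @export
setMethod("predictScores", "PeptideSurrogate",
    function(object, peptides, batchSize = 4096L, ...) {
        if (length(peptides) == 0L) return(numeric(0))
        peptides <- validatePeptide(peptides, object@peptideLength)
        if (!identical(object@alphabet, aaAlphabet()))
            stop("model artifact uses a different alphabet ordering")
        idx <- .seq_index_matrix(peptides)
        out <- .predict_idx(object@config$architecture, object@params, idx,
                            object@config$numLayers, object@config$hiddenDim,
                            chunk = batchSize)
        if (length(object@normalization) > 0L)
            out <- out * object@normalization$sd + object@normalization$mean
        out
    })

#' Evaluate a surrogate on a held-out table
#'
#' Computes the coefficient of determination `R^2 = 1 - SS_res / SS_tot` and
#' the root-mean-square error of the predictions against the table's scores.
#' If the test scores have zero variance, `rSquared` is `NA` (undefined) and
#' `rmse` is still returned.
#'
#' @param model A [PeptideSurrogate-class].
#' @param test A non-empty [ScoreTable-class].
#' @return A list with `rSquared`, `rmse` and `n`.
#' @export
evaluateSurrogate <- function(model, test) {
    stopifnot(is(test, "ScoreTable"), length(test) > 0L)
    y <- scores(test)
    p <- predictScores(model, peptides(test))
    ss_res <- sum((y - p)^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
    list(rSquared = r2, rmse = sqrt(mean((y - p)^2)), n = length(y))
}

#' Grid search over depth and width
#'
#' Trains one model per (layers, hidden) combination and scores each on the
#' validation split by R^2, reproducing the layers-by-hidden hyperparameter
#' sweep at whatever scale the inputs allow. A failed cell is flagged rather
#' than aborting the grid.
#'
#' @param train,validation [ScoreTable-class] splits.
#' @param layerChoices,hiddenChoices Integer vectors of candidate depths and
#'   widths (defaults 1:3 and c(128, 256, 512)).
#' @param baseConfig [surrogateConfig()] whose other settings are shared by
#'   every cell.
#' @return data.frame with columns `numLayers`, `hiddenDim`, `rSquared`,
#'   `error`; the best cell is attached as `attr(, "best")`.
#' @export
gridSearch <- function(train, validation, layerChoices = 1:3,
                       hiddenChoices = c(128L, 256L, 512L),
                       baseConfig = surrogateConfig()) {
    stopifnot(length(layerChoices) >= 1L, length(hiddenChoices) >= 1L)
    grid <- expand.grid(numLayers = as.integer(layerChoices),
                        hiddenDim = as.integer(hiddenChoices))
    grid$rSquared <- NA_real_
    grid$error <- NA_character_
    for (i in seq_len(nrow(grid))) {
        cfg <- baseConfig
        cfg$numLayers <- grid$numLayers[i]
        cfg$hiddenDim <- grid$hiddenDim[i]
        res <- tryCatch({
            m <- trainSurrogate(train, validation, cfg)
            evaluateSurrogate(m, validation)$rSquared
        }, error = function(e) conditionMessage(e))
        if (is.numeric(res)) grid$rSquared[i] <- res
        else grid$error[i] <- res
    }
    best <- which.max(grid$rSquared)
    attr(grid, "best") <- grid[best, c("numLayers", "hiddenDim", "rSquared")]
    grid
}

#' Compare regressor architectures on a shared benchmark
#'
#' Trains one model per requested architecture at matched depth/width and
#' reports wall-clock training time, R^2 and RMSE on the shared test split.
#' Per-architecture failures are flagged in the `error` column and the table
#' is still returned. Training time is hardware-dependent bookkeeping, not a
#' tested quantity.
#'
#' @param train,validation,test [ScoreTable-class] splits.
#' @param architectures Character vector of architectures (default all five).
#' @param config Shared [surrogateConfig()] (its `architecture` field is
#'   overridden per row).
#' @return data.frame `architecture`, `seconds`, `rSquared`, `rmse`, `error`.
#' @export
compareArchitectures <- function(train, validation, test,
                                 architectures = c("lstm", "bilstm", "gru",
                                                   "rnn", "transformer"),
                                 config = surrogateConfig()) {
    out <- data.frame(architecture = architectures, seconds = NA_real_,
                      rSquared = NA_real_, rmse = NA_real_,
                      error = NA_character_, stringsAsFactors = FALSE)
    for (i in seq_along(architectures)) {
        cfg <- config
        cfg$architecture <- architectures[i]
        t0 <- proc.time()[["elapsed"]]
        res <- tryCatch({
            m <- trainSurrogate(train, validation, cfg)
            evaluateSurrogate(m, test)
        }, error = function(e) conditionMessage(e))
        out$seconds[i] <- proc.time()[["elapsed"]] - t0
        if (is.list(res)) {
            out$rSquared[i] <- res$rSquared
            out$rmse[i] <- res$rmse
        } else out$error[i] <- res
    }
    out
}

#' Save a trained surrogate as a directory artifact
#'
#' Writes an opaque weights file (`weights.rds`) plus a human-readable JSON
#' sidecar (`meta.json`) recording architecture, depth, width, alphabet
#' ordering, peptide length, normalization and seed, so the artifact is
#' self-describing.
#'
#' @param model A [PeptideSurrogate-class].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
saveSurrogate <- function(model, dir) {
    stopifnot(is(model, "PeptideSurrogate"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(model@params, file.path(dir, "weights.rds"))
    meta <- list(material = model@material, config = model@config,
                 alphabet = paste(model@alphabet, collapse = ""),
                 peptideLength = model@peptideLength,
                 normalization = model@normalization,
                 history = model@history)
    jsonlite::write_json(meta, file.path(dir, "meta.json"), digits = I(17),
                         auto_unbox = TRUE, dataframe = "columns")
    invisible(dir)
}

#' Load a surrogate artifact written by [saveSurrogate()]
#'
#' @param dir Artifact directory.
#' @return A [PeptideSurrogate-class] giving identical predictions to the
#'   saved model.
#' @export
loadSurrogate <- function(dir) {
    meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                                simplifyVector = TRUE)
    params <- readRDS(file.path(dir, "weights.rds"))
    cfg <- meta$config
    cfg$architecture <- as.character(cfg$architecture)
    norm <- meta$normalization
    if (is.null(norm) || length(norm) == 0L) norm <- list()
    else norm <- list(mean = as.numeric(norm$mean), sd = as.numeric(norm$sd))
    hist <- as.data.frame(meta$history)
    new("PeptideSurrogate", material = meta$material, config = cfg,
        alphabet = strsplit(meta$alphabet, "")[[1L]],
        peptideLength = as.integer(meta$peptideLength), params = params,
        normalization = norm, history = hist)
}

#' Desk-scale training profile
#'
#' The packaged small-benchmark configuration: 1 layer, hidden dimension 128,
#' minibatch 64, learning rate 5e-3 with reduce-on-plateau, weight decay
#' 1e-3, Polyak averaging, and up to 45 epochs with early-stopping patience
#' 12. These settings were chosen for datasets of a few tens of thousands of
#' records, where smaller batches and stronger regularization pay off; the
#' full-scale defaults of [surrogateConfig()] target the hundred-thousand-
#' record regime.
#'
#' @param architecture Architecture (default `"lstm"`).
#' @param seed Integer seed.
#' @param ... Overrides passed to [surrogateConfig()].
#' @return A `surrogateConfig`.
#' @export
toyProfile <- function(architecture = "lstm", seed = 1L, ...) {
    args <- list(architecture = architecture, numLayers = 1L,
                 hiddenDim = 128L, epochs = 45L, batchSize = 64L,
                 learningRate = 5e-3, patience = 12L, weightDecay = 1e-3,
                 emaDecay = 0.999, seed = seed)
    over <- list(...)
    args[names(over)] <- over
    do.call(surrogateConfig, args)
}
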