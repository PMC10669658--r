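#' Architecture hyperparameters for one network branch
#'
#' @param branch `"fnn"`, `"cnn"` or `"fusion"`.
#' @param input_dim gene count (fnn) or `(rows, cols)` image size (cnn).
#' @param feature_dim width `t` of the exported feature layer (default 32;
#'   must be below the input gene count for the fnn branch).
#' @param dropout_rate dropout probability on the regularised layers
#'   (default 0.4).
#' @param l1,l2 kernel penalty weights on the last two dense layers of each
#'   branch (defaults 1e-5 and 1e-4).
#' @param dense_widths fnn dense stack widths; the final entry is the
#'   feature layer (default `c(128, 64, 32, 32)`).
#' @param filters cnn filter counts for the six convolution layers
#'   (default `c(32, 32, 64, 64, 128, 128)`, in pairs between 2x2 max
#'   poolings; kernels are 3x3, stride 1, same padding).
#' @return A validated `NetworkSpec` list.
#' @export
networkSpec <- function(branch = c("fnn", "cnn", "fusion"), input_dim,
                        feature_dim = 32L, dropout_rate = 0.4,
                        l1 = 1e-5, l2 = 1e-4,
                        dense_widths = c(128L, 64L, 32L, 32L),
                        filters = c(32L, 32L, 64L, 64L, 128L, 128L)) {
    branch <- match.arg(branch)
    spec <- list(branch = branch, input_dim = as.integer(input_dim),
                 feature_dim = as.integer(feature_dim),
                 dropout_rate = dropout_rate, l1 = l1, l2 = l2,
                 dense_widths = as.integer(dense_widths),
                 filters = as.integer(filters))
    if (branch == "fnn") {
        if (length(spec$input_dim) != 1L)
            stop("configuration error: fnn input_dim must be a single gene count")
        if (spec$feature_dim != spec$dense_widths[length(spec$dense_widths)])
            stop("configuration error: feature_dim must equal the last dense width")
        if (spec$feature_dim >= spec$input_dim)
            warning("feature width t (", spec$feature_dim,
                    ") is not below the input gene count n (", spec$input_dim,
                    "); the feature layer does not compress")
    }
    if (branch == "cnn") {
        if (length(spec$input_dim) != 2L)
            stop("configuration error: cnn input_dim must be (rows, cols)")
        if (any(spec$input_dim < 8L))
            stop("configuration error: image must be at least 8 x 8 for three ",
                 "2x pooling stages (got ",
                 paste(spec$input_dim, collapse = " x "), ")")
        if (length(spec$filters) != 6L)
            stop("configuration error: exactly six convolution layers expected")
    }
    class(spec) <- "NetworkSpec"
    spec
}

#' Optimisation hyperparameters
#'
#' Defaults follow the training protocol the architectures were designed
#' for: Adam at learning rate `1e-4`, batch size 30, binary cross-entropy,
#' and an early-stop callback that ignores the first `warmup` epochs (250)
#' and halts after `patience` (10) consecutive epochs without a training
#' loss improvement, restoring the best-loss weights. `max_epochs` caps the
#' run since the stop rule alone need not terminate.
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param warmup epochs ignored by the early-stop monitor
#'   (`min_epochs_before_stop`).
#' @param patience consecutive non-improvements that stop training.
#' @param max_epochs hard epoch cap.
#' @param seed integer seed fixing initialisation order, shuffling and
#'   dropout.
#' @return A validated `TrainConfig` list.
#' @export
trainConfig <- function(learning_rate = 1e-4, batch_size = 30L,
                        warmup = 250L, patience = 10L,
                        max_epochs = 2000L, seed = 1L) {
    stopifnot(learning_rate > 0, batch_size >= 1, warmup >= 0,
              patience >= 1, max_epochs >= 1)
    structure(list(learning_rate = learning_rate,
                   batch_size = as.integer(batch_size),
                   warmup = as.integer(warmup),
                   patience = as.integer(patience),
                   max_epochs = as.integer(max_epochs),
                   seed = as.integer(seed)),
              class = "TrainConfig")
}

fnnLayers <- function(spec) {
    w <- spec$dense_widths
    dims <- c(spec$input_dim, w)
    nlay <- length(w)
    layers <- vector("list", nlay + 1L)
    for (i in seq_len(nlay)) {
        regged <- i > nlay - 2L                 # last two dense layers
        layers[[i]] <- nnDense(dims[i], dims[i + 1L], act = "relu",
                               reg = regged,
                               dropout = if (regged) spec$dropout_rate else 0)
    }
    layers[[nlay + 1L]] <- nnDense(w[nlay], 1L, act = "linear")
    layers
}

cnnLayers <- function(spec) {
    H <- spec$input_dim[1L]; W <- spec$input_dim[2L]
    f <- spec$filters
    chans <- c(1L, f)
    layers <- list()
    for (i in 1:6) {
        layers[[length(layers) + 1L]] <- nnConv(chans[i], chans[i + 1L])
        if (i %% 2L == 0L) {
            layers[[length(layers) + 1L]] <- nnPool()
            H <- H %/% 2L; W <- W %/% 2L
        }
    }
    layers[[length(layers) + 1L]] <- nnFlatten()
    flat <- H * W * f[6L]
    t <- spec$feature_dim
    layers[[length(layers) + 1L]] <-
        nnDense(flat, t, act = "relu", reg = TRUE, dropout = spec$dropout_rate)
    layers[[length(layers) + 1L]] <-
        nnDense(t, t, act = "relu", reg = TRUE, dropout = spec$dropout_rate)
    layers[[length(layers) + 1L]] <- nnDense(t, 1L, act = "linear")
    layers
}

#' Build the expression-vector feed-forward network
#'
#' Dense stack 128 - 64 - 32 - 32 with rectifier activations; the last two
#' dense layers carry L1+L2 kernel penalties and dropout; the final 32-unit
#' layer is the exported feature layer (`t = 32`); a linear head provides
#' the sigmoid output.
#'
#' @param spec a [networkSpec()] with `branch = "fnn"`.
#' @param seed integer seed fixing the weight initialisation.
#' @return An untrained [NeuralNet-class].
#' @export
buildFnn <- function(spec, seed = 1L) {
    if (spec$branch != "fnn") stop("configuration error: spec branch must be 'fnn'")
    set.seed(seed)
    new("NeuralNet", kind = "fnn",
        arch = list(layers = fnnLayers(spec), spec = spec, geom = c(1L, 1L)),
        params = list(), log = data.frame(), trained = FALSE)
}

#' Build the gene-image convolutional network
#'
#' Six 3x3 same-padding convolutions in pairs (32/32, 64/64, 128/128
#' filters), each pair followed by 2x2 max pooling, then two dense layers of
#' width `t` with L1+L2 penalties and dropout, and a linear head. Images
#' must be at least 8 x 8 so the three pooling stages remain well defined.
#'
#' @param spec a [networkSpec()] with `branch = "cnn"`.
#' @param seed integer seed fixing the weight initialisation.
#' @return An untrained [NeuralNet-class].
#' @export
buildCnn <- function(spec, seed = 1L) {
    if (spec$branch != "cnn") stop("configuration error: spec branch must be 'cnn'")
    set.seed(seed)
    new("NeuralNet", kind = "cnn",
        arch = list(layers = cnnLayers(spec), spec = spec,
                    geom = spec$input_dim),
        params = list(), log = data.frame(), trained = FALSE)
}

#' Build the late-fusion joint network
#'
#' The two branch feature vectors (each of width `t`) are concatenated into
#' a single `2t` vector and passed through dense(32) - dropout(0.4) -
#' dense(32) and a linear head. Both branches are trainable end-to-end from
#' random initialisation in a single joint optimisation.
#'
#' @param fnn_spec,cnn_spec branch [networkSpec()]s; feature dims must match.
#' @param seed integer seed fixing the weight initialisation.
#' @return An untrained [NeuralNet-class].
#' @export
buildFusion <- function(fnn_spec, cnn_spec, seed = 1L) {
    if (fnn_spec$feature_dim != cnn_spec$feature_dim)
        stop("configuration error: branch feature dims differ (",
             fnn_spec$feature_dim, " vs ", cnn_spec$feature_dim, ")")
    t <- fnn_spec$feature_dim
    set.seed(seed)
    fl <- fnnLayers(fnn_spec); fl <- fl[-length(fl)]   # drop branch heads
    cl <- cnnLayers(cnn_spec); cl <- cl[-length(cl)]
    head <- list(nnDense(2L * t, 32L, act = "relu",
                         dropout = fnn_spec$dropout_rate),
                 nnDense(32L, 32L, act = "relu"),
                 nnDense(32L, 1L, act = "linear"))
    new("NeuralNet", kind = "fusion",
        arch = list(fnn = fl, cnn = cl, head = head,
                    fnn_spec = fnn_spec, cnn_spec = cnn_spec,
                    geom = cnn_spec$input_dim),
        params = list(), log = data.frame(), trained = FALSE)
}

## images array (rows x cols x N) -> (N*H*W) x 1 matrix, sample-major,
## row-major pixels
imagesToMatrix <- function(pixels) {
    matrix(as.vector(aperm(pixels, c(2L, 1L, 3L))), ncol = 1L)
}

## slice rows of an image matrix for a sample subset
imageRows <- function(idx, HW) {
    as.vector(outer(seq_len(HW), (idx - 1L) * HW, `+`))
}

nnPrepareInputs <- function(model, x) {
    kind <- model@kind
    if (kind == "fnn") {
        list(x = as.matrix(x), n = nrow(as.matrix(x)))
    } else if (kind == "cnn") {
        px <- if (is(x, "GeneImageSet")) x@pixels else x
        list(img = imagesToMatrix(px), n = dim(px)[3L],
             HW = prod(dim(px)[1:2]))
    } else {
        px <- if (is(x$images, "GeneImageSet")) x$images@pixels else x$images
        list(x = as.matrix(x$x), img = imagesToMatrix(px),
             n = dim(px)[3L], HW = prod(dim(px)[1:2]))
    }
}

nnForwardModel <- function(model, inp, idx, training = FALSE) {
    kind <- model@kind
    if (kind == "fnn") {
        fw <- nnForward(model@arch$layers, inp$x[idx, , drop = FALSE],
                        c(1L, 1L), training)
        list(logits = fw$out[, 1L], fw = fw)
    } else if (kind == "cnn") {
        fw <- nnForward(model@arch$layers,
                        inp$img[imageRows(idx, inp$HW), , drop = FALSE],
                        model@arch$geom, training)
        list(logits = fw$out[, 1L], fw = fw)
    } else {
        ffw <- nnForward(model@arch$fnn, inp$x[idx, , drop = FALSE],
                         c(1L, 1L), training)
        cfw <- nnForward(model@arch$cnn,
                         inp$img[imageRows(idx, inp$HW), , drop = FALSE],
                         model@arch$geom, training)
        hfw <- nnForward(model@arch$head, cbind(ffw$out, cfw$out),
                         c(1L, 1L), training)
        list(logits = hfw$out[, 1L], ffw = ffw, cfw = cfw, hfw = hfw)
    }
}

## one gradient step; returns updated model pieces + batch loss
nnBatchStep <- function(model, inp, idx, y, opt, lr, step) {
    nb <- length(idx)
    fwd <- nnForwardModel(model, inp, idx, training = TRUE)
    z <- fwd$logits
    p <- nnSigmoid(z)
    dz <- matrix((p - y) / nb, ncol = 1L)
    dataLoss <- nnBceFromLogits(z, y)
    pen <- 0
    if (model@kind == "fusion") {
        t <- model@arch$fnn_spec$feature_dim
        bh <- nnBackward(model@arch$head, fwd$hfw$caches, dz, c(1L, 1L))
        dZ <- bh$dIn
        bf <- nnBackward(model@arch$fnn, fwd$ffw$caches,
                         dZ[, seq_len(t), drop = FALSE], c(1L, 1L))
        bc <- nnBackward(model@arch$cnn, fwd$cfw$caches,
                         dZ[, t + seq_len(t), drop = FALSE], model@arch$geom)
        rf <- nnApplyReg(model@arch$fnn, bf$grads,
                         model@arch$fnn_spec$l1, model@arch$fnn_spec$l2)
        rc <- nnApplyReg(model@arch$cnn, bc$grads,
                         model@arch$cnn_spec$l1, model@arch$cnn_spec$l2)
        pen <- rf$penalty + rc$penalty
        uh <- nnAdamStep(model@arch$head, bh$grads, opt$head, lr, step)
        uf <- nnAdamStep(model@arch$fnn, rf$grads, opt$fnn, lr, step)
        uc <- nnAdamStep(model@arch$cnn, rc$grads, opt$cnn, lr, step)
        model@arch$head <- uh$layers; opt$head <- uh$state
        model@arch$fnn <- uf$layers; opt$fnn <- uf$state
        model@arch$cnn <- uc$layers; opt$cnn <- uc$state
    } else {
        geom <- if (model@kind == "cnn") model@arch$geom else c(1L, 1L)
        bk <- nnBackward(model@arch$layers, fwd$fw$caches, dz, geom)
        rg <- nnApplyReg(model@arch$layers, bk$grads,
                         model@arch$spec$l1, model@arch$spec$l2)
        pen <- rg$penalty
        up <- nnAdamStep(model@arch$layers, rg$grads, opt$layers, lr, step)
        model@arch$layers <- up$layers; opt$layers <- up$state
    }
    nCorrect <- sum((p >= 0.5) == (y == 1L))
    list(model = model, opt = opt, loss = dataLoss + pen, correct = nCorrect)
}

modelLayerSets <- function(model) {
    if (model@kind == "fusion") c("fnn", "cnn", "head") else "layers"
}

#' Train a network with Adam, binary cross-entropy and early stopping
#'
#' Runs minibatch gradient descent with the adaptive-moment optimizer at the
#' configured rate. The monitored quantity is the epoch-mean training loss
#' including the regularisation penalty; the early-stop rule of
#' [earlyStopEpochs()] is applied online and the best-loss weights are
#' restored on return. A fixed seed fixes initialisation (set at build
#' time), shuffling and dropout, making runs exactly repeatable.
#'
#' @param model an untrained (or previously trained) [NeuralNet-class].
#' @param x inputs: a samples x genes matrix (fnn), a [GeneImageSet-class]
#'   or rows x cols x samples array (cnn), or `list(x = , images = )`
#'   (fusion).
#' @param y binary 0/1 response, one per sample.
#' @param config a [trainConfig()].
#' @return The trained model with its per-epoch `log` (epoch, loss,
#'   accuracy).
#' @export
trainNetwork <- function(model, x, y, config = trainConfig()) {
    y <- as.numeric(y)
    if (length(unique(y)) < 2L)
        stop("training data contain a single class")
    inp <- nnPrepareInputs(model, x)
    if (inp$n != length(y)) stop("one label per sample required")
    set.seed(config$seed)
    opt <- lapply(stats::setNames(nm = modelLayerSets(model)), function(s)
        nnAdamInit(if (model@kind == "fusion") model@arch[[s]] else model@arch$layers))
    best <- Inf; bestModel <- NULL; bad <- 0L; step <- 0L
    logs <- vector("list", config$max_epochs)
    nEpochs <- 0L
    for (e in seq_len(config$max_epochs)) {
        ord <- sample.int(inp$n)
        lossSum <- 0; correct <- 0
        for (b in seq_len(ceiling(inp$n / config$batch_size))) {
            idx <- ord[((b - 1L) * config$batch_size + 1L):
                       min(b * config$batch_size, inp$n)]
            step <- step + 1L
            st <- nnBatchStep(model, inp, idx, y[idx], opt,
                              config$learning_rate, step)
            model <- st$model; opt <- st$opt
            lossSum <- lossSum + st$loss * length(idx)
            correct <- correct + st$correct
        }
        epochLoss <- lossSum / inp$n
        logs[[e]] <- data.frame(epoch = e, loss = epochLoss,
                                accuracy = correct / inp$n)
        nEpochs <- e
        if (e > config$warmup) {
            if (epochLoss < best) {
                best <- epochLoss; bestModel <- model; bad <- 0L
            } else {
                bad <- bad + 1L
                if (bad >= config$patience) break
            }
        }
    }
    if (!is.null(bestModel)) model <- bestModel
    model@log <- do.call(rbind, logs[seq_len(nEpochs)])
    model@trained <- TRUE
    model
}

#' Predict class probabilities from a trained network
#'
#' @param object a [NeuralNet-class].
#' @param newdata inputs in the same form [trainNetwork()] accepts.
#' @param ... unused.
#' @return Numeric vector of probabilities in `(0, 1)`.
#' @export
setMethod("predict", "NeuralNet", function(object, newdata, ...) {
    inp <- nnPrepareInputs(object, newdata)
    fwd <- nnForwardModel(object, inp, seq_len(inp$n), training = FALSE)
    nnSigmoid(fwd$logits)
})

#' Save / load a trained network
#'
#' Models are stored via R's native serialisation; the training log is also
#' written alongside as CSV (`<path>.log.csv`).
#'
#' @param model a [NeuralNet-class].
#' @param path output path (conventionally `.rds`).
#' @return Invisibly, `path`; `readModel()` returns the model.
#' @export
writeModel <- function(model, path) {
    saveRDS(model, path)
    if (nrow(model@log))
        utils::write.csv(model@log, paste0(path, ".log.csv"), row.names = FALSE)
    invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) readRDS(path)
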