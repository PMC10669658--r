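## Internal neural-network engine.
##
## A compact, fully deterministic CPU implementation of the layers the
## package's three architectures need: dense, 3x3 same-padding convolution,
## 2x2 max pooling (floor on odd dims), flatten, inverted dropout, ReLU,
## sigmoid + binary cross-entropy, L1+L2 kernel penalties and the Adam
## optimizer. Tensors with spatial structure are carried as (N*H*W) x C
## matrices (sample-major, row-major pixels, channels in columns) so every
## hot operation is a BLAS matrix product or a vectorised gather.
##
## Conventions follow the common deep-learning defaults: Glorot-uniform
## initialisation, Adam eps 1e-7, dropout scaling at train time, and a
## monitored loss that includes the regularisation penalty.

nnGlorot <- function(fan_in, fan_out, n) {
    lim <- sqrt(6 / (fan_in + fan_out))
    stats::runif(n, -lim, lim)
}

nnDense <- function(in_dim, units, act = "relu", reg = FALSE, dropout = 0) {
    list(type = "dense",
         W = matrix(nnGlorot(in_dim, units, in_dim * units), in_dim, units),
         b = numeric(units), act = act, reg = reg, dropout = dropout)
}

nnConv <- function(in_ch, filters) {
    ## 3x3 kernel stored as in_ch x filters x 9 offset slices, (dr, dc)
    ## row-major over {-1,0,1}^2, matching the compiled kernels
    W <- array(nnGlorot(9 * in_ch, filters, in_ch * filters * 9),
               dim = c(in_ch, filters, 9L))
    list(type = "conv", W = W, b = numeric(filters), act = "relu")
}

nnPool <- function() list(type = "pool")
nnFlatten <- function() list(type = "flatten")

nnForward <- function(layers, X, geom, training = FALSE) {
    caches <- vector("list", length(layers))
    H <- geom[1L]; W <- geom[2L]
    for (li in seq_along(layers)) {
        lay <- layers[[li]]
        cache <- list()
        if (lay$type == "conv") {
            N <- nrow(X) / (H * W)
            Y <- nn_conv_fwd_cpp(X, lay$W, lay$b, N, H, W, TRUE)
            cache <- list(Xin = X, Y = Y)
            X <- Y
        } else if (lay$type == "pool") {
            N <- nrow(X) / (H * W)
            res <- nn_pool_fwd_cpp(X, N, H, W)
            cache <- list(arg = res$arg, N = N)
            X <- res$Y
            H <- H %/% 2L; W <- W %/% 2L
        } else if (lay$type == "flatten") {
            P <- H * W; C <- ncol(X); N <- nrow(X) / P
            A <- array(X, dim = c(P, N, C))
            X <- t(matrix(aperm(A, c(1L, 3L, 2L)), P * C, N))
            cache <- list(P = P, C = C, N = N)
        } else if (lay$type == "dense") {
            Xin <- X
            Y <- X %*% lay$W
            Y <- Y + rep(lay$b, each = nrow(Y))
            if (lay$act == "relu") {
                mask <- Y > 0
                Y <- Y * mask
            } else mask <- NULL
            dmask <- NULL
            if (training && lay$dropout > 0) {
                keep <- 1 - lay$dropout
                dmask <- matrix((stats::runif(length(Y)) < keep) / keep,
                                nrow(Y))
                Y <- Y * dmask
            }
            cache <- list(Xin = Xin, mask = mask, dmask = dmask)
            X <- Y
        }
        caches[[li]] <- cache
    }
    list(out = X, caches = caches, geom = c(H, W))
}

## backpropagate dOut through the layer stack; returns gradients per layer
## and the gradient w.r.t. the stack input
nnBackward <- function(layers, caches, dOut, geomIn) {
    grads <- vector("list", length(layers))
    ## replay geometry per layer
    geoms <- vector("list", length(layers))
    H <- geomIn[1L]; W <- geomIn[2L]
    for (li in seq_along(layers)) {
        geoms[[li]] <- c(H, W)
        if (layers[[li]]$type == "pool") { H <- H %/% 2L; W <- W %/% 2L }
    }
    dX <- dOut
    for (li in rev(seq_along(layers))) {
        lay <- layers[[li]]; cache <- caches[[li]]
        if (lay$type == "dense") {
            if (!is.null(cache$dmask)) dX <- dX * cache$dmask
            if (!is.null(cache$mask)) dX <- dX * cache$mask
            gW <- crossprod(cache$Xin, dX)
            gb <- colSums(dX)
            grads[[li]] <- list(W = gW, b = gb)
            dX <- dX %*% t(lay$W)
        } else if (lay$type == "flatten") {
            P <- cache$P; C <- cache$C; N <- cache$N
            A <- array(t(dX), dim = c(P, C, N))
            dX <- matrix(aperm(A, c(1L, 3L, 2L)), P * N, C)
        } else if (lay$type == "pool") {
            g <- geoms[[li]]
            dX <- nn_pool_bwd_cpp(dX, cache$arg, cache$N, g[1L], g[2L])
        } else if (lay$type == "conv") {
            g <- geoms[[li]]
            N <- nrow(cache$Xin) / (g[1L] * g[2L])
            res <- nn_conv_bwd_cpp(cache$Xin, cache$Y, lay$W, dX,
                                   N, g[1L], g[2L])
            grads[[li]] <- list(W = res$dW, b = as.vector(res$db))
            dX <- res$dX
        }
    }
    list(grads = grads, dIn = dX)
}

## add L1+L2 penalty gradients in place; returns penalty value
nnApplyReg <- function(layers, grads, l1, l2) {
    pen <- 0
    for (li in seq_along(layers)) {
        lay <- layers[[li]]
        if (identical(lay$type, "dense") && isTRUE(lay$reg)) {
            pen <- pen + l1 * sum(abs(lay$W)) + l2 * sum(lay$W^2)
            grads[[li]]$W <- grads[[li]]$W + l1 * sign(lay$W) + 2 * l2 * lay$W
        }
    }
    list(grads = grads, penalty = pen)
}

## ---- Adam ----------------------------------------------------------------

nnAdamInit <- function(layers) {
    lapply(layers, function(lay) {
        if (lay$type %in% c("dense", "conv"))
            list(mW = lay$W * 0, vW = lay$W * 0,
                 mb = lay$b * 0, vb = lay$b * 0)
        else NULL
    })
}

nnAdamStep <- function(layers, grads, state, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
    corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
    upd <- function(theta, g, m, v) {
        m <- beta1 * m + (1 - beta1) * g
        v <- beta2 * v + (1 - beta2) * g^2
        theta <- theta - lr * (m / corr1) / (sqrt(v / corr2) + eps)
        list(theta = theta, m = m, v = v)
    }
    for (li in seq_along(layers)) {
        g <- grads[[li]]
        if (is.null(g)) next
        lay <- layers[[li]]; st <- state[[li]]
        u <- upd(lay$W, g$W, st$mW, st$vW)
        lay$W <- u$theta; st$mW <- u$m; st$vW <- u$v
        u <- upd(lay$b, g$b, st$mb, st$vb)
        lay$b <- u$theta; st$mb <- u$m; st$vb <- u$v
        layers[[li]] <- lay; state[[li]] <- st
    }
    list(layers = layers, state = state)
}

nnSigmoid <- function(z) 1 / (1 + exp(-z))

## numerically safe binary cross-entropy from logits
nnBceFromLogits <- function(z, y) {
    ## log(1+exp(z)) - y*z, stabilised
    mean(pmax(z, 0) - y * z + log1p(exp(-abs(z))))
}

nnCountLayerParams <- function(layers) {
    sum(vapply(layers, function(lay) {
        if (lay$type %in% c("dense", "conv")) length(lay$W) + length(lay$b)
        else 0
    }, numeric(1)))
}

#' Number of trainable parameters in a network
#'
#' @param model a [NeuralNet-class].
#' @return Integer parameter count.
#' @export
nnCountParams <- function(model) {
    if (model@kind == "fusion")
        nnCountLayerParams(model@arch$fnn) + nnCountLayerParams(model@arch$cnn) +
            nnCountLayerParams(model@arch$head)
    else nnCountLayerParams(model@arch$layers)
}

#' Early-stopping epoch under the warm-up/patience rule
#'
#' The monitored loss is ignored for the first `warmup` epochs; afterwards
#' the best (strictly smallest) loss is tracked and training stops once
#' `patience` consecutive epochs fail to improve on it. Pure over its input,
#' so the rule is unit-testable without any training.
#'
#' @param losses numeric per-epoch loss sequence.
#' @param warmup number of initial epochs to ignore (default 250).
#' @param patience consecutive non-improvements that trigger the stop
#'   (default 10).
#' @return List with `stop_epoch` (NA if never triggered within the
#'   sequence) and `best_epoch` (NA while monitoring has not started).
#' @examples
#' l <- c(seq(1, 0.5, length.out = 260), rep(0.5, 40))
#' earlyStopEpochs(l, warmup = 250, patience = 10)  # stop 270, best 260
#' @export
earlyStopEpochs <- function(losses, warmup = 250L, patience = 10L) {
    if (patience < 1L) stop("patience must be >= 1")
    best <- Inf; best_e <- NA_integer_; bad <- 0L
    for (e in seq_along(losses)) {
        if (e <= warmup) next
        if (losses[e] < best) {
            best <- losses[e]; best_e <- e; bad <- 0L
        } else {
            bad <- bad + 1L
            if (bad >= patience)
                return(list(stop_epoch = e, best_epoch = best_e))
        }
    }
    list(stop_epoch = NA_integer_, best_epoch = best_e)
}
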