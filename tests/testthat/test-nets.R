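test_that("network specs enforce their geometry constraints", {
    expect_error(networkSpec("fnn", input_dim = c(4, 4)), "single gene count")
    expect_warning(networkSpec("fnn", input_dim = 10), "does not compress")
    expect_error(networkSpec("fnn", input_dim = 400, feature_dim = 16),
                 "last dense width")
    expect_error(networkSpec("cnn", input_dim = 50), "rows, cols")
    ## three 2x poolings need at least 8 pixels per side
    expect_error(networkSpec("cnn", input_dim = c(7, 7)), "8 x 8")
    expect_error(buildFusion(networkSpec("fnn", input_dim = 400),
                             networkSpec("cnn", input_dim = c(12, 12),
                                         feature_dim = 16,
                                         dense_widths = c(128, 64, 16, 16))),
                 "feature dims differ")
})

test_that("the fnn honours its shape contract and emits finite probabilities", {
    spec <- networkSpec("fnn", input_dim = 400)
    net <- buildFnn(spec, seed = 1)
    expect_equal(net@kind, "fnn")
    ## last hidden layer is the 32-wide feature layer; head maps 32 -> 1
    nl <- length(net@arch$layers)
    expect_equal(ncol(net@arch$layers[[nl - 1]]$W), 32L)
    expect_equal(dim(net@arch$layers[[nl]]$W), c(32L, 1L))
    p <- predict(net, matrix(0, 3, 400))
    expect_length(p, 3)
    expect_true(all(is.finite(p) & p > 0 & p < 1))
})

test_that("the cnn emits a feature vector of width t from a 50x50 image", {
    spec <- networkSpec("cnn", input_dim = c(50, 50))
    net <- buildCnn(spec, seed = 1)
    nl <- length(net@arch$layers)
    expect_equal(ncol(net@arch$layers[[nl - 1]]$W), 32L)
    imgs <- array(stats::runif(50 * 50 * 2), c(50, 50, 2))
    p <- predict(net, imgs)
    expect_length(p, 2)
    expect_true(all(is.finite(p) & p > 0 & p < 1))
})

test_that("fusion concatenates two t-vectors into a 2t head input", {
    fspec <- networkSpec("fnn", input_dim = 200)
    cspec <- networkSpec("cnn", input_dim = c(12, 12))
    fus <- buildFusion(fspec, cspec, seed = 1)
    expect_equal(nrow(fus@arch$head[[1]]$W), 64L)   # 2t with t = 32
    x <- matrix(rnorm(5 * 200), 5, 200)
    imgs <- array(stats::runif(12 * 12 * 5), c(12, 12, 5))
    p <- predict(fus, list(x = x, images = imgs))
    expect_length(p, 5)
    expect_true(all(p > 0 & p < 1))
})

test_that("the early-stop callback reproduces the warm-up/patience rule", {
    ## plateau at 260: stop at 270, best at 260 (warm-up 250, patience 10)
    l <- c(seq(2, 1, length.out = 260), rep(1, 40))
    out <- earlyStopEpochs(l, warmup = 250, patience = 10)
    expect_equal(out$stop_epoch, 270)
    expect_equal(out$best_epoch, 260)

    ## scaled constants: plateau at 26 with warm-up 20, patience 5
    l2 <- c(seq(2, 1, length.out = 26), rep(1, 20))
    out2 <- earlyStopEpochs(l2, warmup = 20, patience = 5)
    expect_equal(out2$stop_epoch, 31)
    expect_equal(out2$best_epoch, 26)

    ## strictly decreasing loss never triggers the stop
    out3 <- earlyStopEpochs(seq(1, 0.1, length.out = 50), warmup = 0,
                            patience = 10)
    expect_true(is.na(out3$stop_epoch))

    ## non-improvement during warm-up is ignored
    l4 <- c(rep(5, 20), seq(1, 0.5, length.out = 10), rep(0.5, 5))
    out4 <- earlyStopEpochs(l4, warmup = 20, patience = 5)
    expect_equal(out4$stop_epoch, 35)
    expect_equal(out4$best_epoch, 30)
})

test_that("training on linearly separable expression data fits quickly", {
    set.seed(7)
    n <- 200
    x <- matrix(rnorm(n * 2), n, 2)
    y <- as.integer(x[, 1] + x[, 2] > 0)
    suppressWarnings(spec <- networkSpec("fnn", input_dim = 2))
    net <- buildFnn(spec, seed = 1)
    net <- trainNetwork(net, x, y, trainConfig(learning_rate = 1e-3,
                                               warmup = 0, patience = 200,
                                               max_epochs = 200, seed = 1))
    expect_gte(utils::tail(net@log$accuracy, 1), 0.95)
})

test_that("the cnn learns a bright-patch class from images", {
    set.seed(9)
    n <- 120
    px <- array(stats::runif(10 * 10 * n, 0, 0.4), c(10, 10, n))
    y <- rep(0:1, length.out = n)
    px[4:6, 4:6, y == 1] <- px[4:6, 4:6, y == 1] + 0.6
    spec <- networkSpec("cnn", input_dim = c(10, 10))
    net <- buildCnn(spec, seed = 2)
    net <- trainNetwork(net, px, y, trainConfig(learning_rate = 1e-3,
                                                warmup = 0, patience = 60,
                                                max_epochs = 60, seed = 2))
    expect_gte(utils::tail(net@log$accuracy, 1), 0.95)
})

test_that("fusion trains through the fnn branch even with blank images", {
    set.seed(10)
    n <- 150
    x <- matrix(rnorm(n * 20), n, 20)
    y <- as.integer(x[, 1] > 0)
    blank <- array(0, c(10, 10, n))
    fspec <- networkSpec("fnn", input_dim = 20)
    cspec <- networkSpec("cnn", input_dim = c(10, 10))
    fus <- buildFusion(fspec, cspec, seed = 3)
    fus <- trainNetwork(fus, list(x = x, images = blank), y,
                        trainConfig(learning_rate = 1e-3, warmup = 0,
                                    patience = 80, max_epochs = 80, seed = 3))
    expect_gte(utils::tail(fus@log$accuracy, 1), 0.9)
})

test_that("loss decreases within the first epochs on separable data", {
    set.seed(11)
    x <- matrix(rnorm(60 * 5), 60, 5)
    y <- as.integer(x[, 1] > 0)
    spec <- networkSpec("fnn", input_dim = 5)
    net <- trainNetwork(buildFnn(spec, seed = 4), x, y, fastTrain(epochs = 5))
    expect_lt(net@log$loss[5], net@log$loss[1])
})

test_that("identical seeds give identical loss logs; single-class data fail", {
    set.seed(12)
    x <- matrix(rnorm(40 * 6), 40, 6)
    y <- rep(0:1, 20)
    spec <- networkSpec("fnn", input_dim = 6)
    a <- trainNetwork(buildFnn(spec, seed = 5), x, y, fastTrain(epochs = 4))
    b <- trainNetwork(buildFnn(spec, seed = 5), x, y, fastTrain(epochs = 4))
    expect_identical(a@log, b@log)
    expect_error(trainNetwork(buildFnn(spec, seed = 5), x, rep(1, 40),
                              fastTrain()), "single class")
})

test_that("parameter counts are reported for every architecture", {
    suppressWarnings({
        f <- buildFnn(networkSpec("fnn", input_dim = 100))
        c0 <- buildCnn(networkSpec("cnn", input_dim = c(12, 12)))
        fu <- buildFusion(networkSpec("fnn", input_dim = 100),
                          networkSpec("cnn", input_dim = c(12, 12)))
    })
    expect_gt(nnCountParams(f), 0)
    ## conv stack alone contributes 286,432 parameters
    expect_gt(nnCountParams(c0), 286432)
    ## fusion = both branches minus their heads plus the joint head
    expect_equal(nnCountParams(fu),
                 nnCountParams(f) + nnCountParams(c0) - 2 * 33 +
                     (64 * 32 + 32) + (32 * 32 + 32) + (32 + 1))
})
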