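#' Stratified fold assignment
#'
#' Samples are partitioned into `k` disjoint folds preserving class
#' proportions: within each class the (seed-shuffled) samples are dealt
#' round-robin over the folds, visiting folds in order of their current
#' size so the overall fold sizes also differ by at most one.
#'
#' @param labels binary (or categorical) label per sample.
#' @param k number of folds (default 5); every class must have at least `k`
#'   members.
#' @param seed integer seed; the assignment is deterministic under it.
#' @return Integer fold id in `1..k` per sample.
#' @export
makeFolds <- function(labels, k = 5L, seed = 1L) {
    k <- as.integer(k)
    tab <- table(labels)
    if (any(tab < k))
        stop("class '", names(tab)[which.min(tab)], "' has fewer than k = ",
             k, " samples")
    set.seed(seed)
    folds <- integer(length(labels))
    sizes <- integer(k)
    for (cl in names(tab)) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        ord <- order(sizes, seq_len(k))         # smallest folds first
        assign <- rep(ord, length.out = length(idx))
        folds[idx] <- assign
        sizes <- sizes + tabulate(assign, k)
    }
    folds
}

#' Area under the ROC curve via the rank statistic
#'
#' Computes AUC as the normalised Mann-Whitney U statistic with midranks,
#' i.e. the probability a random positive is scored above a random negative
#' (ties counted half).
#'
#' @param scores numeric classifier scores.
#' @param y binary 0/1 truth.
#' @return AUC in `[0, 1]`.
#' @export
aucRank <- function(scores, y) {
    y <- as.integer(y)
    n1 <- sum(y == 1L); n0 <- sum(y == 0L)
    if (n1 == 0L || n0 == 0L) stop("both classes required for AUC")
    r <- rank(scores, ties.method = "average")
    (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve by threshold sweep
#'
#' Sweeps every distinct score (plus sentinels) as a decision threshold
#' (predict positive when `score >= threshold`) and reports the false- and
#' true-positive rates.
#'
#' @inheritParams aucRank
#' @return data.frame with columns `threshold`, `fpr`, `tpr`, ordered from
#'   (0, 0) to (1, 1).
#' @export
rocCurve <- function(scores, y) {
    y <- as.integer(y)
    thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
    n1 <- sum(y == 1L); n0 <- sum(y == 0L)
    tpr <- vapply(thr, function(t) sum(scores >= t & y == 1L) / n1, numeric(1))
    fpr <- vapply(thr, function(t) sum(scores >= t & y == 0L) / n0, numeric(1))
    data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

## trapezoidal area under a rocCurve() data.frame
rocAuc <- function(roc) {
    sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Thresholded and threshold-free binary classification metrics
#'
#' Accuracy, precision, recall and F1 are computed at decision threshold
#' 0.5 for the positive class; zero-division cases (no predicted or no true
#' positives) are defined as 0 with a warning. AUC uses the rank statistic
#' of [aucRank()].
#'
#' @param scores predicted probabilities.
#' @param y binary 0/1 truth.
#' @return Named numeric vector: accuracy, auc, precision, recall, f1.
#' @export
binaryMetrics <- function(scores, y) {
    y <- as.integer(y)
    pred <- as.integer(scores >= 0.5)
    tp <- sum(pred == 1L & y == 1L)
    fp <- sum(pred == 1L & y == 0L)
    fn <- sum(pred == 0L & y == 1L)
    acc <- mean(pred == y)
    if (tp + fp == 0L) {
        warning("no predicted positives; precision defined as 0")
        prec <- 0
    } else prec <- tp / (tp + fp)
    if (tp + fn == 0L) {
        warning("no true positives; recall defined as 0")
        rec <- 0
    } else rec <- tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(accuracy = acc, auc = aucRank(scores, y), precision = prec,
      recall = rec, f1 = f1)
}

## derive a per-(fold, model) child seed; kept well below 2^31
childSeed <- function(seed, fold, salt) {
    as.integer((as.numeric(seed) * 1009 + fold * 131 + salt * 7919) %% 2147483L + 1L)
}

#' Stratified k-fold cross-validation of the three models
#'
#' For every fold the entire upstream pipeline — LASSO gene selection,
#' Fisher scoring, categorisation and the LDA gene map — is fitted on the
#' training folds only; held-out samples are transformed through the frozen
#' artifacts and scored by the feed-forward, convolutional and fusion
#' models. Each model's training sample set is recorded and checked to be
#' disjoint from the test fold.
#'
#' @param cohort a merged [ExpressionCohort-class] (full label set).
#' @param task a [PairTask-class] or task name.
#' @param models subset of `c("fnn_only", "cnn_only", "fusion")`.
#' @param folds number of folds (default 5).
#' @param seed integer master seed for fold assignment and training.
#' @param lambda LASSO penalty (default 1e-6).
#' @param K Fisher categories (default 15).
#' @param resolution image size `(rows, cols)` (default 50 x 50).
#' @param feature_dim branch feature width `t` (default 32).
#' @param train_config a [trainConfig()]; its seed is re-derived per fold
#'   and model.
#' @return Named list of [FoldReport-class] objects, one per model.
#' @export
runCV <- function(cohort, task, models = c("fnn_only", "cnn_only", "fusion"),
                  folds = 5L, seed = 1L, lambda = 1e-6, K = 15L,
                  resolution = c(50L, 50L), feature_dim = 32L,
                  train_config = trainConfig()) {
    models <- match.arg(models, several.ok = TRUE)
    if (is.character(task)) task <- pairTask(task)
    sub <- makePairSubset(cohort, task)
    y <- response(sub)
    fold <- makeFolds(y, k = folds, seed = seed)
    names(fold) <- colnames(sub)

    perFold <- vector("list", folds)
    fittedOn <- vector("list", folds)
    for (f in seq_len(folds)) {
        testIdx <- which(fold == f)
        trainIdx <- which(fold != f)
        trainCo <- sub[, trainIdx]
        testCo <- sub[, testIdx]
        if (length(unique(response(testCo))) < 2L)
            stop("fold ", f, " has a single class in its test set")

        sel <- lassoSelect(trainCo, lambda = lambda)
        trainSel <- trainCo[sel@selected, ]
        testSel <- testCo[sel@selected, ]
        map <- fitGeneMap(trainSel, K = K, resolution = resolution)
        stopifnot(!any(fittedOn(map) %in% colnames(testCo)))  # leakage guard
        fittedOn[[f]] <- fittedOn(map)
        imgTrain <- renderImages(trainSel, map)
        imgTest <- renderImages(testSel, map)
        xTrain <- t(exprs(trainSel)); xTest <- t(exprs(testSel))
        yTrain <- response(trainCo); yTest <- response(testCo)

        fspec <- networkSpec("fnn", input_dim = ncol(xTrain),
                             feature_dim = feature_dim)
        cspec <- networkSpec("cnn", input_dim = resolution,
                             feature_dim = feature_dim)
        out <- list()
        for (m in models) {
            cfg <- train_config
            cfg$seed <- childSeed(seed, f, match(m, c("fnn_only", "cnn_only",
                                                      "fusion")))
            if (m == "fnn_only") {
                net <- buildFnn(fspec, seed = cfg$seed)
                net <- trainNetwork(net, xTrain, yTrain, cfg)
                scores <- predict(net, xTest)
            } else if (m == "cnn_only") {
                net <- buildCnn(cspec, seed = cfg$seed)
                net <- trainNetwork(net, imgTrain, yTrain, cfg)
                scores <- predict(net, imgTest)
            } else {
                net <- buildFusion(fspec, cspec, seed = cfg$seed)
                net <- trainNetwork(net, list(x = xTrain, images = imgTrain),
                                    yTrain, cfg)
                scores <- predict(net, list(x = xTest, images = imgTest))
            }
            roc <- rocCurve(scores, yTest)
            out[[m]] <- list(metrics = binaryMetrics(scores, yTest),
                             roc = cbind(fold = f, roc))
        }
        perFold[[f]] <- out
    }

    reports <- lapply(models, function(m) {
        mets <- do.call(rbind, lapply(perFold, function(pf) pf[[m]]$metrics))
        mets <- data.frame(fold = seq_len(folds), mets)
        roc <- do.call(rbind, lapply(perFold, function(pf) pf[[m]]$roc))
        new("FoldReport", model = m, task = task@name,
            metrics = mets,
            means = colMeans(mets[, -1L, drop = FALSE]),
            roc = roc, folds = fold, fittedOn = fittedOn,
            seed = as.integer(seed))
    })
    names(reports) <- models
    reports
}

#' Serialize fold reports
#'
#' Writes the full report set as one JSON document plus a flat CSV
#' (`model, fold, metric, value`) and a ROC-point CSV for plotting. The
#' JSON contains no timestamps, so identical runs produce byte-identical
#' files.
#'
#' @param reports named list of [FoldReport-class] objects (as returned by
#'   [runCV()]).
#' @param path output JSON path; CSVs are written next to it.
#' @return Invisibly, `path`.
#' @export
writeFoldReport <- function(reports, path) {
    obj <- lapply(reports, function(r)
        list(model = r@model, task = r@task, seed = r@seed,
             folds = as.list(r@folds),
             per_fold = r@metrics, means = as.list(r@means)))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    flat <- do.call(rbind, lapply(reports, function(r) {
        long <- utils::stack(r@metrics[, -1L])
        data.frame(model = r@model, fold = rep(r@metrics$fold, ncol(r@metrics) - 1L),
                   metric = long$ind, value = long$values)
    }))
    utils::write.csv(flat, sub("\\.json$", ".csv", path), row.names = FALSE)
    rocs <- do.call(rbind, lapply(reports, function(r)
        cbind(model = r@model, r@roc)))
    utils::write.csv(rocs, sub("\\.json$", "_roc.csv", path), row.names = FALSE)
    invisible(path)
}
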