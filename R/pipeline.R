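#' Pipeline configuration
#'
#' A nested key-value document with one level of stage namespacing, carrying
#' every tunable of the pipeline with its standard default: LASSO `lambda`
#' 1e-6, 15 Fisher categories, 50 x 50 images, feature width 32, Adam at
#' 1e-4 with batch 30, early stopping after 250 warm-up epochs with
#' patience 10, five folds. `pipelineConfig()` builds the defaults,
#' [readPipelineConfig()] loads a YAML file over them, and `overrides`
#' (flat names such as `seed`, `task`, `lambda`, `categories`,
#' `resolution`, `feature_dim`, `folds`, `outdir`) take final precedence
#' without touching the file on disk.
#'
#' @param ... named overrides of the flat keys above, plus nested lists
#'   (`simulate`, `inputs`, `train`) replacing whole sections.
#' @return A validated `PipelineConfig` list.
#' @export
pipelineConfig <- function(...) {
    cfg <- list(
        seed = 1L,
        outdir = "one2m_out",
        task = "AD_vs_NC",
        simulate = list(n_datasets = 3L, samples_per_class = 50L,
                        n_genes = 1000L, n_informative = 60L,
                        effect_size = 1.0, noise_sd = 1.0,
                        batch_scale = c(0.75, 1.25),
                        batch_offset = c(-0.5, 0.5),
                        classes = c("AD", "NC")),
        inputs = list(expression = NULL, labels = NULL, format = "tsv"),
        select = list(lambda = 1e-6),
        map = list(categories = 15L, resolution = c(50L, 50L)),
        train = list(learning_rate = 1e-4, batch_size = 30L, warmup = 250L,
                     patience = 10L, max_epochs = 2000L, feature_dim = 32L),
        evaluate = list(folds = 5L))
    applyOverrides(cfg, list(...))
}

flatKeyMap <- list(seed = c("seed"), outdir = c("outdir"), task = c("task"),
                   lambda = c("select", "lambda"),
                   categories = c("map", "categories"),
                   resolution = c("map", "resolution"),
                   feature_dim = c("train", "feature_dim"),
                   folds = c("evaluate", "folds"))

applyOverrides <- function(cfg, overrides) {
    for (nm in names(overrides)) {
        val <- overrides[[nm]]
        if (nm %in% names(flatKeyMap)) {
            cfg[[flatKeyMap[[nm]]]] <- val
        } else if (nm %in% names(cfg)) {
            if (is.list(cfg[[nm]]) && is.list(val))
                cfg[[nm]][names(val)] <- val
            else cfg[[nm]] <- val
        } else stop("unknown configuration key: ", nm)
    }
    validatePipelineConfig(cfg)
}

validatePipelineConfig <- function(cfg) {
    stopifnot(cfg$select$lambda > 0, cfg$map$categories >= 2,
              length(cfg$map$resolution) == 2L, all(cfg$map$resolution >= 2),
              cfg$evaluate$folds >= 2, cfg$train$feature_dim >= 1)
    cfg$seed <- as.integer(cfg$seed)
    pairTask(cfg$task)                          # validates the task name
    class(cfg) <- "PipelineConfig"
    cfg
}

#' @rdname pipelineConfig
#' @param path YAML configuration file.
#' @param overrides named list of overrides applied after the file.
#' @export
readPipelineConfig <- function(path, overrides = list()) {
    cfg <- pipelineConfig()
    if (!is.null(path)) {
        y <- yaml::read_yaml(path)
        cfg <- applyOverrides(cfg, y)
    }
    applyOverrides(cfg, overrides)
}

## ---- stage plumbing ------------------------------------------------------

artifactPath <- function(cfg, name) file.path(cfg$outdir, name)

requireArtifact <- function(cfg, name, producer) {
    p <- artifactPath(cfg, name)
    if (!file.exists(p))
        stop("stage order error: missing artifact '", p,
             "'; run the '", producer, "' stage first")
    p
}

logStage <- function(cfg, stage, params, inputs, elapsed) {
    entry <- list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  params = params,
                  input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
                  wall_seconds = round(elapsed, 3))
    cat(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), "\n",
        sep = "", file = artifactPath(cfg, "pipeline_log.jsonl"), append = TRUE)
}

withStageLog <- function(cfg, stage, params, inputs, expr) {
    if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    logStage(cfg, stage, params, inputs, proc.time()[["elapsed"]] - t0)
    invisible(res)
}

loadMerged <- function(cfg) {
    p <- requireArtifact(cfg, "merged.tsv", "preprocess")
    s <- requireArtifact(cfg, "samples.csv", "preprocess")
    dt <- data.table::fread(p, sep = "\t")
    vals <- as.matrix(dt[, -1L]); rownames(vals) <- dt[[1L]]
    info <- utils::read.csv(s, stringsAsFactors = FALSE)
    ExpressionCohort(vals, labels = info$label[match(colnames(vals), info$sample_id)],
                     dataset_id = info$dataset[match(colnames(vals), info$sample_id)])
}

loadSelected <- function(cfg, merged) {
    p <- requireArtifact(cfg, "selection.csv", "select")
    sel <- utils::read.csv(p, stringsAsFactors = FALSE)
    sub <- makePairSubset(merged, cfg$task)
    sub[match(sel$probe_id, rownames(sub)), ]
}

## ---- stage commands ------------------------------------------------------

#' Pipeline stage commands
#'
#' Each command reads its upstream artifacts from `cfg$outdir`, runs one
#' stage, writes its outputs there, and appends a line-delimited JSON log
#' entry (stage, parameters, input hashes, wall time). Missing upstream
#' artifacts raise a stage-order error naming the file and the stage that
#' produces it. [cmdRunAll()] chains every stage; with identical
#' configuration and seed it is bitwise reproducible (the evaluation report
#' carries no timestamps).
#'
#' @param cfg a `PipelineConfig` (see [pipelineConfig()]).
#' @return Invisibly, the stage's primary artifact path (or object).
#' @name pipeline-commands
NULL

#' @rdname pipeline-commands
#' @export
cmdSimulate <- function(cfg) {
    sim <- cfg$simulate
    sc <- simConfig(n_datasets = sim$n_datasets,
                    samples_per_class = sim$samples_per_class,
                    n_genes = sim$n_genes, n_informative = sim$n_informative,
                    effect_size = sim$effect_size, noise_sd = sim$noise_sd,
                    batch_scale_range = sim$batch_scale,
                    batch_offset_range = sim$batch_offset,
                    classes = sim$classes, seed = cfg$seed)
    withStageLog(cfg, "simulate", sim, character(), {
        paths <- writeCohort(simulateCohort(sc), cfg$outdir)
        paths
    })
}

#' @rdname pipeline-commands
#' @export
cmdPreprocess <- function(cfg) {
    inp <- cfg$inputs
    if (is.null(inp$expression)) {
        inp$expression <- Sys.glob(file.path(cfg$outdir, "dataset_*.tsv"))
        inp$labels <- artifactPath(cfg, "labels.csv")
        if (!length(inp$expression))
            stop("stage order error: no input expression files configured and no ",
                 "simulated datasets found; run the 'simulate' stage first")
    }
    withStageLog(cfg, "preprocess", list(format = inp$format),
                 c(inp$expression, inp$labels), {
        cohorts <- lapply(inp$expression, readExpression, format = inp$format,
                          labels = inp$labels)
        if (length(cohorts) > 1L) cohorts <- intersectProbes(cohorts)
        merged <- mergeAndNormalize(cohorts)
        writeExpressionTsv(merged, artifactPath(cfg, "merged.tsv"))
        utils::write.csv(data.frame(sample_id = colnames(merged),
                                    label = diagnosis(merged),
                                    dataset = datasetId(merged)),
                         artifactPath(cfg, "samples.csv"), row.names = FALSE,
                         quote = FALSE)
        artifactPath(cfg, "merged.tsv")
    })
}

#' @rdname pipeline-commands
#' @export
cmdSelect <- function(cfg) {
    merged <- loadMerged(cfg)
    withStageLog(cfg, "select", list(lambda = cfg$select$lambda,
                                     task = cfg$task),
                 artifactPath(cfg, "merged.tsv"), {
        sub <- makePairSubset(merged, cfg$task)
        sel <- lassoSelect(sub, lambda = cfg$select$lambda)
        writeSelection(sel, artifactPath(cfg, "selection.csv"))
    })
}

#' @rdname pipeline-commands
#' @export
cmdMap <- function(cfg) {
    merged <- loadMerged(cfg)
    selCo <- loadSelected(cfg, merged)
    withStageLog(cfg, "map", cfg$map, artifactPath(cfg, "selection.csv"), {
        map <- fitGeneMap(selCo, K = cfg$map$categories,
                          resolution = cfg$map$resolution)
        writeGeneMap(map, artifactPath(cfg, "genemap.json"))
    })
}

#' @rdname pipeline-commands
#' @export
cmdRender <- function(cfg) {
    merged <- loadMerged(cfg)
    selCo <- loadSelected(cfg, merged)
    mp <- requireArtifact(cfg, "genemap.json", "map")
    withStageLog(cfg, "render", list(), mp, {
        map <- readGeneMap(mp)
        imgs <- renderImages(selCo, map)
        writeImages(imgs, artifactPath(cfg, "images.tsv"))
    })
}

#' @rdname pipeline-commands
#' @export
cmdTrain <- function(cfg) {
    merged <- loadMerged(cfg)
    selCo <- loadSelected(cfg, merged)
    mp <- requireArtifact(cfg, "genemap.json", "map")
    requireArtifact(cfg, "images.tsv", "render")
    withStageLog(cfg, "train", cfg$train, mp, {
        map <- readGeneMap(mp)
        imgs <- renderImages(selCo, map)
        x <- t(exprs(selCo)); y <- response(selCo)
        tc <- trainConfig(learning_rate = cfg$train$learning_rate,
                          batch_size = cfg$train$batch_size,
                          warmup = cfg$train$warmup,
                          patience = cfg$train$patience,
                          max_epochs = cfg$train$max_epochs,
                          seed = cfg$seed)
        fspec <- networkSpec("fnn", input_dim = ncol(x),
                             feature_dim = cfg$train$feature_dim)
        cspec <- networkSpec("cnn", input_dim = cfg$map$resolution,
                             feature_dim = cfg$train$feature_dim)
        dir.create(artifactPath(cfg, "models"), showWarnings = FALSE)
        writeModel(trainNetwork(buildFnn(fspec, tc$seed), x, y, tc),
                   artifactPath(cfg, "models/fnn.rds"))
        writeModel(trainNetwork(buildCnn(cspec, tc$seed), imgs, y, tc),
                   artifactPath(cfg, "models/cnn.rds"))
        writeModel(trainNetwork(buildFusion(fspec, cspec, tc$seed),
                                list(x = x, images = imgs), y, tc),
                   artifactPath(cfg, "models/fusion.rds"))
        artifactPath(cfg, "models")
    })
}

#' @rdname pipeline-commands
#' @export
cmdEvaluate <- function(cfg) {
    merged <- loadMerged(cfg)
    withStageLog(cfg, "evaluate", c(cfg$evaluate, list(task = cfg$task)),
                 artifactPath(cfg, "merged.tsv"), {
        tc <- trainConfig(learning_rate = cfg$train$learning_rate,
                          batch_size = cfg$train$batch_size,
                          warmup = cfg$train$warmup,
                          patience = cfg$train$patience,
                          max_epochs = cfg$train$max_epochs,
                          seed = cfg$seed)
        reports <- runCV(merged, cfg$task, folds = cfg$evaluate$folds,
                         seed = cfg$seed, lambda = cfg$select$lambda,
                         K = cfg$map$categories,
                         resolution = cfg$map$resolution,
                         feature_dim = cfg$train$feature_dim,
                         train_config = tc)
        writeFoldReport(reports, artifactPath(cfg, "report.json"))
        reports
    })
}

#' @rdname pipeline-commands
#' @export
cmdRunAll <- function(cfg) {
    if (is.null(cfg$inputs$expression)) cmdSimulate(cfg)
    cmdPreprocess(cfg)
    cmdSelect(cfg)
    cmdMap(cfg)
    cmdRender(cfg)
    cmdTrain(cfg)
    cmdEvaluate(cfg)
}
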