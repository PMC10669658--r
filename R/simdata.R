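#' Configuration for the synthetic multi-dataset cohort simulator
#'
#' The simulator emulates the structure of a merged multi-study expression
#' cohort: several datasets measured on a shared probe set, two or three
#' diagnostic groups, a subset of informative genes whose class-conditional
#' means are shifted, and per-dataset affine batch effects (a multiplicative
#' scale followed by an additive offset) that the ingest stage must remove.
#'
#' Informative genes shift the mean of the AD group upward by `effect_size`
#' (in units of the latent per-gene signal); when MCI is simulated its shift
#' is `effect_size / 2`, placing it midway between NC and AD, so pairwise
#' contrasts have graded difficulty mirroring MCI's intermediate clinical
#' status. Non-informative genes are class-independent.
#'
#' @param n_datasets number of simulated datasets (batches).
#' @param samples_per_class number of samples per class in each dataset.
#' @param n_genes total genes per dataset (shared probe namespace).
#' @param n_informative number of informative (differentially expressed)
#'   genes, `<= n_genes`.
#' @param effect_size class mean shift on informative genes, latent units.
#' @param noise_sd per-gene Gaussian noise standard deviation (> 0).
#' @param batch_scale_range interval the per-dataset multiplicative batch
#'   factor is drawn from.
#' @param batch_offset_range interval the per-dataset additive batch offset
#'   is drawn from.
#' @param classes ordered subset of `c("AD", "MCI", "NC")`.
#' @param seed integer seed; identical configurations reproduce identical
#'   cohorts.
#' @return A `list` of class `SimConfig`.
#' @examples
#' cfg <- simConfig(n_datasets = 2, samples_per_class = 10, n_genes = 50,
#'                  n_informative = 5, seed = 1)
#' cohorts <- simulateCohort(cfg)
#' @export
simConfig <- function(n_datasets = 3L, samples_per_class = 50L,
                      n_genes = 1000L, n_informative = 60L,
                      effect_size = 1.0, noise_sd = 1.0,
                      batch_scale_range = c(0.75, 1.25),
                      batch_offset_range = c(-0.5, 0.5),
                      classes = c("AD", "NC"), seed = 1L) {
    cfg <- list(n_datasets = as.integer(n_datasets),
                samples_per_class = as.integer(samples_per_class),
                n_genes = as.integer(n_genes),
                n_informative = as.integer(n_informative),
                effect_size = effect_size, noise_sd = noise_sd,
                batch_scale_range = batch_scale_range,
                batch_offset_range = batch_offset_range,
                classes = classes, seed = as.integer(seed))
    class(cfg) <- "SimConfig"
    validateSimConfig(cfg)
    cfg
}

validateSimConfig <- function(cfg) {
    if (cfg$n_datasets < 1L || cfg$samples_per_class < 1L || cfg$n_genes < 1L)
        stop("configuration error: counts must be positive")
    if (cfg$n_informative < 0L || cfg$n_informative > cfg$n_genes)
        stop("configuration error: n_informative must lie in [0, n_genes]")
    if (cfg$effect_size < 0)
        stop("configuration error: effect_size must be >= 0")
    if (cfg$noise_sd <= 0)
        stop("configuration error: noise_sd must be > 0")
    if (!length(cfg$classes) || !all(cfg$classes %in% c("AD", "MCI", "NC")) ||
        anyDuplicated(cfg$classes))
        stop("configuration error: classes must be a non-empty subset of AD, MCI, NC")
    invisible(cfg)
}

## per-class shift multiplier on informative genes: NC at 0, AD at 1,
## MCI midway.
classShift <- c(AD = 1, MCI = 0.5, NC = 0)

#' Simulate a multi-dataset expression cohort with planted signal
#'
#' Expression is Gaussian per gene around a gene-specific baseline drawn from
#' `U(4, 8)` (a log-intensity scale typical of normalised arrays), with
#' standard deviation `noise_sd`. The first `n_informative` probes (ids
#' `info0001`, ...) carry the planted class signal; the remainder
#' (`gene0001`, ...) are null. Each dataset is then distorted by its own
#' affine batch effect applied to every value.
#'
#' @param config a [simConfig()] object.
#' @return A list of [ExpressionCohort-class] objects, one per dataset,
#'   sharing one probe namespace.
#' @seealso [writeCohort()], [mergeAndNormalize()]
#' @export
simulateCohort <- function(config) {
    validateSimConfig(config)
    set.seed(config$seed)
    g <- config$n_genes; ninf <- config$n_informative
    probes <- c(if (ninf) sprintf("info%04d", seq_len(ninf)),
                if (g > ninf) sprintf("gene%04d", seq_len(g - ninf)))
    baseline <- runif(g, 4, 8)
    shift <- numeric(g)
    shift[seq_len(ninf)] <- config$effect_size

    lapply(seq_len(config$n_datasets), function(d) {
        scl <- runif(1, config$batch_scale_range[1], config$batch_scale_range[2])
        off <- runif(1, config$batch_offset_range[1], config$batch_offset_range[2])
        labels <- rep(config$classes, each = config$samples_per_class)
        n <- length(labels)
        vals <- baseline + matrix(rnorm(g * n, sd = config$noise_sd), g, n)
        vals <- vals + outer(shift, classShift[labels])
        vals <- scl * vals + off
        ExpressionCohort(vals, probe_ids = probes,
                         sample_ids = sprintf("d%d_s%03d", d, seq_len(n)),
                         labels = labels,
                         dataset_id = sprintf("dataset%d", d))
    })
}

#' Write a simulated cohort to disk
#'
#' Each dataset is written as a TSV expression matrix (genes in rows, first
#' column `probe_id`, header row of sample ids) plus one combined two-column
#' labels CSV (`sample_id`, `label`) covering all datasets.
#'
#' @param cohorts list of [ExpressionCohort-class] objects.
#' @param dir output directory (created if missing).
#' @return Invisibly, a list with the written `expression` paths and the
#'   `labels` path.
#' @export
writeCohort <- function(cohorts, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- vapply(seq_along(cohorts), function(i) {
        p <- file.path(dir, sprintf("dataset_%d.tsv", i))
        writeExpressionTsv(cohorts[[i]], p)
        p
    }, character(1))
    lab <- do.call(rbind, lapply(cohorts, function(co)
        data.frame(sample_id = colnames(co), label = diagnosis(co))))
    labPath <- file.path(dir, "labels.csv")
    utils::write.csv(lab, labPath, row.names = FALSE, quote = FALSE)
    invisible(list(expression = paths, labels = labPath))
}

writeExpressionTsv <- function(cohort, path) {
    dt <- data.table::data.table(probe_id = rownames(cohort))
    dt <- cbind(dt, data.table::as.data.table(exprs(cohort)))
    data.table::fwrite(dt, path, sep = "\t")
    invisible(path)
}
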