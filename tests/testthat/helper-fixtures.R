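## Shared fixtures, built in code.

## tiny labelled cohort with exact values
toyCohort <- function(values, labels, dataset = "toy") {
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
    ExpressionCohort(values, labels = labels, dataset_id = dataset)
}

## binary-task cohort wrapper around a plain matrix
toyBinary <- function(values, y01) {
    co <- toyCohort(values, labels = ifelse(y01 == 1, "AD", "NC"))
    makePairSubset(co, "AD_vs_NC")
}

## a small simulated merged cohort with strong signal, for fast end-to-end
## tests (each class >= 5 per fold under k = 5)
smallMerged <- function(seed = 3, samples_per_class = 15, n_genes = 60,
                        n_informative = 10, effect_size = 2, noise_sd = 0.5,
                        n_datasets = 2, classes = c("AD", "NC")) {
    cfg <- simConfig(n_datasets = n_datasets,
                     samples_per_class = samples_per_class,
                     n_genes = n_genes, n_informative = n_informative,
                     effect_size = effect_size, noise_sd = noise_sd,
                     classes = classes, seed = seed)
    mergeAndNormalize(intersectProbes(simulateCohort(cfg)))
}

## fast training configuration for smoke-level network fits
fastTrain <- function(epochs = 5, lr = 1e-3, seed = 1)
    trainConfig(learning_rate = lr, warmup = 0L, patience = epochs,
                max_epochs = epochs, seed = seed)
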