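#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData colData<- rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom stats predict
NULL

#' ExpressionCohort: labelled expression matrix with dataset provenance
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' genes x samples expression matrix in the `"exprs"` assay, per-sample
#' diagnosis labels (`colData(x)$diagnosis`) and the originating dataset
#' identifier (`colData(x)$dataset`). Row names are probe identifiers and
#' column names are sample identifiers; both must be unique. After
#' [makePairSubset()] the object additionally carries a binary response in
#' `colData(x)$y` and the task in `metadata(x)$task`.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment]; no extra slots.
#' @export
setClass("ExpressionCohort", contains = "SummarizedExperiment")

setValidity("ExpressionCohort", function(object) {
    msg <- character()
    if (!("exprs" %in% names(assays(object))))
        msg <- c(msg, "assay 'exprs' is required")
    rn <- rownames(object); cn <- colnames(object)
    if (is.null(rn) || anyDuplicated(rn))
        msg <- c(msg, sprintf("probe ids must be unique and non-NULL (duplicated: %s)",
                              paste(unique(rn[duplicated(rn)]), collapse = ", ")))
    if (is.null(cn) || anyDuplicated(cn))
        msg <- c(msg, "sample ids must be unique and non-NULL")
    cd <- colData(object)
    if (!all(c("diagnosis", "dataset") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'diagnosis' and 'dataset'")
    else if (anyNA(cd$diagnosis))
        msg <- c(msg, "diagnosis labels contain NA")
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionCohort
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param probe_ids character vector of unique probe identifiers (defaults to
#'   `rownames(values)`).
#' @param sample_ids character vector of unique sample identifiers (defaults
#'   to `colnames(values)`).
#' @param labels per-sample diagnosis labels, typically in
#'   `c("AD", "MCI", "NC")`.
#' @param dataset_id a single dataset identifier or one per sample.
#' @return An [ExpressionCohort-class] object.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' ExpressionCohort(m, labels = c("AD", "NC"), dataset_id = "toy")
#' @export
ExpressionCohort <- function(values, probe_ids = rownames(values),
                             sample_ids = colnames(values), labels,
                             dataset_id = "dataset1") {
    values <- as.matrix(values)
    if (is.null(probe_ids) || is.null(sample_ids))
        stop("probe and sample identifiers are required")
    dup <- unique(probe_ids[duplicated(probe_ids)])
    if (length(dup))
        stop("duplicated probe ids: ", paste(dup, collapse = ", "))
    if (length(labels) != ncol(values))
        stop("need one diagnosis label per sample (", ncol(values),
             " samples, ", length(labels), " labels)")
    if (length(dataset_id) == 1L) dataset_id <- rep(dataset_id, ncol(values))
    dimnames(values) <- list(probe_ids, sample_ids)
    se <- SummarizedExperiment(
        assays = list(exprs = values),
        colData = DataFrame(diagnosis = as.character(labels),
                            dataset = as.character(dataset_id),
                            row.names = sample_ids))
    new("ExpressionCohort", se)
}

#' @describeIn ExpressionCohort expression matrix accessor.
#' @param object,x an `ExpressionCohort`.
#' @export
setGeneric("exprs", function(object) standardGeneric("exprs"))

#' @rdname ExpressionCohort
#' @export
setMethod("exprs", "ExpressionCohort", function(object) assay(object, "exprs"))

#' @describeIn ExpressionCohort per-sample diagnosis labels.
#' @export
setGeneric("diagnosis", function(object) standardGeneric("diagnosis"))

#' @rdname ExpressionCohort
#' @export
setMethod("diagnosis", "ExpressionCohort",
          function(object) colData(object)$diagnosis)

#' @describeIn ExpressionCohort per-sample dataset identifiers.
#' @export
setGeneric("datasetId", function(object) standardGeneric("datasetId"))

#' @rdname ExpressionCohort
#' @export
setMethod("datasetId", "ExpressionCohort",
          function(object) colData(object)$dataset)

#' @describeIn ExpressionCohort binary response (only after [makePairSubset()]).
#' @export
setGeneric("response", function(object) standardGeneric("response"))

#' @rdname ExpressionCohort
#' @export
setMethod("response", "ExpressionCohort", function(object) {
    y <- colData(object)$y
    if (is.null(y)) stop("cohort has no binary response; run makePairSubset() first")
    y
})

setMethod("show", "ExpressionCohort", function(object) {
    cat("ExpressionCohort:", nrow(object), "probes x", ncol(object), "samples\n")
    tab <- table(diagnosis(object))
    cat("  diagnosis:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    cat("  datasets :", paste(unique(datasetId(object)), collapse = ", "), "\n")
    if (!is.null(metadata(object)$task))
        cat("  task     :", metadata(object)$task$name, "\n")
})

#' PairTask: a pairwise classification contrast
#'
#' @slot name task name, one of `AD_vs_NC`, `AD_vs_MCI`, `MCI_vs_NC`,
#'   `AD_vs_MCI+NC`, `AD+MCI_vs_NC`.
#' @slot positive labels coded 1 (the first-named group).
#' @slot negative labels coded 0.
#' @export
setClass("PairTask", representation(name = "character",
                                    positive = "character",
                                    negative = "character"))

setValidity("PairTask", function(object) {
    msg <- character()
    if (length(intersect(object@positive, object@negative)))
        msg <- c(msg, "positive and negative classes overlap")
    if (!all(c(object@positive, object@negative) %in% c("AD", "MCI", "NC")))
        msg <- c(msg, "classes must be drawn from AD, MCI, NC")
    if (!length(object@positive) || !length(object@negative))
        msg <- c(msg, "both class sets must be non-empty")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PairTask", function(object) {
    cat("PairTask ", object@name, ": [",
        paste(object@positive, collapse = "+"), "] (1) vs [",
        paste(object@negative, collapse = "+"), "] (0)\n", sep = "")
})

#' SelectionResult: genes retained by LASSO
#'
#' @slot selected ascending indices (into the input probe list) of genes with
#'   non-zero coefficient.
#' @slot lambda the L1 penalty weight used, on the mean-squared-error
#'   objective scale (see [lassoSelect()]).
#' @slot coefficients full per-gene coefficient vector, named by probe id.
#' @slot probeIds input probe identifiers.
#' @export
setClass("SelectionResult", representation(selected = "integer",
                                           lambda = "numeric",
                                           coefficients = "numeric",
                                           probeIds = "character"))

setValidity("SelectionResult", function(object) {
    msg <- character()
    if (is.unsorted(object@selected, strictly = TRUE))
        msg <- c(msg, "selected indices must be strictly ascending")
    if (length(object@coefficients) != length(object@probeIds))
        msg <- c(msg, "one coefficient per probe required")
    if (length(object@selected) &&
        (min(object@selected) < 1L || max(object@selected) > length(object@probeIds)))
        msg <- c(msg, "selected indices out of range")
    if (length(msg)) msg else TRUE
})

#' @describeIn SelectionResult selected probe identifiers.
#' @param object a `SelectionResult`.
#' @export
setGeneric("selectedProbes", function(object) standardGeneric("selectedProbes"))

#' @rdname SelectionResult
#' @export
setMethod("selectedProbes", "SelectionResult",
          function(object) object@probeIds[object@selected])

setMethod("show", "SelectionResult", function(object) {
    cat("SelectionResult:", length(object@selected), "of",
        length(object@probeIds), "genes selected at lambda =",
        format(object@lambda), "\n")
})

#' GeneMap: fitted gene-to-pixel transformation
#'
#' The supervised 2D embedding of genes. `coords` holds the rotated LDA
#' coordinates (x, y per gene); `pixel` the 1-based (row, col) pixel each gene
#' occupies at `resolution` (rows, cols); `fittedOn` records the sample ids
#' the map was fitted on, for leakage auditing.
#'
#' @slot probeIds gene/probe identifiers, one per mapped gene.
#' @slot coords numeric matrix (genes x 2), post-rotation coordinates.
#' @slot resolution integer (rows, cols).
#' @slot pixel integer matrix (genes x 2), 1-based (row, col).
#' @slot rotation rotation angle in radians applied to axis-align the
#'   minimum-area enclosing rectangle.
#' @slot categories the Fisher-distance category of each gene.
#' @slot fittedOn sample identifiers used to fit the map.
#' @export
setClass("GeneMap", representation(probeIds = "character",
                                   coords = "matrix",
                                   resolution = "integer",
                                   pixel = "matrix",
                                   rotation = "numeric",
                                   categories = "integer",
                                   fittedOn = "character"))

setValidity("GeneMap", function(object) {
    msg <- character()
    n <- length(object@probeIds)
    if (nrow(object@coords) != n || nrow(object@pixel) != n)
        msg <- c(msg, "coords and pixel must have one row per gene")
    if (length(object@resolution) != 2L || any(object@resolution < 2L))
        msg <- c(msg, "resolution must be (rows, cols), each >= 2")
    else if (n) {
        if (any(object@pixel[, 1L] < 1L) || any(object@pixel[, 1L] > object@resolution[1L]) ||
            any(object@pixel[, 2L] < 1L) || any(object@pixel[, 2L] > object@resolution[2L]))
            msg <- c(msg, "pixel indices out of image bounds")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn GeneMap (row, col) pixel of each gene (genes x 2, 1-based).
#' @param object a `GeneMap`.
#' @export
setGeneric("pixelOfGene", function(object) standardGeneric("pixelOfGene"))

#' @rdname GeneMap
#' @export
setMethod("pixelOfGene", "GeneMap", function(object) object@pixel)

#' @describeIn GeneMap list of gene indices per occupied pixel, named
#'   `"row,col"`.
#' @export
setGeneric("genesOfPixel", function(object) standardGeneric("genesOfPixel"))

#' @rdname GeneMap
#' @export
setMethod("genesOfPixel", "GeneMap", function(object) {
    key <- paste(object@pixel[, 1L], object@pixel[, 2L], sep = ",")
    split(seq_along(object@probeIds), key)
})

#' @describeIn GeneMap sample ids the map was fitted on.
#' @export
setGeneric("fittedOn", function(object) standardGeneric("fittedOn"))

#' @rdname GeneMap
#' @export
setMethod("fittedOn", "GeneMap", function(object) object@fittedOn)

setMethod("show", "GeneMap", function(object) {
    occ <- nrow(unique(object@pixel))
    cat("GeneMap:", length(object@probeIds), "genes ->",
        paste(object@resolution, collapse = "x"), "image;",
        occ, "occupied pixels; rotation",
        sprintf("%.2f deg", object@rotation * 180 / pi),
        "; fitted on", length(object@fittedOn), "samples\n")
})

#' GeneImageSet: rasterised per-sample gene images
#'
#' @slot pixels numeric array (rows x cols x samples).
#' @slot sampleIds sample identifiers (third dimension).
#' @export
setClass("GeneImageSet", representation(pixels = "array",
                                        sampleIds = "character"))

setValidity("GeneImageSet", function(object) {
    msg <- character()
    if (length(dim(object@pixels)) != 3L)
        msg <- c(msg, "pixels must be a rows x cols x samples array")
    else if (dim(object@pixels)[3L] != length(object@sampleIds))
        msg <- c(msg, "one sample id per image required")
    if (any(!is.finite(object@pixels)))
        msg <- c(msg, "pixel values must be finite")
    if (length(msg)) msg else TRUE
})

setMethod("show", "GeneImageSet", function(object) {
    d <- dim(object@pixels)
    cat("GeneImageSet:", d[3L], "images of", d[1L], "x", d[2L], "pixels\n")
})

#' @describeIn GeneImageSet number of images.
#' @param x a `GeneImageSet`.
#' @export
setMethod("length", "GeneImageSet", function(x) dim(x@pixels)[3L])

#' @describeIn GeneImageSet extract one image as a matrix.
#' @param i sample index or id.
#' @param j,...,drop ignored.
#' @export
setMethod("[[", "GeneImageSet", function(x, i, j, ...) {
    if (is.character(i)) i <- match(i, x@sampleIds)
    x@pixels[, , i]
})

#' NeuralNet: a feed-forward, convolutional or fusion network
#'
#' Container for an architecture description (`arch`), its parameter arrays
#' (`params`), and — after [trainNetwork()] — the per-epoch training log.
#'
#' @slot kind `"fnn"`, `"cnn"` or `"fusion"`.
#' @slot arch architecture description (layer list; for fusion, branch lists
#'   and head).
#' @slot params named list of numeric parameter arrays.
#' @slot log data.frame with columns `epoch`, `loss`, `accuracy` (empty until
#'   trained).
#' @slot trained logical.
#' @export
setClass("NeuralNet", representation(kind = "character",
                                     arch = "list",
                                     params = "list",
                                     log = "data.frame",
                                     trained = "logical"))

setMethod("show", "NeuralNet", function(object) {
    cat("NeuralNet (", object@kind, "): ",
        nnCountParams(object), " parameters; ",
        if (object@trained)
            sprintf("trained %d epochs, final loss %.4f",
                    nrow(object@log), object@log$loss[nrow(object@log)])
        else "untrained", "\n", sep = "")
})

#' FoldReport: cross-validation metrics for one model
#'
#' @slot model model name (`fnn_only`, `cnn_only`, `fusion`).
#' @slot task task name.
#' @slot metrics data.frame: one row per fold with accuracy, auc, precision,
#'   recall, f1.
#' @slot means named numeric vector of fold-averaged metrics.
#' @slot roc data.frame of ROC points (fold, threshold, fpr, tpr).
#' @slot folds integer fold assignment per sample (named by sample id).
#' @slot fittedOn list (per fold) of training-sample ids used to fit all
#'   stage artifacts, for leakage auditing.
#' @slot seed integer seed the folds and training were derived from.
#' @export
setClass("FoldReport", representation(model = "character",
                                      task = "character",
                                      metrics = "data.frame",
                                      means = "numeric",
                                      roc = "data.frame",
                                      folds = "integer",
                                      fittedOn = "list",
                                      seed = "integer"))

setValidity("FoldReport", function(object) {
    msg <- character()
    num <- object@means[c("accuracy", "auc", "precision", "recall", "f1")]
    if (anyNA(num) || any(num < 0) || any(num > 1))
        msg <- c(msg, "mean metrics must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "FoldReport", function(object) {
    cat("FoldReport [", object@model, "] task ", object@task, " (",
        max(object@folds), " folds)\n", sep = "")
    m <- object@means
    cat(sprintf("  mean: acc=%.3f auc=%.3f prec=%.3f rec=%.3f f1=%.3f\n",
                m["accuracy"], m["auc"], m["precision"], m["recall"], m["f1"]))
})
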