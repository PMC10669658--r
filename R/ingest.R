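#' Read an expression matrix with labels
#'
#' Supports two dialects: `"tsv"` — a genes x samples table whose first
#' column holds probe ids and whose header row holds sample ids (the format
#' written by [writeCohort()]); and `"geo_series_matrix"` — a GEO
#' series-matrix text file, whose expression table is parsed from the block
#' between `!series_matrix_table_begin` and `!series_matrix_table_end` only.
#'
#' Labels come either from a companion two-column CSV (`sample_id,label`;
#' the `labels` argument) or, for series-matrix input, from
#' `!Sample_characteristics_ch1` lines matched against `label_map`:
#' a named character vector whose names are regular expressions tried in
#' order against each sample's characteristics strings and whose values are
#' the corresponding diagnosis labels (e.g.
#' `c("status: AD" = "AD", "status: CTL" = "NC")`).
#'
#' @param path input file.
#' @param format `"tsv"` or `"geo_series_matrix"`.
#' @param labels path to a labels CSV (required for `"tsv"`; overrides
#'   characteristics parsing for series-matrix input when given).
#' @param label_map named character vector mapping characteristics regexes to
#'   diagnosis labels (series-matrix input only).
#' @param dataset_id dataset identifier recorded per sample; defaults to the
#'   file name without extension.
#' @return An [ExpressionCohort-class].
#' @export
readExpression <- function(path, format = c("tsv", "geo_series_matrix"),
                           labels = NULL, label_map = NULL,
                           dataset_id = NULL) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (is.null(dataset_id))
        dataset_id <- sub("\\.[^.]*$", "", basename(path))
    if (format == "tsv") {
        dt <- data.table::fread(path, sep = "\t", header = TRUE)
        probes <- as.character(dt[[1L]])
        vals <- as.matrix(dt[, -1L])
        storage.mode(vals) <- "double"
        rownames(vals) <- probes
        lab <- readLabels(labels, colnames(vals))
    } else {
        parsed <- parseSeriesMatrix(path)
        vals <- parsed$values
        if (!is.null(labels)) {
            lab <- readLabels(labels, colnames(vals))
        } else {
            if (is.null(label_map))
                stop("labeling error: series-matrix input needs 'labels' or 'label_map'")
            lab <- mapCharacteristics(parsed$characteristics, colnames(vals),
                                      label_map)
        }
    }
    dup <- unique(rownames(vals)[duplicated(rownames(vals))])
    if (length(dup))
        stop("format error: duplicated probe ids: ", paste(dup, collapse = ", "))
    ExpressionCohort(vals, labels = lab, dataset_id = dataset_id)
}

#' Read a two-column labels CSV and align it to sample ids
#'
#' @param path CSV with columns `sample_id` and `label`.
#' @param sample_ids sample ids to align to; every id must be labelled.
#' @return Character vector of labels in `sample_ids` order.
#' @export
readLabels <- function(path, sample_ids) {
    if (is.null(path)) stop("labeling error: a labels CSV is required")
    lab <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "label") %in% names(lab)))
        stop("labeling error: labels CSV needs 'sample_id' and 'label' columns")
    idx <- match(sample_ids, lab$sample_id)
    if (anyNA(idx))
        stop("labeling error: no label for sample(s): ",
             paste(sample_ids[is.na(idx)], collapse = ", "))
    lab$label[idx]
}

## Parse a GEO series-matrix file: expression values strictly from the
## table block; !Sample_* header lines kept for label extraction.
parseSeriesMatrix <- function(path) {
    lines <- readLines(path)
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
        stop("format error: series_matrix table block not found in ", path)
    tab <- data.table::fread(text = lines[(beg + 1L):(end - 1L)],
                             sep = "\t", header = TRUE)
    probes <- gsub('"', "", as.character(tab[[1L]]))
    vals <- as.matrix(tab[, -1L])
    storage.mode(vals) <- "double"
    rownames(vals) <- probes
    colnames(vals) <- gsub('"', "", colnames(vals))
    chLines <- grep("^!Sample_characteristics_ch1", lines, value = TRUE)
    ch <- lapply(chLines, function(l) {
        fields <- gsub('"', "", strsplit(l, "\t")[[1L]][-1L])
        fields
    })
    list(values = vals, characteristics = ch)
}

mapCharacteristics <- function(characteristics, sample_ids, label_map) {
    vapply(seq_along(sample_ids), function(j) {
        fields <- unlist(lapply(characteristics, `[`, j))
        for (pat in names(label_map)) {
            if (any(grepl(pat, fields))) return(unname(label_map[pat]))
        }
        stop("labeling error: no label_map pattern matched sample ",
             sample_ids[j])
    }, character(1))
}

#' Restrict cohorts to their shared probes
#'
#' Every returned cohort is restricted to the intersection of all probe
#' sets, rows reordered to one canonical lexicographic order so the result
#' is independent of input file or argument order.
#'
#' @param cohorts list of at least two [ExpressionCohort-class] objects.
#' @return List of cohorts, all with identical row names.
#' @export
intersectProbes <- function(cohorts) {
    if (length(cohorts) < 2L) stop("need at least two cohorts")
    shared <- Reduce(intersect, lapply(cohorts, rownames))
    if (!length(shared)) stop("empty probe intersection across datasets")
    shared <- sort(shared)
    lapply(cohorts, function(co) co[shared, ])
}

#' Merge datasets with per-dataset standardisation and cohort min-max scaling
#'
#' Within each dataset every gene row is z-scored (population standard
#' deviation; constant rows map to zero); datasets are then concatenated
#' along samples and each gene is min-max scaled over the combined cohort so
#' all values lie in `[0, 1]`. Zero-range genes after merging also map to
#' zero. Per-sample dataset ids are retained for traceability.
#'
#' @param cohorts list of [ExpressionCohort-class] objects sharing one probe
#'   order (run [intersectProbes()] first).
#' @return A single merged [ExpressionCohort-class] with values in `[0, 1]`.
#' @export
mergeAndNormalize <- function(cohorts) {
    if (!is.list(cohorts)) cohorts <- list(cohorts)
    ref <- rownames(cohorts[[1L]])
    for (co in cohorts[-1L])
        if (!identical(rownames(co), ref))
            stop("probe-order mismatch: run intersectProbes() first")
    zs <- lapply(cohorts, function(co) rowZscore(exprs(co)))
    vals <- do.call(cbind, zs)
    rng <- matrixStatsRange(vals)
    span <- rng[, 2L] - rng[, 1L]
    span[span == 0] <- Inf                      # constant rows -> 0
    vals <- (vals - rng[, 1L]) / span
    ExpressionCohort(vals, probe_ids = ref,
                     sample_ids = unlist(lapply(cohorts, colnames)),
                     labels = unlist(lapply(cohorts, diagnosis)),
                     dataset_id = unlist(lapply(cohorts, datasetId)))
}

## row-wise z-score with population (1/n) standard deviation;
## zero-variance rows map to 0
rowZscore <- function(m) {
    mu <- rowMeans(m)
    sd <- sqrt(rowMeans((m - mu)^2))
    sd[sd == 0] <- Inf
    (m - mu) / sd
}

matrixStatsRange <- function(m) {
    cbind(apply(m, 1L, min), apply(m, 1L, max))
}

#' Construct a pairwise classification task
#'
#' @param name one of `"AD_vs_NC"`, `"AD_vs_MCI"`, `"MCI_vs_NC"`,
#'   `"AD_vs_MCI+NC"`, `"AD+MCI_vs_NC"`. The first-named group is the
#'   positive class (coded 1).
#' @return A [PairTask-class].
#' @export
pairTask <- function(name = c("AD_vs_NC", "AD_vs_MCI", "MCI_vs_NC",
                              "AD_vs_MCI+NC", "AD+MCI_vs_NC")) {
    name <- match.arg(name)
    sides <- strsplit(name, "_vs_")[[1L]]
    new("PairTask", name = name,
        positive = strsplit(sides[1L], "+", fixed = TRUE)[[1L]],
        negative = strsplit(sides[2L], "+", fixed = TRUE)[[1L]])
}

#' Restrict a cohort to a pairwise task and attach the binary response
#'
#' Samples with a diagnosis outside the task are dropped; positive classes
#' are coded 1 and negative classes 0 in `colData(x)$y`. Sample order is
#' preserved.
#'
#' @param cohort an [ExpressionCohort-class].
#' @param task a [PairTask-class] or task name accepted by [pairTask()].
#' @return The restricted cohort with binary response and
#'   `metadata(x)$task` recorded.
#' @export
makePairSubset <- function(cohort, task) {
    if (is.character(task)) task <- pairTask(task)
    lab <- diagnosis(cohort)
    for (cl in c(task@positive, task@negative))
        if (!any(lab == cl))
            stop("task class absent from cohort: ", cl)
    keep <- lab %in% c(task@positive, task@negative)
    out <- cohort[, keep]
    colData(out)$y <- as.integer(diagnosis(out) %in% task@positive)
    metadata(out)$task <- list(name = task@name, positive = task@positive,
                               negative = task@negative)
    out
}
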