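#' Select differentially expressed genes by LASSO regression
#'
#' Fits an L1-penalised linear model of the binary response on all gene
#' values (genes as predictors, samples as observations, intercept
#' included) and returns the genes with non-zero coefficients.
#'
#' The penalty convention is pinned so that `lambda` is meaningful: the
#' objective is `mean((y - b0 - X'beta)^2) + lambda * sum(|beta|)`, with
#' predictors entering as-is (no internal re-standardisation — inputs are
#' expected already on the `[0, 1]` scale from [mergeAndNormalize()]).
#' The fit is delegated to coordinate descent in \pkg{glmnet}, whose
#' objective divides the squared error by `2n`, so the penalty weight passed
#' down is `lambda / 2`. Convergence threshold `1e-9`. A coefficient counts
#' as non-zero when its magnitude exceeds `1e-12`, absorbing solver noise.
#'
#' Genes enter the model only when `lambda` is below the analytic bound
#' `2 * max_g |cov(x_g, y)|` (population covariance with the centred
#' response); at or above it the selection is empty and an error advising a
#' smaller `lambda` is raised.
#'
#' @param cohort an [ExpressionCohort-class] carrying a binary response
#'   (see [makePairSubset()]).
#' @param lambda L1 penalty weight on the mean-squared-error objective;
#'   default `1e-6`.
#' @return A [SelectionResult-class].
#' @examples
#' cfg <- simConfig(n_datasets = 1, samples_per_class = 20, n_genes = 60,
#'                  n_informative = 5, effect_size = 2, noise_sd = 0.5, seed = 3)
#' co <- makePairSubset(mergeAndNormalize(simulateCohort(cfg)), "AD_vs_NC")
#' sel <- lassoSelect(co, lambda = 1e-4)
#' selectedProbes(sel)[1:5]
#' @export
lassoSelect <- function(cohort, lambda = 1e-6) {
    if (lambda <= 0) stop("lambda must be > 0")
    y <- response(cohort)
    if (length(unique(y)) < 2L)
        stop("all samples belong to one class; cannot fit LASSO")
    x <- t(exprs(cohort))                       # samples x genes
    glam <- lambda / 2                          # glmnet objective is (1/2n)RSS
    ## a short decreasing path ending at the target stabilises the
    ## coordinate-descent warm starts at very small penalties
    path <- sort(unique(c(glam * c(1000, 100, 10, 1))), decreasing = TRUE)
    fit <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1,
                          lambda = path, standardize = FALSE,
                          intercept = TRUE, thresh = 1e-9)
    beta <- as.numeric(stats::coef(fit, s = glam, exact = FALSE))[-1L]
    names(beta) <- rownames(cohort)
    sel <- which(abs(beta) > 1e-12)
    if (!length(sel))
        stop("empty selection: no gene has a non-zero coefficient at lambda = ",
             format(lambda), "; try a smaller lambda")
    new("SelectionResult", selected = as.integer(sort(sel)), lambda = lambda,
        coefficients = beta, probeIds = rownames(cohort))
}

#' Write a selection result to disk
#'
#' Writes a CSV of `(probe_id, coefficient)` for the selected genes plus a
#' JSON sidecar holding `lambda` and the selected count `n`.
#'
#' @param sel a [SelectionResult-class].
#' @param path output CSV path; the sidecar is `<path>.json`.
#' @return Invisibly, the CSV path.
#' @export
writeSelection <- function(sel, path) {
    df <- data.frame(probe_id = selectedProbes(sel),
                     coefficient = sel@coefficients[sel@selected])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(lambda = sel@lambda, n = length(sel@selected)),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    invisible(path)
}
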