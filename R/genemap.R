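#' Fisher-distance score of each gene for a binary contrast
#'
#' For gene `g` with class means `mu1, mu0` and population variances
#' `s1^2, s0^2` over the given samples, the score is
#' `(mu1 - mu0)^2 / (s1^2 + s0^2 + eps)` with `eps = 1e-12` guarding the
#' degenerate both-classes-constant case. Larger scores mean more
#' discriminative genes.
#'
#' @param cohort an [ExpressionCohort-class] with binary response; each
#'   class needs at least two samples.
#' @return Numeric vector of non-negative scores, named by probe id.
#' @examples
#' m <- rbind(g1 = c(0, 2, 4, 6))
#' colnames(m) <- paste0("s", 1:4)
#' co <- ExpressionCohort(m, labels = c("NC", "NC", "AD", "AD"))
#' co <- makePairSubset(co, "AD_vs_NC")
#' fisherScores(co)   # (5-1)^2 / (1+1) = 8
#' @export
fisherScores <- function(cohort) {
    y <- response(cohort)
    if (sum(y == 1L) < 2L || sum(y == 0L) < 2L)
        stop("each class needs >= 2 samples for Fisher scoring")
    m <- exprs(cohort)
    m1 <- m[, y == 1L, drop = FALSE]
    m0 <- m[, y == 0L, drop = FALSE]
    mu1 <- rowMeans(m1); mu0 <- rowMeans(m0)
    v1 <- rowMeans((m1 - mu1)^2)                # population variance
    v0 <- rowMeans((m0 - mu0)^2)
    (mu1 - mu0)^2 / (v1 + v0 + 1e-12)
}

#' Bin genes into equal-count categories by Fisher score
#'
#' Genes are ranked ascending by score (ties broken by gene index) and split
#' into `K` contiguous rank blocks whose sizes differ by at most one; when
#' the division is uneven the larger blocks go to the lower categories.
#' Category 1 therefore holds the least discriminative genes and category
#' `K` the most.
#'
#' @param scores numeric score vector (one per gene).
#' @param K number of categories (default 15; must satisfy `2 <= K <=
#'   length(scores)`).
#' @return Integer vector of categories in `1..K`, parallel to `scores`.
#' @export
categorizeGenes <- function(scores, K = 15L) {
    n <- length(scores); K <- as.integer(K)
    if (K < 2L) stop("K must be >= 2")
    if (n < K) stop("need at least K genes (", n, " < ", K, ")")
    sizes <- rep(n %/% K, K)
    extra <- n %% K
    if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    rk <- order(scores, seq_len(n))             # ascending, index tie-break
    cat <- integer(n)
    cat[rk] <- rep(seq_len(K), times = sizes)
    cat
}

#' Supervised 2D embedding of genes by linear discriminant analysis
#'
#' Each gene is treated as an observation whose feature vector is its
#' expression across the (training) samples and whose class is its Fisher
#' category; LDA then maximises between-category scatter relative to
#' within-category scatter, placing similarly discriminative genes near one
#' another. The generalized eigenproblem is solved by symmetric whitening of
#' the within-scatter matrix (spectral pseudo-inverse when singular) and
#' genes are projected onto the top two discriminant axes. Sign convention:
#' each axis's largest-magnitude loading is made positive, so the embedding
#' is reproducible.
#'
#' @param cohort an [ExpressionCohort-class] restricted to the selected
#'   genes (samples = feature dimensions).
#' @param categories integer category per gene with at least 3 distinct
#'   non-empty categories (fewer yields fewer than 2 discriminant axes).
#' @return Numeric matrix (genes x 2) of raw 2D coordinates.
#' @export
ldaProject <- function(cohort, categories) {
    x <- exprs(cohort)                          # genes x samples
    if (nrow(x) != length(categories))
        stop("one category per gene required")
    K <- length(unique(categories))
    if (K < 3L) stop("LDA mapping needs K >= 3 categories for 2 axes")
    if (all(apply(x, 2L, stats::var) == 0))
        stop("degenerate input: all gene feature vectors identical")
    s <- ncol(x)
    gm <- colMeans(x)
    xc <- sweep(x, 2L, gm)
    Sw <- matrix(0, s, s); Sb <- matrix(0, s, s)
    for (k in unique(categories)) {
        xk <- x[categories == k, , drop = FALSE]
        mk <- colMeans(xk)
        xkc <- sweep(xk, 2L, mk)
        Sw <- Sw + crossprod(xkc)
        d <- mk - gm
        Sb <- Sb + nrow(xk) * tcrossprod(d)
    }
    ## whiten Sw spectrally (pseudo-inverse on the retained subspace)
    ew <- eigen((Sw + t(Sw)) / 2, symmetric = TRUE)
    tol <- max(ew$values, 0) * s * .Machine$double.eps
    keep <- ew$values > max(tol, 1e-300)
    if (!any(keep)) stop("degenerate input: within-category scatter is zero")
    W <- ew$vectors[, keep, drop = FALSE] %*%
        diag(1 / sqrt(ew$values[keep]), sum(keep))
    B <- crossprod(W, Sb %*% W)
    eb <- eigen((B + t(B)) / 2, symmetric = TRUE)
    nax <- min(2L, ncol(W))
    axes <- W %*% eb$vectors[, seq_len(nax), drop = FALSE]
    if (nax < 2L) axes <- cbind(axes, 0)        # guard: rank-1 fallback
    ## deterministic sign: largest-|loading| entry positive per axis
    for (j in 1:2) {
        a <- axes[, j]
        i <- which.max(abs(a))
        if (a[i] < 0) axes[, j] <- -a
    }
    coords <- xc %*% axes
    dimnames(coords) <- list(rownames(x), c("x", "y"))
    coords
}

#' Rotate a point set so its minimum-area enclosing rectangle is axis-aligned
#'
#' Computes the convex hull, finds the minimum-area enclosing rectangle by
#' rotating calipers (one rectangle side is collinear with a hull edge), and
#' rotates all points by the negative of that side's angle. Candidate angles
#' are reduced modulo 90 degrees into `(-45, 45]`; area ties are broken by
#' the smallest `|angle|`.
#'
#' @param coords numeric matrix (points x 2); at least 3 non-collinear
#'   points.
#' @return List with `coords` (rotated points), `angle` (radians, the
#'   rotation that was removed) and `area` (rectangle area).
#' @export
minRectangleAlign <- function(coords) {
    coords <- as.matrix(coords)
    if (nrow(coords) < 3L)
        stop("degenerate point set: need >= 3 points")
    hull <- grDevices::chull(coords)
    if (length(hull) < 3L)
        stop("degenerate point set: points are collinear or coincident")
    h <- coords[hull, , drop = FALSE]
    nh <- nrow(h)
    edges <- h[c(2:nh, 1L), ] - h
    ang <- atan2(edges[, 2L], edges[, 1L])
    ang <- ((ang + pi / 4) %% (pi / 2)) - pi / 4   # reduce to (-45, 45] deg
    ang <- unique(ang)
    cand <- vapply(ang, function(a) rotatedBboxArea(h, a), numeric(1))
    best <- min(cand)
    ok <- which(cand <= best * (1 + 1e-9))
    a <- ang[ok][which.min(abs(ang[ok]))]
    rot <- rotateCoords(coords, -a)
    list(coords = rot, angle = a, area = rotatedBboxArea(h, a))
}

rotateCoords <- function(m, theta) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
    out <- m %*% t(R)
    dimnames(out) <- dimnames(m)
    out
}

rotatedBboxArea <- function(pts, theta) {
    r <- rotateCoords(pts, -theta)
    (max(r[, 1L]) - min(r[, 1L])) * (max(r[, 2L]) - min(r[, 2L]))
}

#' Rasterise 2D gene coordinates onto a pixel grid
#'
#' Each axis is min-max scaled to `[0, cols - 1]` (x) and `[0, rows - 1]`
#' (y) and rounded half-up to the nearest integer pixel. The returned pixel
#' indices are 1-based `(row, col)` with row 1 at the top; y increases
#' downward in image convention.
#'
#' @param coords numeric matrix (genes x 2) of rotated coordinates.
#' @param resolution integer `(rows, cols)`, each at least 2.
#' @return Integer matrix (genes x 2) of `(row, col)` pixel indices.
#' @export
rasterizeCoords <- function(coords, resolution = c(50L, 50L)) {
    resolution <- as.integer(resolution)
    if (length(resolution) != 2L || any(resolution < 2L))
        stop("resolution must be (rows, cols) with each >= 2")
    rngx <- range(coords[, 1L]); rngy <- range(coords[, 2L])
    if (diff(rngx) == 0 || diff(rngy) == 0)
        stop("degenerate coordinates: zero range on an axis")
    sx <- (coords[, 1L] - rngx[1L]) / diff(rngx) * (resolution[2L] - 1L)
    sy <- (coords[, 2L] - rngy[1L]) / diff(rngy) * (resolution[1L] - 1L)
    px <- cbind(row = as.integer(floor(sy + 0.5)) + 1L,
                col = as.integer(floor(sx + 0.5)) + 1L)
    rownames(px) <- rownames(coords)
    px
}

#' Fit the full gene-to-image map on a training cohort
#'
#' Chains [fisherScores()], [categorizeGenes()], [ldaProject()],
#' [minRectangleAlign()] and [rasterizeCoords()] and records the training
#' sample ids, so downstream code can verify that no held-out sample
#' influenced the map.
#'
#' @param cohort an [ExpressionCohort-class] with binary response,
#'   restricted to the selected genes.
#' @param K number of Fisher categories (default 15).
#' @param resolution integer `(rows, cols)` image size (default 50 x 50).
#' @return A [GeneMap-class].
#' @export
fitGeneMap <- function(cohort, K = 15L, resolution = c(50L, 50L)) {
    sc <- fisherScores(cohort)
    cats <- categorizeGenes(sc, K)
    raw <- ldaProject(cohort, cats)
    al <- minRectangleAlign(raw)
    px <- rasterizeCoords(al$coords, resolution)
    new("GeneMap", probeIds = rownames(cohort), coords = al$coords,
        resolution = as.integer(resolution), pixel = px,
        rotation = al$angle, categories = as.integer(cats),
        fittedOn = colnames(cohort))
}

#' Render per-sample gene images through a fitted map
#'
#' Each sample's image holds, at every occupied pixel, the arithmetic mean
#' of that sample's expression over the genes assigned to the pixel;
#' unoccupied pixels are zero.
#'
#' @param cohort an [ExpressionCohort-class] with exactly the map's genes in
#'   the map's order.
#' @param map a [GeneMap-class].
#' @return A [GeneImageSet-class].
#' @export
renderImages <- function(cohort, map) {
    if (!identical(rownames(cohort), map@probeIds))
        stop("dimension mismatch: cohort genes must equal the map's genes, same order")
    m <- exprs(cohort)
    rows <- map@resolution[1L]; cols <- map@resolution[2L]
    lin <- (map@pixel[, 2L] - 1L) * rows + map@pixel[, 1L]
    sums <- rowsum(m, group = lin)              # sorted by linear pixel id
    counts <- as.vector(table(lin))
    flat <- matrix(0, rows * cols, ncol(m))
    flat[as.integer(rownames(sums)), ] <- sums / counts
    new("GeneImageSet",
        pixels = array(flat, dim = c(rows, cols, ncol(m))),
        sampleIds = colnames(m))
}

#' Serialize a GeneMap to JSON
#'
#' Writes probe-to-pixel assignments (`probe_id -> [row, col]`, 1-based),
#' the resolution, rotation angle, categories, coordinates and fitting
#' provenance. [readGeneMap()] restores the object.
#'
#' @param map a [GeneMap-class].
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
writeGeneMap <- function(map, path) {
    obj <- list(resolution = map@resolution,
                rotation = map@rotation,
                probe_ids = map@probeIds,
                pixel = unname(lapply(seq_along(map@probeIds),
                                      function(i) map@pixel[i, ])),
                coords = unname(lapply(seq_along(map@probeIds),
                                       function(i) unname(map@coords[i, ]))),
                categories = map@categories,
                fitted_on = map@fittedOn,
                index_base = 1L)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeGeneMap
#' @export
readGeneMap <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    asMat <- function(x) {                      # rows may simplify to a matrix
        m <- if (is.matrix(x)) x else do.call(rbind, x)
        dimnames(m) <- NULL
        m
    }
    new("GeneMap", probeIds = obj$probe_ids,
        coords = asMat(obj$coords),
        resolution = as.integer(obj$resolution),
        pixel = matrix(as.integer(asMat(obj$pixel)), ncol = 2L),
        rotation = obj$rotation,
        categories = as.integer(obj$categories),
        fittedOn = obj$fitted_on)
}

#' Write rendered images to disk
#'
#' Writes one wide TSV (samples in rows; columns `px_<row>_<col>` in
#' column-major order) and, optionally, one grayscale PNG per sample for
#' visual inspection (requires the \pkg{png} package).
#'
#' @param images a [GeneImageSet-class].
#' @param path output TSV path.
#' @param png_dir optional directory for per-sample PNGs.
#' @return Invisibly, `path`.
#' @export
writeImages <- function(images, path, png_dir = NULL) {
    d <- dim(images@pixels)
    flat <- matrix(images@pixels, d[1L] * d[2L], d[3L])
    grid <- expand.grid(row = seq_len(d[1L]), col = seq_len(d[2L]))
    df <- data.table::data.table(sample_id = images@sampleIds)
    wide <- data.table::as.data.table(t(flat))
    data.table::setnames(wide, sprintf("px_%d_%d", grid$row, grid$col))
    data.table::fwrite(cbind(df, wide), path, sep = "\t")
    if (!is.null(png_dir)) {
        if (!requireNamespace("png", quietly = TRUE))
            stop("PNG output needs the 'png' package")
        if (!dir.exists(png_dir)) dir.create(png_dir, recursive = TRUE)
        rngAll <- range(images@pixels)
        for (i in seq_len(d[3L])) {
            img <- images@pixels[, , i]
            scl <- if (diff(rngAll) > 0) (img - rngAll[1L]) / diff(rngAll) else img * 0
            png::writePNG(scl, file.path(png_dir,
                                         paste0(images@sampleIds[i], ".png")))
        }
    }
    invisible(path)
}
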