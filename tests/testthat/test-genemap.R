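test_that("Fisher scores match hand evaluation and degenerate cases", {
    co <- toyBinary(matrix(c(0, 2, 4, 6), 1, 4), c(0, 0, 1, 1))
    expect_equal(unname(fisherScores(co)), 8, tolerance = 1e-12)

    same <- toyBinary(matrix(c(1, 3, 1, 3), 1, 4), c(0, 0, 1, 1))
    expect_equal(unname(fisherScores(same)), 0)

    const <- toyBinary(matrix(2, 1, 4), c(0, 0, 1, 1))
    expect_equal(unname(fisherScores(const)), 0)   # eps guard, no NaN

    tiny <- toyBinary(matrix(rnorm(3), 1, 3), c(0, 1, 1))
    expect_error(fisherScores(tiny), ">= 2 samples")
})

test_that("category sizes differ by at most one with larger blocks first", {
    expect_equal(as.vector(table(categorizeGenes(rnorm(30), 15))), rep(2L, 15))
    cats31 <- categorizeGenes(rnorm(31), 15)
    sz <- as.vector(table(cats31))
    expect_equal(sort(sz, decreasing = TRUE), c(3L, rep(2L, 14)))
    expect_equal(sz[1], 3L)                     # the larger block is category 1

    ## all-tied scores: assignment is by gene index, still balanced
    tied <- categorizeGenes(rep(1, 10), 5)
    expect_identical(tied, rep(1:5, each = 2L))

    expect_error(categorizeGenes(rnorm(5), 15), "at least K")
    expect_error(categorizeGenes(rnorm(5), 1), ">= 2")
})

test_that("categories are rank-monotone in the score", {
    set.seed(3)
    for (K in c(7, 9, 11, 13, 15, 17)) {
        sc <- sample(c(rnorm(40), rep(0.5, 10)))   # includes ties
        cats <- categorizeGenes(sc, K)
        ord <- order(sc, seq_along(sc))
        expect_true(all(diff(cats[ord]) >= 0))
        expect_lte(diff(range(table(cats))), 1)
    }
})

ldaFixture <- function(n = 24, s = 5, seed = 17) {
    set.seed(seed)
    cats <- sort(rep_len(1:3, n))
    x <- matrix(rnorm(n * s, sd = 0.05), n, s)
    x[, 1] <- x[, 1] + c(0, 4, 8)[cats]         # clusters along feature 1
    rownames(x) <- sprintf("g%02d", 1:n)
    colnames(x) <- sprintf("s%d", 1:s)
    list(co = toyCohort(x, labels = rep("AD", s)), cats = cats, x = x)
}

test_that("LDA axis 1 tracks the separating feature on clustered categories", {
    f <- ldaFixture()
    proj <- ldaProject(f$co, f$cats)
    expect_equal(dim(proj), c(24L, 2L))
    expect_gt(abs(stats::cor(proj[, 1], f$x[, 1])), 0.99)
})

test_that("LDA projections are invariant to adding a constant to every feature", {
    f <- ldaFixture(seed = 23)
    proj <- ldaProject(f$co, f$cats)
    co2 <- toyCohort(f$x + 7, labels = rep("AD", ncol(f$x)))
    expect_equal(ldaProject(co2, f$cats), proj, tolerance = 1e-9)
})

test_that("LDA rejects too few categories and degenerate inputs", {
    f <- ldaFixture()
    expect_error(ldaProject(f$co, rep(1:2, each = 12)), "K >= 3")
    flat <- toyCohort(matrix(1, 9, 4), labels = rep("AD", 4))
    expect_error(ldaProject(flat, rep(1:3, each = 3)), "degenerate")
})

test_that("already axis-aligned rectangles are returned unchanged", {
    sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
    out <- minRectangleAlign(sq)
    expect_equal(out$angle, 0)
    expect_equal(out$area, 1, tolerance = 1e-12)
    expect_equal(out$coords, sq, ignore_attr = TRUE)
})

test_that("a rotated square is restored to axis alignment", {
    sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
    th <- 45 * pi / 180
    rot <- sq %*% t(matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2))
    out <- minRectangleAlign(rot)
    expect_equal(out$area, 1, tolerance = 1e-9)
    ## restored rectangle is axis aligned: spans equal side length 1
    expect_equal(diff(range(out$coords[, 1])), 1, tolerance = 1e-9)
    expect_equal(diff(range(out$coords[, 2])), 1, tolerance = 1e-9)
})

test_that("collinear point sets raise a degeneracy error", {
    line <- cbind(1:5, 2 * (1:5))
    expect_error(minRectangleAlign(line), "collinear|degenerate")
    expect_error(minRectangleAlign(cbind(1, 1)), "degenerate")
})

test_that("rasterisation maps rectangle corners to distinct pixels", {
    corners <- cbind(c(0, 3, 0, 3), c(0, 0, 2, 2))
    rownames(corners) <- paste0("g", 1:4)
    px <- rasterizeCoords(corners, c(2, 2))
    expect_equal(nrow(unique(px)), 4L)
    ## coincident points share a pixel and genesOfPixel lists both
    co2 <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 0), d = c(0.2, 1))
    px2 <- rasterizeCoords(co2, c(3, 3))
    expect_identical(px2["a", ], px2["b", ])
    expect_error(rasterizeCoords(cbind(c(0, 0, 0), c(0, 1, 2)), c(4, 4)),
                 "zero range|degenerate")
})

test_that("occupied pixel count is non-increasing as resolution decreases", {
    set.seed(12)
    pts <- cbind(runif(100), runif(100))
    occ <- vapply(c(50, 20, 10, 5), function(r)
        nrow(unique(rasterizeCoords(pts, c(r, r)))), numeric(1))
    expect_true(all(diff(occ) <= 0))
})

test_that("pixel values average the co-located genes exactly", {
    x <- rbind(g1 = c(0.2, 0.8), g2 = c(0.4, 0.6), g3 = c(1.0, 0.0))
    colnames(x) <- c("sA", "sB")
    co <- toyCohort(x, labels = c("AD", "NC"))
    map <- new("GeneMap", probeIds = rownames(x),
               coords = cbind(c(0, 0, 1), c(0, 0, 1)),
               resolution = c(2L, 2L),
               pixel = cbind(c(1L, 1L, 2L), c(1L, 1L, 2L)),
               rotation = 0, categories = c(1L, 2L, 3L),
               fittedOn = c("sA", "sB"))
    imgs <- renderImages(co, map)
    expect_equal(imgs[["sA"]][1, 1], 0.3)       # mean of 0.2 and 0.4
    expect_equal(imgs[["sA"]][2, 2], 1.0)       # singleton pixel
    expect_equal(imgs[["sA"]][1, 2], 0)         # unoccupied
    expect_equal(imgs[["sB"]][1, 1], 0.7)
    ## conservation: image total equals sum of per-pixel means
    gp <- genesOfPixel(map)
    manual <- sum(vapply(gp, function(idx) mean(x[idx, "sB"]), numeric(1)))
    expect_equal(sum(imgs[["sB"]]), manual, tolerance = 1e-12)

    bad <- toyCohort(x[1:2, ], labels = c("AD", "NC"))
    expect_error(renderImages(bad, map), "mismatch")
})

test_that("fitted maps are deterministic and serialise losslessly", {
    merged <- smallMerged(seed = 19)
    sub <- makePairSubset(merged, "AD_vs_NC")
    sel <- lassoSelect(sub, lambda = 1e-4)
    co <- sub[sel@selected, ]
    m1 <- fitGeneMap(co, K = 5, resolution = c(10, 10))
    m2 <- fitGeneMap(co, K = 5, resolution = c(10, 10))
    expect_identical(m1@pixel, m2@pixel)
    expect_identical(m1@coords, m2@coords)
    expect_identical(fittedOn(m1), colnames(co))

    dir <- withr::local_tempdir()
    p <- file.path(dir, "map.json")
    writeGeneMap(m1, p)
    back <- readGeneMap(p)
    expect_identical(back@pixel, unname(m1@pixel))
    expect_equal(back@coords, m1@coords, ignore_attr = TRUE)
    expect_equal(back@rotation, m1@rotation)
    expect_identical(back@fittedOn, fittedOn(m1))
})

test_that("maps are fitted per task and record their own provenance", {
    merged <- smallMerged(seed = 29, classes = c("AD", "MCI", "NC"),
                          samples_per_class = 12)
    maps <- list()
    for (task in c("AD_vs_NC", "AD_vs_MCI")) {
        sub <- makePairSubset(merged, task)
        sel <- lassoSelect(sub, lambda = 1e-4)
        maps[[task]] <- fitGeneMap(sub[sel@selected, ], K = 5,
                                   resolution = c(10, 10))
    }
    ## different tasks see different sample sets, hence separate provenance
    expect_false(setequal(fittedOn(maps$AD_vs_NC), fittedOn(maps$AD_vs_MCI)))
    expect_false(any(grepl("MCI", diagnosis(makePairSubset(merged, "AD_vs_NC")))))
})
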