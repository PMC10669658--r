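test_that("TSV expression files are read back verbatim", {
    dir <- withr::local_tempdir()
    vals <- matrix(c(1.5, 2, 3, 4, 5, 6), 3, 2,
                   dimnames = list(c("p_b", "p_a", "p_c"), c("s1", "s2")))
    co <- toyCohort(vals, labels = c("AD", "NC"))
    p <- file.path(dir, "m.tsv")
    one2mfusion:::writeExpressionTsv(co, p)
    writeLines("sample_id,label\ns1,AD\ns2,NC", file.path(dir, "lab.csv"))
    back <- readExpression(p, "tsv", labels = file.path(dir, "lab.csv"))
    expect_equal(dim(exprs(back)), c(3L, 2L))
    expect_identical(rownames(back), c("p_b", "p_a", "p_c"))  # file order kept
    expect_equal(exprs(back), vals)
})

test_that("duplicate probe ids are rejected with the offending id named", {
    dir <- withr::local_tempdir()
    writeLines(c("probe_id\ts1\ts2", "pX\t1\t2", "pX\t3\t4", "pY\t5\t6"),
               file.path(dir, "dup.tsv"))
    writeLines("sample_id,label\ns1,AD\ns2,NC", file.path(dir, "lab.csv"))
    expect_error(readExpression(file.path(dir, "dup.tsv"), "tsv",
                                labels = file.path(dir, "lab.csv")),
                 "pX")
})

test_that("missing labels raise a labeling error naming the sample", {
    dir <- withr::local_tempdir()
    writeLines(c("probe_id\ts1\ts2", "pX\t1\t2"), file.path(dir, "m.tsv"))
    writeLines("sample_id,label\ns1,AD", file.path(dir, "lab.csv"))
    expect_error(readExpression(file.path(dir, "m.tsv"), "tsv",
                                labels = file.path(dir, "lab.csv")),
                 "s2")
})

seriesMatrixFixture <- function(path) {
    writeLines(c(
        '!Series_title\t"toy series"',
        '!Sample_geo_accession\t"GSM1"\t"GSM2"\t"GSM3"',
        '!Sample_characteristics_ch1\t"status: AD"\t"status: CTL"\t"status: MCI"',
        '!Sample_characteristics_ch1\t"age: 70"\t"age: 68"\t"age: 72"',
        "!series_matrix_table_begin",
        '"ID_REF"\t"GSM1"\t"GSM2"\t"GSM3"',
        '"p1"\t1.25\t2.5\t3',
        '"p2"\t4\t5\t6.75',
        "!series_matrix_table_end",
        "!ignored_trailer\t0\t0\t0"), path)
}

test_that("series-matrix values come from the table block only", {
    dir <- withr::local_tempdir()
    p <- file.path(dir, "gse.txt")
    seriesMatrixFixture(p)
    co <- readExpression(p, "geo_series_matrix",
                         label_map = c("status: AD" = "AD",
                                       "status: CTL" = "NC",
                                       "status: MCI" = "MCI"))
    expect_equal(exprs(co),
                 matrix(c(1.25, 4, 2.5, 5, 3, 6.75), 2, 3,
                        dimnames = list(c("p1", "p2"),
                                        c("GSM1", "GSM2", "GSM3"))))
    expect_identical(diagnosis(co), c("AD", "NC", "MCI"))
})

test_that("series-matrix parsing fails cleanly without a table block", {
    dir <- withr::local_tempdir()
    writeLines(c("!Series_title\tnope", "p1\t1\t2"), file.path(dir, "bad.txt"))
    expect_error(readExpression(file.path(dir, "bad.txt"), "geo_series_matrix",
                                label_map = c(x = "AD")),
                 "table block")
})

test_that("probe intersection restricts to shared probes in canonical order", {
    a <- toyCohort(matrix(1:6, 3, 2, dimnames = list(c("a", "b", "c"), NULL)),
                   labels = c("AD", "NC"))
    b <- toyCohort(matrix(1:6, 3, 2, dimnames = list(c("d", "c", "b"), NULL)),
                   labels = c("AD", "NC"), dataset = "toy2")
    out <- intersectProbes(list(a, b))
    expect_identical(rownames(out[[1]]), c("b", "c"))
    expect_identical(rownames(out[[2]]), c("b", "c"))
    ## order-independence of the input list
    rev_out <- intersectProbes(list(b, a))
    expect_identical(rownames(rev_out[[1]]), c("b", "c"))
    ## identical probe sets: unchanged up to canonical reordering
    out2 <- intersectProbes(list(a, a))
    expect_identical(rownames(out2[[1]]), c("a", "b", "c"))
    ## disjoint sets fail
    d <- toyCohort(matrix(1:4, 2, 2, dimnames = list(c("x", "y"), NULL)),
                   labels = c("AD", "NC"))
    expect_error(intersectProbes(list(a, d)), "empty")
})

test_that("three datasets sharing exactly 5 of 20 probes intersect to 5 rows", {
    probes <- sprintf("p%02d", 1:20)
    shared <- probes[3:7]
    sets <- list(c(shared, probes[8:12]),
                 c(probes[13:17], shared),
                 c(shared, probes[c(1, 2, 18, 19, 20)]))
    cohorts <- lapply(seq_along(sets), function(i) {
        ids <- sample(sets[[i]])                # scrambled input order
        toyCohort(matrix(rnorm(20), 10, 2, dimnames = list(ids, NULL)),
                  labels = c("AD", "NC"), dataset = paste0("d", i))
    })
    out <- intersectProbes(cohorts)
    for (co in out) expect_identical(rownames(co), sort(shared))
})

test_that("z-score then min-max reproduces hand-computed values", {
    co <- toyCohort(matrix(c(2, 4, 6), 1, 3,
                           dimnames = list("g", c("a", "b", "c"))),
                    labels = c("AD", "NC", "AD"))
    out <- mergeAndNormalize(list(co))
    expect_equal(as.vector(exprs(out)), c(0, 0.5, 1))

    ## constant gene row maps to zero, not NaN
    cc <- toyCohort(matrix(5, 1, 3), labels = c("AD", "NC", "AD"))
    expect_equal(as.vector(exprs(mergeAndNormalize(list(cc)))), c(0, 0, 0))

    ## dataset-level offset removed: [0,1] and [100,101] align exactly
    d1 <- toyCohort(matrix(c(0, 1), 1, 2, dimnames = list("g", c("s1", "s2"))),
                    labels = c("NC", "AD"), dataset = "d1")
    d2 <- toyCohort(matrix(c(100, 101), 1, 2,
                           dimnames = list("g", c("s3", "s4"))),
                    labels = c("NC", "AD"), dataset = "d2")
    out2 <- mergeAndNormalize(list(d1, d2))
    expect_equal(as.vector(exprs(out2)), c(0, 1, 0, 1))
    expect_identical(datasetId(out2), c("d1", "d1", "d2", "d2"))
})

test_that("normalisation output stays in [0,1] and re-scaling is idempotent", {
    set.seed(8)
    for (i in 1:20) {
        g <- sample(2:15, 1); n <- sample(3:12, 1)
        co <- toyCohort(matrix(rnorm(g * n, sd = 10), g, n),
                        labels = sample(c("AD", "NC"), n, replace = TRUE))
        out <- mergeAndNormalize(list(co))
        v <- exprs(out)
        expect_true(all(v >= 0 & v <= 1))
        ## re-applying min-max to its own output changes nothing
        rng <- cbind(apply(v, 1, min), apply(v, 1, max))
        span <- rng[, 2] - rng[, 1]; span[span == 0] <- Inf
        expect_equal((v - rng[, 1]) / span, v, tolerance = 1e-12)
    }
})

test_that("probe-order mismatch is detected at merge time", {
    a <- toyCohort(matrix(1:4, 2, 2, dimnames = list(c("a", "b"), NULL)),
                   labels = c("AD", "NC"))
    b <- toyCohort(matrix(1:4, 2, 2, dimnames = list(c("b", "a"), NULL)),
                   labels = c("AD", "NC"))
    expect_error(mergeAndNormalize(list(a, b)), "intersectProbes")
})

test_that("pairwise subsets code the first-named group as positive", {
    set.seed(1)
    co <- toyCohort(matrix(rnorm(30 * 4), 4, 30),
                    labels = rep(c("AD", "MCI", "NC"), each = 10))
    adnc <- makePairSubset(co, "AD_vs_NC")
    expect_equal(ncol(adnc), 20L)
    expect_equal(sum(response(adnc)), 10L)
    expect_true(all(diagnosis(adnc)[response(adnc) == 1] == "AD"))

    un <- makePairSubset(co, "AD+MCI_vs_NC")
    expect_equal(ncol(un), 30L)
    expect_equal(sum(response(un)), 20L)

    ## sample order preserved
    expect_identical(colnames(adnc),
                     colnames(co)[diagnosis(co) %in% c("AD", "NC")])

    two <- toyCohort(matrix(rnorm(8), 2, 4), labels = rep(c("AD", "NC"), 2))
    expect_error(makePairSubset(two, "AD_vs_MCI"), "MCI")
})
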