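test_that("sample sheet parsing validates columns and types", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("sample_id\tyears_of_play\tage_at_death\tsmoking_history",
                 "a\t0\t80.5\t0", "b\t0\t77\t1", "c\t6\t91.2\t0"), path)
    sheet <- readSampleSheet(path)
    expect_equal(nrow(sheet), 3)
    expect_equal(sum(sheet$exposed), 1)
    expect_type(sheet$years_of_play, "integer")

    writeLines(c("sample_id\tyears_of_play\tage_at_death",
                 "a\t0\t80.5"), path)
    expect_error(readSampleSheet(path), "smoking_history")

    writeLines(c("sample_id\tyears_of_play\tage_at_death\tsmoking_history",
                 "a\t0\t80.5\t0", "b\tsix\t77\t1"), path)
    expect_error(readSampleSheet(path), "row 2")

    writeLines(c("sample_id\tyears_of_play\tage_at_death\tsmoking_history",
                 "a\t0\t80.5\t0", "a\t3\t77\t1"), path)
    expect_error(readSampleSheet(path), "duplicate")
})

test_that("a simulated 89-donor sheet reports the exposed fraction from its counts", {
    cfg <- simConfig(seed = 42)   # defaults: 89 donors, pExposed 0.213
    cohort <- simulateCohort(cfg)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeSampleSheet(cohort, path)
    sheet <- readSampleSheet(path)
    expect_equal(nrow(sheet), 89)
    expect_equal(mean(sheet$exposed), sum(cohort$exposed) / 89)
})

test_that("Bismark coverage rows parse 1-based with counts recomputed", {
    path <- withr::local_tempfile(fileext = ".cov")
    writeLines("chr18\t29265538\t29265538\t75.0\t9\t3", path)
    obs <- readBismarkCov(path)
    expect_equal(obs, data.frame(chrom = "chr18", pos = 29265538L,
                                 meth = 9L, total = 12L))

    writeLines(character(), path)
    expect_equal(nrow(readBismarkCov(path)), 0)

    writeLines(c("chr1\t100\t100\t0\t0\t0"), path)
    expect_equal(readBismarkCov(path)$total, 0L)   # zero-coverage row retained

    writeLines(c("chr1\t100\t100\t50\t1\t1", "chr1\t200\t999\t50\t1\t1"), path)
    expect_error(readBismarkCov(path), "line 2")
    writeLines(c("chr1\t100\t100\t50\t1\t1", "chr1\t200\t200\t50\tx\t1"), path)
    expect_error(readBismarkCov(path), "line 2")
})

test_that("coverage files round-trip through write+read identically", {
    set.seed(7)
    n <- 100
    obs <- data.frame(chrom = "chr3",
                      pos = sort(sample.int(1e6, n)),
                      meth = integer(n), total = rpois(n, 20))
    obs$meth <- rbinom(n, obs$total, 0.4)
    path <- withr::local_tempfile(fileext = ".cov")
    writeBismarkCov(obs, path)
    expect_identical(readBismarkCov(path), obs)
})

test_that("matrix assembly equals the naive nested-loop oracle", {
    obsA <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
                       meth = 1:4, total = 11:14)
    obsB <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 55L),
                       meth = 5:8, total = 15:18)
    me <- assembleMatrix(list(a = obsA, b = obsB))
    expect_equal(nrow(me), 5)
    expect_equal(sum(is.na(methReads(me))), 2)     # one gap in each sample

    single <- assembleMatrix(list(only = obsA))
    expect_equal(unname(methReads(single)[, 1]), obsA$meth)

    expect_error(assembleMatrix(list(a = rbind(obsA, obsA[1, ]))),
                 "duplicate")

    set.seed(11)
    obsList <- lapply(1:10, function(j) {
        pos <- sort(sample.int(500, 50))
        data.frame(chrom = sample(c("chr1", "chr2"), 50, TRUE)[order(pos)],
                   pos = pos, meth = rbinom(50, 20, 0.5),
                   total = rbinom(50, 30, 0.9) + 20L)
    })
    obsList <- lapply(obsList, function(o)
        o[!duplicated(paste0(o$chrom, ":", o$pos)), ])
    names(obsList) <- paste0("s", 1:10)
    me <- assembleMatrix(obsList)
    oracle <- naiveAssemble(obsList)
    expect_equal(siteTable(me)$pos, oracle$pos)
    expect_equal(unname(methReads(me)), oracle$meth)
    expect_equal(unname(totalReads(me)), oracle$total)
})

test_that("BED writing is 0-based half-open and bijective with internal coordinates", {
    dmr <- data.frame(chrom = "chr1", start = 100L, end = 260L,
                      length_bp = 161L, n_cpg = 5L, n_sig = 5L,
                      frac_sig = 1, mean_slope = -0.01, min_p = 1e-10)
    path <- withr::local_tempfile(fileext = ".bed")
    writeBed(dmr, path)
    line <- grep("^[^#]", readLines(path), value = TRUE)
    expect_equal(strsplit(line, "\t")[[1]][2:3], c("99", "260"))

    set.seed(3)
    gr <- GenomicRanges::GRanges(
        sample(c("chr1", "chr2"), 50, TRUE),
        IRanges::IRanges(start = sample.int(1e5, 50), width = sample.int(500, 50)))
    gr <- sort(gr)
    writeBed(gr, path)
    back <- readBedTrack(path)
    expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
    expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
})

test_that("results tables round-trip to full precision", {
    res <- data.frame(chrom = "chr2", pos = c(5L, 9L),
                      slope = c(-1.234567890123e-3, 2e-8),
                      se = c(1e-4, 3.3e-9), t = c(-12.34567890123, 6.1),
                      p = c(5.4321e-30, 4.9e-8), n_used = c(80L, 85L),
                      direction = c("hypo", "hyper"),
                      gw_significant = c(TRUE, TRUE))
    path <- withr::local_tempfile(fileext = ".tsv")
    writeResultsTable(res, path, params = list(alpha_gw = 5e-8))
    back <- readResultsTable(path)
    expect_equal(back$slope, res$slope, tolerance = 1e-12)
    expect_equal(back$p, res$p, tolerance = 1e-12)
    expect_equal(back$gw_significant, res$gw_significant)
    expect_equal(colnames(back)[1:9], colnames(res))

    writeResultsTable(res[0, ], path)
    expect_equal(nrow(readResultsTable(path)), 0)  # header-only file
})
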