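fixtureTrack <- function() {
    genes <- GenomicRanges::GRanges(
        c("chr1", "chr1"),
        IRanges::IRanges(c(10000L, 40000L), c(20000L, 50000L)),
        strand = c("+", "-"), gene = c("GENEA", "GENEB"))
    exons <- GenomicRanges::GRanges(
        c("chr1", "chr1", "chr1"),
        IRanges::IRanges(c(10000L, 15000L, 40000L),
                         c(11000L, 16000L, 42000L)),
        strand = c("+", "+", "-"), gene = c("GENEA", "GENEA", "GENEB"))
    geneTrack(genes, exons)
}

fixtureIslands <- function()
    GenomicRanges::GRanges("chr1", IRanges::IRanges(12000L, 13000L),
                           name = "CGI_1")

test_that("genic categories follow the stated priority and strand rules", {
    gt <- fixtureTrack(); cgi <- fixtureIslands()
    ann <- function(pos) annotateSites(
        data.frame(chrom = "chr1", pos = pos), gt, cgi)

    expect_equal(ann(9500L)$genic_category, "promoter")     # 500 bp upstream, + strand
    expect_equal(ann(7000L)$genic_category, "1to5kb_upstream") # 3 kb upstream
    expect_equal(ann(10500L)$genic_category, "exon")
    expect_equal(ann(13000L)$genic_category, "intron")
    expect_equal(ann(30000L)$genic_category, "intergenic")
    ## - strand gene: TSS at the right end, promoter extends rightward
    expect_equal(ann(50400L)$genic_category, "promoter")
    expect_equal(ann(53000L)$genic_category, "1to5kb_upstream")
    ## signed TSS distance: negative = upstream of the gene
    expect_equal(ann(9500L)$tss_distance, -500L)
    expect_equal(ann(50400L)$tss_distance, -400L)
    expect_equal(ann(10500L)$tss_distance, 500L)
    expect_equal(ann(9500L)$nearest_gene, "GENEA")
})

test_that("CGI axis distances define island, shore, shelf, open sea", {
    gt <- fixtureTrack(); cgi <- fixtureIslands()
    cat4 <- function(pos) annotateSites(
        data.frame(chrom = "chr1", pos = pos), gt, cgi)$cgi_category
    expect_equal(cat4(12500L), "island")      # inside
    expect_equal(cat4(13001L), "shore")       # adjacent to the edge
    expect_equal(cat4(15000L), "shore")       # 2000 bp out (within 2 kb)
    expect_equal(cat4(15001L), "shelf")       # just beyond the shore
    expect_equal(cat4(17000L), "shelf")       # 4 kb out
    expect_equal(cat4(17001L), "open_sea")
    expect_equal(cat4(10001L), "shore")       # left side symmetric
})

test_that("a mirrored gene mirrors its upstream calls", {
    plus <- geneTrack(GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(10000L, 20000L), strand = "+",
        gene = "G"))
    minus <- geneTrack(GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(10000L, 20000L), strand = "-",
        gene = "G"))
    cgi <- GenomicRanges::GRanges()
    upPlus <- annotateSites(data.frame(chrom = "chr1", pos = 9400L),
                            plus, cgi)$genic_category
    upMinus <- annotateSites(data.frame(chrom = "chr1", pos = 20600L),
                             minus, cgi)$genic_category
    expect_equal(upPlus, "promoter")
    expect_equal(upMinus, "promoter")
    ## the + promoter position is plain gene-interior for the - gene
    expect_equal(annotateSites(data.frame(chrom = "chr1", pos = 20600L),
                               plus, cgi)$genic_category, "intergenic")
})

test_that("every site gets exactly one category per axis", {
    sim <- smallSimExperiment(seed = 71, nSites = 300)
    st <- siteTable(sim$me)
    ann <- annotateSites(st, sim$landscape$genes, sim$landscape$islands)
    expect_equal(nrow(ann), nrow(st))
    expect_true(all(ann$genic_category %in%
        c("promoter", "1to5kb_upstream", "exon", "intron", "intergenic")))
    expect_true(all(ann$cgi_category %in%
        c("island", "shore", "shelf", "open_sea")))
    ann$p <- runif(nrow(ann)); ann$degenerate <- FALSE
    summ <- annotationSummary(ann, pCut = 0.5)
    nPass <- sum(ann$p < 0.5)
    expect_equal(sum(summ$n[summ$axis == "genic_category"]), nPass)
    expect_equal(sum(summ$n[summ$axis == "cgi_category"]), nPass)
    expect_equal(sum(summ$pct[summ$axis == "genic_category"]), 100)
})

test_that("annotation summary handles uniform and empty passing sets", {
    ann <- data.frame(genic_category = "intron", cgi_category = "island",
                      p = c(0.01, 0.02), degenerate = FALSE)
    summ <- annotationSummary(ann, 0.05)
    expect_equal(summ$pct[summ$category == "intron"], 100)
    empty <- annotationSummary(transform(ann, p = 0.9), 0.05)
    expect_true(all(empty$n == 0))
})

test_that("DMR gene overlap equals a naive all-pairs oracle", {
    gt <- fixtureTrack()
    dmrs <- data.frame(chrom = "chr1",
                       start = c(13000L, 19500L, 60000L),
                       end = c(14000L, 40500L, 61000L))
    out <- annotateDmr(dmrs, gt)
    expect_equal(out$genes[[1]], "GENEA")           # fully inside GENEA intron
    expect_equal(out$genes[[2]], c("GENEA", "GENEB")) # spans both genes
    expect_equal(out$genes[[3]], character(0))

    set.seed(72)
    genes <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(sample.int(1e5, 20) + 10000L,
                                 width = sample(500:5000, 20)),
        strand = sample(c("+", "-"), 20, TRUE),
        gene = sprintf("G%02d", 1:20))
    gt2 <- geneTrack(genes)
    rdm <- data.frame(chrom = "chr1",
                      start = sample.int(1e5, 30),
                      end = integer(30))
    rdm$end <- rdm$start + sample(100:3000, 30)
    out2 <- annotateDmr(rdm, gt2, promoterBp = 1000L)
    tss <- ifelse(as.character(GenomicRanges::strand(genes)) == "+",
                  GenomicRanges::start(genes), GenomicRanges::end(genes))
    for (q in seq_len(nrow(rdm))) {
        hits <- character()
        for (g in seq_along(genes)) {
            gs <- GenomicRanges::start(genes)[g]
            ge <- GenomicRanges::end(genes)[g]
            ps <- if (as.character(GenomicRanges::strand(genes))[g] == "+")
                c(tss[g] - 1000L, tss[g] - 1L) else c(tss[g] + 1L, tss[g] + 1000L)
            if (max(rdm$start[q], gs) <= min(rdm$end[q], ge) ||
                max(rdm$start[q], ps[1]) <= min(rdm$end[q], ps[2]))
                hits <- c(hits, genes$gene[g])
        }
        expect_equal(out2$genes[[q]], sort(unique(hits)))
    }
})
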