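#' Build a GeneTrack
#'
#' @param genes stranded `GRanges` of gene bodies with a `gene` metadata
#'   column (unique names); the TSS is the 5' end.
#' @param exons `GRanges` of exon intervals with a `gene` column naming
#'   the parent gene.
#' @return A [GeneTrack-class].
#' @export
geneTrack <- function(genes, exons = GenomicRanges::GRanges()) {
    new("GeneTrack", genes = genes, exons = exons)
}

#' Read a gene track from BED files
#'
#' Gene bodies come from a BED6 file (name = gene, strand required);
#' exons, if a path is given, from a second BED6 whose names match genes.
#'
#' @param genesPath,exonsPath file paths.
#' @return A [GeneTrack-class].
#' @export
readGeneTrack <- function(genesPath, exonsPath = NULL) {
    genes <- readBedTrack(genesPath)
    genes$gene <- genes$name; genes$name <- NULL
    exons <- if (is.null(exonsPath)) GenomicRanges::GRanges()
             else {
                 e <- readBedTrack(exonsPath)
                 e$gene <- e$name; e$name <- NULL
                 e
             }
    geneTrack(genes, exons)
}

setMethod("show", "GeneTrack", function(object) {
    cat("GeneTrack:", length(object@genes), "genes,",
        length(object@exons), "exons\n")
    invisible(NULL)
})

.tssPositions <- function(genes) {
    ifelse(as.character(GenomicRanges::strand(genes)) == "+",
           GenomicRanges::start(genes), GenomicRanges::end(genes))
}

## Strand-aware upstream window [distLo, distHi] bp upstream of the TSS
## (1-based inclusive internal coordinates).
.upstreamWindows <- function(genes, distLo, distHi) {
    tss <- .tssPositions(genes)
    plus <- as.character(GenomicRanges::strand(genes)) == "+"
    s <- ifelse(plus, tss - distHi, tss + distLo)
    e <- ifelse(plus, tss - distLo, tss + distHi)
    GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                           IRanges::IRanges(pmax(1, s), pmax(1, e)),
                           gene = genes$gene)
}

#' Annotate CpG sites by genomic and CpG-island context
#'
#' Assigns each site exactly one category per axis. Genic axis, by
#' priority `promoter > 1to5kb_upstream > exon > intron > intergenic`,
#' where the promoter is the 1 kb window immediately upstream of a TSS
#' (strand-aware) and `1to5kb_upstream` the 1-5 kb window beyond it; these
#' widths follow common annotation conventions and are configurable. CGI
#' axis: `island` inside an island; `shore` within `shoreBp` (2 kb) of an
#' island edge; `shelf` in the next `shelfBp` (2 kb, i.e. 2-4 kb from the
#' edge); else `open_sea`. Also reports every overlapping gene (body,
#' promoter or upstream window), the nearest-TSS gene and the signed
#' distance to that TSS (negative = upstream of the gene).
#'
#' @param sites data.frame with `chrom`, `pos` (e.g. [runEwas()] results)
#'   or a width-1 `GRanges`.
#' @param geneTrack a [GeneTrack-class].
#' @param islands `GRanges` of CpG islands.
#' @param promoterBp,upstreamMaxBp,shoreBp,shelfBp window widths in bp.
#' @return The input data.frame with appended columns `genic_category`,
#'   `cgi_category`, `overlapping_genes` (comma-separated, "" if none),
#'   `nearest_gene`, `tss_distance`.
#' @export
annotateSites <- function(sites, geneTrack, islands,
                          promoterBp = 1000L, upstreamMaxBp = 5000L,
                          shoreBp = 2000L, shelfBp = 2000L) {
    df <- if (is(sites, "GRanges"))
        data.frame(chrom = as.character(GenomicRanges::seqnames(sites)),
                   pos = GenomicRanges::start(sites))
    else as.data.frame(sites)
    gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, width = 1L))
    genes <- geneTrack@genes; exons <- geneTrack@exons
    prom <- .upstreamWindows(genes, 1L, promoterBp)
    up5 <- .upstreamWindows(genes, promoterBp + 1L, upstreamMaxBp)
    inProm <- GenomicRanges::countOverlaps(gr, prom, ignore.strand = TRUE) > 0
    inUp5 <- GenomicRanges::countOverlaps(gr, up5, ignore.strand = TRUE) > 0
    inExon <- if (length(exons))
        GenomicRanges::countOverlaps(gr, exons, ignore.strand = TRUE) > 0
    else rep(FALSE, length(gr))
    inGene <- GenomicRanges::countOverlaps(gr, genes, ignore.strand = TRUE) > 0
    df$genic_category <- ifelse(inProm, "promoter",
                         ifelse(inUp5, "1to5kb_upstream",
                         ifelse(inExon, "exon",
                         ifelse(inGene, "intron", "intergenic"))))
    inIsland <- GenomicRanges::countOverlaps(gr, islands,
                                             ignore.strand = TRUE) > 0
    dIsl <- rep(Inf, length(gr))
    if (length(islands)) {
        hit <- GenomicRanges::distanceToNearest(gr, islands,
                                                ignore.strand = TRUE)
        dIsl[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
    }
    df$cgi_category <- ifelse(inIsland, "island",
                       ifelse(dIsl < shoreBp, "shore",
                       ifelse(dIsl < shoreBp + shelfBp, "shelf", "open_sea")))
    ## every gene whose body or upstream windows touch the site
    touch <- c(GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                                      IRanges::ranges(genes),
                                      gene = genes$gene), prom, up5)
    ov <- GenomicRanges::findOverlaps(gr, touch, ignore.strand = TRUE)
    gl <- split(touch$gene[S4Vectors::subjectHits(ov)],
                S4Vectors::queryHits(ov))
    df$overlapping_genes <- ""
    if (length(gl))
        df$overlapping_genes[as.integer(names(gl))] <-
            vapply(gl, function(g) paste(sort(unique(g)), collapse = ","),
                   character(1))
    df$nearest_gene <- NA_character_
    df$tss_distance <- NA_integer_
    if (length(genes)) {
        tss <- .tssPositions(genes)
        plus <- as.character(GenomicRanges::strand(genes)) == "+"
        chromGenes <- as.character(GenomicRanges::seqnames(genes))
        for (q in seq_len(nrow(df))) {
            onChrom <- which(chromGenes == df$chrom[q])
            if (!length(onChrom)) next
            dAbs <- abs(df$pos[q] - tss[onChrom])
            g <- onChrom[which.min(dAbs)]
            df$nearest_gene[q] <- genes$gene[g]
            df$tss_distance[q] <- if (plus[g]) df$pos[q] - tss[g]
                                  else tss[g] - df$pos[q]
        }
    }
    df
}

#' Genes overlapped by a DMR
#'
#' All genes whose body or promoter (strand-aware 1 kb upstream window, as
#' in [annotateSites()]) overlaps the region span; the empty list is
#' allowed.
#'
#' @param dmrs data.frame from [callDmrs()].
#' @param geneTrack a [GeneTrack-class].
#' @param promoterBp promoter width in bp.
#' @return `dmrs` with an appended `genes` list-column of gene names.
#' @export
annotateDmr <- function(dmrs, geneTrack, promoterBp = 1000L) {
    genes <- geneTrack@genes
    dmrs$genes <- replicate(nrow(dmrs), character(0), simplify = FALSE)
    if (!nrow(dmrs) || !length(genes)) return(dmrs)
    gr <- GenomicRanges::GRanges(dmrs$chrom,
                                 IRanges::IRanges(dmrs$start, dmrs$end))
    touch <- c(GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                                      IRanges::ranges(genes),
                                      gene = genes$gene),
               .upstreamWindows(genes, 1L, promoterBp))
    ov <- GenomicRanges::findOverlaps(gr, touch, ignore.strand = TRUE)
    gl <- split(touch$gene[S4Vectors::subjectHits(ov)],
                S4Vectors::queryHits(ov))
    for (k in names(gl))
        dmrs$genes[[as.integer(k)]] <- sort(unique(gl[[k]]))
    dmrs
}

#' Category composition of significant sites
#'
#' Counts and percentages per annotation category (both axes) among sites
#' passing a nominal p cutoff.
#'
#' @param annotated data.frame from [annotateSites()] carrying `p` (and
#'   optionally `degenerate`).
#' @param pCut p-value cutoff (default 0.05).
#' @return data.frame: `axis`, `category`, `n`, `pct`.
#' @export
annotationSummary <- function(annotated, pCut = 0.05) {
    pass <- !is.na(annotated$p) & annotated$p < pCut
    if ("degenerate" %in% colnames(annotated))
        pass <- pass & !annotated$degenerate
    a <- annotated[pass, , drop = FALSE]
    axisTable <- function(axis, cats) {
        n <- vapply(cats, function(cat) sum(a[[axis]] == cat), integer(1))
        data.frame(axis = axis, category = cats, n = n,
                   pct = if (nrow(a)) 100 * n / nrow(a) else 0)
    }
    out <- rbind(
        axisTable("genic_category",
                  c("promoter", "1to5kb_upstream", "exon", "intron",
                    "intergenic")),
        axisTable("cgi_category", c("island", "shore", "shelf", "open_sea")))
    rownames(out) <- NULL
    out
}
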