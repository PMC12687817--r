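#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end strand findOverlaps
#'   countOverlaps distanceToNearest nearest
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowRanges colData assay<- colData<-
NULL

#' MethylExperiment: CpG methylation counts for a cohort
#'
#' An S4 container for reduced representation bisulfite sequencing (RRBS)
#' style CpG methylation counts, extending
#' [SummarizedExperiment::RangedSummarizedExperiment]. Two integer assays,
#' `"meth"` (methylated read count) and `"total"` (total read count), share a
#' sites-by-samples grid; a cell that was not profiled in a sample is `NA` in
#' both assays ("missing"), which is distinct from an observed cell with
#' `total == 0`. Rows are width-1 CpG positions (1-based), sorted by
#' chromosome then position with no duplicates; `colData` carries the sample
#' sheet (exposure and covariates).
#'
#' @seealso [MethylExperiment()] (constructor), [assembleMatrix()],
#'   [filterLowCoverage()], [rawLevels()]
#' @export
setClass("MethylExperiment",
         contains = "RangedSummarizedExperiment")

.validMethylExperiment <- function(object) {
    msg <- character()
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("meth", "total") %in% an))
        return("assays 'meth' and 'total' are required")
    m <- SummarizedExperiment::assay(object, "meth")
    t <- SummarizedExperiment::assay(object, "total")
    if (!identical(dim(m), dim(t)))
        return("'meth' and 'total' assays differ in dimension")
    if (!identical(is.na(m), is.na(t)))
        msg <- c(msg, "missingness pattern differs between 'meth' and 'total'")
    ok <- !is.na(m)
    if (any(m[ok] < 0) || any(t[ok] < 0))
        msg <- c(msg, "negative read counts")
    if (any(m[ok] > t[ok]))
        msg <- c(msg, "meth_reads > total_reads in at least one cell")
    rr <- SummarizedExperiment::rowRanges(object)
    if (length(rr)) {
        if (any(GenomicRanges::width(rr) != 1L))
            msg <- c(msg, "all sites must be width-1 CpG positions")
        chrom <- as.character(GenomicRanges::seqnames(rr))
        pos <- GenomicRanges::start(rr)
        o <- order(chrom, pos)
        if (!identical(o, seq_along(rr)))
            msg <- c(msg, "sites must be sorted by (chrom, pos)")
        if (anyDuplicated(paste0(chrom, ":", pos)))
            msg <- c(msg, "duplicate site positions within a chromosome")
    }
    if (length(msg)) msg else TRUE
}
setValidity("MethylExperiment", .validMethylExperiment)

#' QCReport: tally of quality-control removals
#'
#' Records what the two QC filters removed from a [MethylExperiment]: the
#' number of per-sample observations blanked for low coverage and the number
#' of sites dropped for being profiled in too few samples, together with the
#' thresholds used.
#'
#' @slot nSitesIn integer, sites before filtering.
#' @slot nObsRemovedLowCoverage integer, cells set to missing by the
#'   coverage filter.
#' @slot nSitesRemovedFewSamples integer, sites dropped by the sample-count
#'   filter.
#' @slot nSitesOut integer, sites surviving.
#' @slot minReads,minSamples integer thresholds used.
#'
#' @seealso [filterFewSamples()], [qcReport()]
#' @export
setClass("QCReport",
         representation(nSitesIn = "integer",
                        nObsRemovedLowCoverage = "integer",
                        nSitesRemovedFewSamples = "integer",
                        nSitesOut = "integer",
                        minReads = "integer",
                        minSamples = "integer"))

setValidity("QCReport", function(object) {
    v <- c(object@nSitesIn, object@nObsRemovedLowCoverage,
           object@nSitesRemovedFewSamples, object@nSitesOut)
    if (any(is.na(v)) || any(v < 0L))
        return("all QC counts must be non-negative")
    if (object@nSitesOut > object@nSitesIn)
        return("nSitesOut exceeds nSitesIn")
    TRUE
})

#' SimConfig: parameters of the synthetic RRBS cohort generator
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' discovery cohort conditions: 89 donors of whom about 21.3% were exposed
#' to repetitive head impacts through contact-sports play (years of play
#' uniform integers on 2-19 for exposed donors, 0 otherwise), age at death
#' normal with mean 84 and SD 10.2 truncated at 40, smoking prevalence 0.36.
#' Counts are beta-binomial on negative-binomial coverage; a minority of
#' sites carry a per-year effect on the logit of methylation, 70.7% of them
#' negative (hypomethylation with increasing play).
#'
#' @seealso [simConfig()] for the documented constructor.
#' @export
setClass("SimConfig",
         representation(nSamples = "integer",
                        pExposed = "numeric",
                        yearsRange = "integer",
                        ageMean = "numeric",
                        ageSd = "numeric",
                        ageMin = "numeric",
                        smokingPrev = "numeric",
                        nSites = "integer",
                        nChroms = "integer",
                        meanGapBp = "numeric",
                        fracIslandSites = "numeric",
                        fracEffectSites = "numeric",
                        effectSlopeSd = "numeric",
                        fracNegativeEffects = "numeric",
                        baseShape1 = "numeric",
                        baseShape2 = "numeric",
                        ageEffectSd = "numeric",
                        smokeEffectSd = "numeric",
                        coverageMean = "numeric",
                        coverageDispersion = "numeric",
                        betaBinomialRho = "numeric",
                        missingRate = "numeric",
                        seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    pr <- c(pExposed = object@pExposed, smokingPrev = object@smokingPrev,
            fracIslandSites = object@fracIslandSites,
            fracEffectSites = object@fracEffectSites,
            fracNegativeEffects = object@fracNegativeEffects,
            missingRate = object@missingRate)
    bad <- names(pr)[is.na(pr) | pr < 0 | pr > 1]
    if (length(bad))
        msg <- c(msg, paste0("probabilities outside [0,1]: ",
                             paste(bad, collapse = ", ")))
    if (object@nSamples < 4L)
        msg <- c(msg, "nSamples must be >= 4 (regression degrees of freedom)")
    if (object@betaBinomialRho < 0 || object@betaBinomialRho >= 1)
        msg <- c(msg, "betaBinomialRho must be in [0, 1)")
    if (length(object@yearsRange) != 2L ||
        object@yearsRange[1] < 0L ||
        object@yearsRange[2] < object@yearsRange[1])
        msg <- c(msg, "yearsRange must be an increasing non-negative pair")
    if (object@nChroms < 1L) msg <- c(msg, "nChroms must be >= 1")
    if (object@meanGapBp < 1) msg <- c(msg, "meanGapBp must be >= 1")
    if (object@coverageMean <= 0 || object@coverageDispersion <= 0)
        msg <- c(msg, "coverage parameters must be positive")
    if (object@effectSlopeSd < 0)
        msg <- c(msg, "effectSlopeSd must be non-negative")
    if (length(msg)) msg else TRUE
})

#' GeneTrack: gene models for genomic-context annotation
#'
#' Holds stranded gene bodies and their exon intervals (both as
#' [GenomicRanges::GRanges], 1-based inclusive). The transcription start
#' site of each gene is its 5' end (`start` on `+`, `end` on `-`); one TSS
#' per gene model -- isoform handling is the track-builder's concern.
#'
#' @slot genes GRanges with a `gene` metadata column and `+`/`-` strand.
#' @slot exons GRanges with a `gene` metadata column naming the parent gene.
#'
#' @seealso [geneTrack()], [annotateSites()]
#' @export
setClass("GeneTrack",
         representation(genes = "GRanges", exons = "GRanges"))

setValidity("GeneTrack", function(object) {
    msg <- character()
    if (is.null(object@genes$gene) || anyNA(object@genes$gene))
        msg <- c(msg, "genes must carry a 'gene' metadata column")
    else if (anyDuplicated(object@genes$gene))
        msg <- c(msg, "gene names must be unique")
    if (!all(as.character(GenomicRanges::strand(object@genes)) %in% c("+", "-")))
        msg <- c(msg, "gene strand must be '+' or '-'")
    if (length(object@exons)) {
        if (is.null(object@exons$gene) ||
            !all(object@exons$gene %in% object@genes$gene))
            msg <- c(msg, "every exon must name a gene present in the track")
    }
    if (length(msg)) msg else TRUE
})
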