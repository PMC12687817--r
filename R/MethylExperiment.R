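#' Construct a MethylExperiment
#'
#' Builds the central sites-by-samples container from methylated and total
#' read-count matrices. Sites are given either as a `GRanges` of width-1
#' positions or as a data.frame with `chrom` and `pos` (1-based) columns;
#' rows are re-sorted by (chrom, pos) if needed. A cell that was not
#' profiled is `NA` in both matrices; `NA` must occur in both or neither.
#'
#' @param meth,total integer matrices, sites x samples; `meth[i,j] <=
#'   total[i,j]` cellwise.
#' @param sites `GRanges` (width 1) or data.frame with columns `chrom`,
#'   `pos`.
#' @param sampleData data.frame or `DataFrame` of per-sample covariates
#'   (e.g. a sample sheet read by [readSampleSheet()]); rownames or a
#'   `sample_id` column give the sample names.
#'
#' @return A [MethylExperiment-class] object.
#' @examples
#' me <- MethylExperiment(
#'     meth  = matrix(c(3L, 5L, 0L, 9L), 2),
#'     total = matrix(c(10L, 12L, 11L, 12L), 2),
#'     sites = data.frame(chrom = "chr1", pos = c(100L, 250L)),
#'     sampleData = data.frame(sample_id = c("a", "b")))
#' methReads(me)
#' @export
MethylExperiment <- function(meth, total, sites, sampleData = NULL) {
    meth <- as.matrix(meth); total <- as.matrix(total)
    storage.mode(meth) <- "integer"; storage.mode(total) <- "integer"
    rr <- .asSiteRanges(sites)
    if (length(rr) != nrow(meth))
        stop("number of sites (", length(rr), ") does not match nrow(meth) (",
             nrow(meth), ")")
    o <- order(as.character(GenomicRanges::seqnames(rr)),
               GenomicRanges::start(rr))
    rr <- rr[o]; meth <- meth[o, , drop = FALSE]; total <- total[o, , drop = FALSE]
    if (is.null(sampleData))
        sampleData <- S4Vectors::DataFrame(row.names = .sampleNames(meth))
    else {
        sampleData <- S4Vectors::DataFrame(sampleData)
        if ("sample_id" %in% colnames(sampleData))
            rownames(sampleData) <- sampleData$sample_id
    }
    colnames(meth) <- colnames(total) <- rownames(sampleData)
    rownames(meth) <- rownames(total) <- .siteKeys(rr)
    names(rr) <- rownames(meth)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(meth = meth, total = total),
        rowRanges = rr, colData = sampleData)
    new("MethylExperiment", se)
}

.asSiteRanges <- function(sites) {
    if (is(sites, "GRanges")) {
        if (any(GenomicRanges::width(sites) != 1L))
            stop("site ranges must have width 1")
        return(sites)
    }
    if (!all(c("chrom", "pos") %in% colnames(sites)))
        stop("'sites' needs columns 'chrom' and 'pos'")
    if (any(sites$pos < 1L)) stop("positions are 1-based and must be >= 1")
    GenomicRanges::GRanges(sites$chrom,
                           IRanges::IRanges(sites$pos, width = 1L))
}

.siteKeys <- function(rr)
    paste0(as.character(GenomicRanges::seqnames(rr)), ":",
           GenomicRanges::start(rr))

.sampleNames <- function(m) {
    if (!is.null(colnames(m))) colnames(m)
    else sprintf("S%03d", seq_len(ncol(m)))
}

#' Count and level accessors
#'
#' `methReads()` and `totalReads()` return the integer count assays
#' (`NA` = unprofiled cell). `methLevels()` returns the `"level"` assay
#' written by [rawLevels()] or [smoothLevels()] (error if absent).
#' `siteTable()` returns the site coordinates as a data.frame with `chrom`
#' and `pos` (1-based).
#'
#' @param object a [MethylExperiment-class].
#' @return matrices (counts/levels) or a data.frame (`siteTable`).
#' @aliases methReads totalReads methLevels siteTable
#' @export
setMethod("methReads", "MethylExperiment", function(object)
    SummarizedExperiment::assay(object, "meth"))

#' @rdname methReads
#' @export
setMethod("totalReads", "MethylExperiment", function(object)
    SummarizedExperiment::assay(object, "total"))

#' @rdname methReads
#' @export
setMethod("methLevels", "MethylExperiment", function(object) {
    if (!"level" %in% SummarizedExperiment::assayNames(object))
        stop("no 'level' assay; run rawLevels() or smoothLevels() first")
    SummarizedExperiment::assay(object, "level")
})

#' @rdname methReads
#' @export
setMethod("siteTable", "MethylExperiment", function(object) {
    rr <- SummarizedExperiment::rowRanges(object)
    data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
               pos = GenomicRanges::start(rr))
})

setMethod("show", "MethylExperiment", function(object) {
    cat("MethylExperiment:", nrow(object), "CpG sites x", ncol(object),
        "samples\n")
    m <- SummarizedExperiment::assay(object, "total")
    cat("  missing cells:", sum(is.na(m)), "of", length(m), "\n")
    cat("  assays:", paste(SummarizedExperiment::assayNames(object),
                           collapse = ", "), "\n")
    qc <- S4Vectors::metadata(object)$qcReport
    if (!is.null(qc)) cat("  QC applied: yes\n")
    invisible(NULL)
})

setMethod("show", "QCReport", function(object) {
    cat("QCReport (minReads =", object@minReads,
        ", minSamples =", object@minSamples, ")\n")
    cat("  sites in:                    ", object@nSitesIn, "\n")
    cat("  low-coverage cells removed:  ", object@nObsRemovedLowCoverage, "\n")
    cat("  sites dropped (few samples): ", object@nSitesRemovedFewSamples, "\n")
    cat("  sites out:                   ", object@nSitesOut, "\n")
    invisible(NULL)
})

#' Serialize a QCReport
#'
#' @param report a [QCReport-class].
#' @return A named list suitable for JSON/YAML serialization.
#' @export
qcReportAsList <- function(report) {
    stopifnot(is(report, "QCReport"))
    list(n_sites_in = report@nSitesIn,
         n_obs_removed_low_coverage = report@nObsRemovedLowCoverage,
         n_sites_removed_few_samples = report@nSitesRemovedFewSamples,
         n_sites_out = report@nSitesOut,
         min_reads = report@minReads,
         min_samples = report@minSamples)
}
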