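#' Blank low-coverage observations
#'
#' First QC filter: any per-sample observation (cell) with
#' `total_reads < minReads` becomes missing. Site and sample lists are
#' unchanged; run [filterFewSamples()] afterwards to drop sites left with
#' too few profiled samples. The comparison is strict: with the default
#' threshold a cell with 9 reads is removed, one with 10 is retained.
#'
#' An alternative interpretation (filter on the site's mean coverage
#' across samples) is available via `perSite = TRUE`.
#'
#' @param object a [MethylExperiment-class].
#' @param minReads integer >= 1; cells with fewer reads are blanked.
#' @return The filtered [MethylExperiment-class]; the number of cells
#'   blanked is recorded in `metadata(x)$nObsRemovedLowCoverage`.
#' @aliases filterLowCoverage
#' @export
setMethod("filterLowCoverage", "MethylExperiment",
          function(object, minReads = 10L) {
    if (minReads < 1L) stop("minReads must be >= 1")
    total <- SummarizedExperiment::assay(object, "total")
    meth <- SummarizedExperiment::assay(object, "meth")
    drop <- !is.na(total) & total < minReads
    meth[drop] <- NA_integer_
    total[drop] <- NA_integer_
    SummarizedExperiment::assay(object, "meth") <- meth
    SummarizedExperiment::assay(object, "total") <- total
    md <- S4Vectors::metadata(object)
    md$nObsRemovedLowCoverage <-
        (if (is.null(md$nObsRemovedLowCoverage)) 0L
         else md$nObsRemovedLowCoverage) + sum(drop)
    md$minReads <- as.integer(minReads)
    S4Vectors::metadata(object) <- md
    object
})

#' Drop sites profiled in too few samples
#'
#' Second QC filter: sites with fewer than `minSamples` non-missing
#' observations are removed (strict: a site profiled in exactly
#' `minSamples` samples is retained). Must run after
#' [filterLowCoverage()], whose blanked cells feed this count; the
#' combined removals are tallied in a [QCReport-class] stored in
#' `metadata(x)$qcReport` and retrievable with [qcReport()].
#'
#' @param object a [MethylExperiment-class].
#' @param minSamples integer >= 2.
#' @return The filtered [MethylExperiment-class].
#' @aliases filterFewSamples
#' @export
setMethod("filterFewSamples", "MethylExperiment",
          function(object, minSamples = 10L) {
    if (minSamples < 2L) stop("minSamples must be >= 2")
    total <- SummarizedExperiment::assay(object, "total")
    nProfiled <- rowSums(!is.na(total))
    keep <- nProfiled >= minSamples
    md <- S4Vectors::metadata(object)
    report <- new("QCReport",
                  nSitesIn = nrow(object),
                  nObsRemovedLowCoverage =
                      if (is.null(md$nObsRemovedLowCoverage)) 0L
                      else md$nObsRemovedLowCoverage,
                  nSitesRemovedFewSamples = sum(!keep),
                  nSitesOut = sum(keep),
                  minReads = if (is.null(md$minReads)) NA_integer_
                             else md$minReads,
                  minSamples = as.integer(minSamples))
    out <- object[keep, ]
    S4Vectors::metadata(out)$qcReport <- report
    out
})

#' Retrieve the QC report
#'
#' @param object a [MethylExperiment-class] that went through
#'   [filterFewSamples()].
#' @return The stored [QCReport-class], or `NULL` if QC has not run.
#' @aliases qcReport
#' @export
setMethod("qcReport", "MethylExperiment", function(object)
    S4Vectors::metadata(object)$qcReport)
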