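#' Raw per-cell methylation levels
#'
#' The passthrough estimator: `level = meth_reads / total_reads` per cell,
#' with missing cells propagated. Cells with `total_reads == 0` should
#' have been blanked by QC and raise an error here.
#'
#' @param object a [MethylExperiment-class] (QC applied).
#' @return The object with an added `"level"` assay in `[0, 1]`.
#' @aliases rawLevels
#' @export
setMethod("rawLevels", "MethylExperiment", function(object) {
    meth <- SummarizedExperiment::assay(object, "meth")
    total <- SummarizedExperiment::assay(object, "total")
    if (any(!is.na(total) & total == 0L))
        stop("non-missing cell with total_reads == 0; run filterLowCoverage()")
    lev <- meth / total
    SummarizedExperiment::assay(object, "level", withDimnames = FALSE) <- lev
    S4Vectors::metadata(object)$levelMethod <- "raw"
    object
})

#' Locally smoothed methylation levels
#'
#' A kernel-weighted coverage-ratio estimator in the spirit of local
#' smoothing of bisulfite data: for each sample and site, the level is
#' `sum(w_k * meth_k) / sum(w_k * total_k)` over neighbouring CpGs on the
#' same chromosome, with tricube weights `w_k = (1 - (d_k / h)^3)^3` in
#' distance `d_k` from the focal site. The half-width `h` is
#' `windowBp / 2`, widened where necessary so that at least `minSites`
#' sites fall in the window (capped at the sites available in the local
#' block); windows never cross chromosome boundaries and additionally
#' break at inter-CpG gaps larger than `maxGapBp`, so strength is never
#' borrowed across unsequenced deserts. Missing neighbours are excluded;
#' a missing focal cell stays missing. This is a deliberately simplified
#' local estimator, not a reimplementation of any published smoother: it
#' preserves coverage weighting, locality and the `[0, 1]` range with far
#' less machinery.
#'
#' @param object a [MethylExperiment-class] with sorted sites (QC applied).
#' @param windowBp window width in bp (default 1000).
#' @param minSites minimum number of CpGs per window (default 70); capped
#'   at the block size in small datasets.
#' @param maxGapBp gap above which smoothing blocks are split
#'   (default 10000).
#' @return The object with a smoothed `"level"` assay.
#' @aliases smoothLevels
#' @export
setMethod("smoothLevels", "MethylExperiment",
          function(object, windowBp = 1000L, minSites = 70L,
                   maxGapBp = 10000L) {
    if (windowBp < 1L) stop("windowBp must be >= 1")
    if (minSites < 1L) stop("minSites must be >= 1")
    st <- siteTable(object)
    if (is.unsorted(order(st$chrom, st$pos)))
        stop("sites must be sorted")      # enforced by the class; belt and braces
    meth <- SummarizedExperiment::assay(object, "meth")
    total <- SummarizedExperiment::assay(object, "total")
    if (any(!is.na(total) & total == 0L))
        stop("non-missing cell with total_reads == 0; run filterLowCoverage()")
    lev <- matrix(NA_real_, nrow(object), ncol(object))
    blocks <- .smoothBlocks(st$chrom, st$pos, maxGapBp)
    h0 <- windowBp / 2
    for (b in blocks) {
        p <- st$pos[b]
        m <- length(b)
        k <- min(minSites, m)
        for (ii in seq_len(m)) {
            d <- abs(p - p[ii])
            h <- max(h0, sort(d, partial = k)[k])
            inWin <- which(d <= h)
            w <- (1 - (d[inWin] / (h + 1))^3)^3
            rows <- b[inWin]
            num <- colSums(w * meth[rows, , drop = FALSE], na.rm = TRUE)
            den <- colSums(w * total[rows, , drop = FALSE], na.rm = TRUE)
            v <- ifelse(den > 0, num / den, NA_real_)
            lev[b[ii], ] <- v
        }
    }
    lev[is.na(total)] <- NA_real_         # focal missing stays missing
    SummarizedExperiment::assay(object, "level", withDimnames = FALSE) <- lev
    S4Vectors::metadata(object)$levelMethod <- "smoothed"
    S4Vectors::metadata(object)$smoothing <-
        list(window_bp = windowBp, min_sites = minSites,
             max_gap_bp = maxGapBp, kernel = "tricube")
    object
})

## Split sorted sites into smoothing blocks: per chromosome, breaking at
## gaps > maxGapBp. Returns a list of integer row-index vectors.
.smoothBlocks <- function(chrom, pos, maxGapBp) {
    idx <- seq_along(pos)
    newBlock <- c(TRUE, chrom[-1] != chrom[-length(chrom)] |
                        diff(pos) > maxGapBp)
    split(idx, cumsum(newBlock))
}
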