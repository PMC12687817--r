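## A differentially methylated region (DMR) qualifies when, on its trimmed
## span (1-based inclusive, ends coinciding with significant member CpGs):
##   length_bp = end - start + 1 >= minLen        (>= 100 bp)
##   n_sig >= minSig                              (>= 3 significant CpGs)
##   n_sig / n_cpg > minFrac (strict)             (> 80% of CpGs in the span)
## with all inter-CpG gaps inside the span <= maxGap. The qualifying-
## interval set is reduced to maximal intervals and remaining overlaps are
## resolved preferring higher n_sig, then greater length, then leftmost
## start.

.dmrPrep <- function(results, sigThreshold) {
    keep <- !is.na(results$p) &
        (if ("degenerate" %in% colnames(results)) !results$degenerate else TRUE)
    r <- results[keep, , drop = FALSE]
    o <- order(r$chrom, r$pos)
    if (!identical(o, seq_len(nrow(r)))) stop("results must be sorted by (chrom, pos)")
    r$sig <- r$p < sigThreshold
    r
}

.dmrRecord <- function(chrom, pos, slope, p, i, j) {
    span <- seq.int(i, j)
    data.frame(chrom = chrom, start = pos[i], end = pos[j],
               length_bp = pos[j] - pos[i] + 1L,
               n_cpg = length(span),
               n_sig = NA_integer_,       # filled by caller
               frac_sig = NA_real_,
               mean_slope = mean(slope[span]),
               min_p = min(p[span]))
}

#' Call differentially methylated regions
#'
#' Finds, per chromosome, every maximal run of CpGs that satisfies the
#' three region criteria (minimum length, minimum count of significant
#' CpGs, strict minimum fraction of significant CpGs), with region ends
#' trimmed to significant CpGs and inter-CpG gaps capped at `maxGap`.
#' Candidate intervals are scanned within gap-delimited blocks using
#' significant endpoints and prefix sums; qualifying intervals contained
#' in a larger qualifying interval are removed, and remaining overlaps are
#' resolved preferring higher `n_sig`, then greater length, then leftmost
#' start, so emitted regions are disjoint. Every emitted region is
#' re-checked against the criteria by an assertion independent of the
#' construction path.
#'
#' @param results data.frame from [runEwas()], sorted by (chrom, pos);
#'   degenerate sites are excluded before calling.
#' @param sigThreshold p-value threshold defining a "significant" member
#'   CpG (default the genome-wide 5e-8).
#' @param minLen minimum region length in bp, inclusive (default 100).
#' @param minSig minimum number of significant CpGs (default 3).
#' @param minFrac strict lower bound on the significant fraction
#'   (default 0.8: a region at exactly 80% is rejected).
#' @param maxGap maximum inter-CpG gap inside a region, bp (default 250).
#' @return data.frame of regions: `chrom`, `start`, `end`, `length_bp`,
#'   `n_cpg`, `n_sig`, `frac_sig`, `mean_slope`, `min_p`, plus a
#'   `members` list-column of member positions.
#' @seealso [bruteForceDmrs()] for the exhaustive verification oracle.
#' @export
callDmrs <- function(results, sigThreshold = 5e-8, minLen = 100L,
                     minSig = 3L, minFrac = 0.8, maxGap = 250L) {
    if (minFrac <= 0 || minFrac > 1) stop("minFrac must be in (0, 1]")
    r <- .dmrPrep(results, sigThreshold)
    out <- list()
    for (cn in unique(r$chrom)) {
        rc <- r[r$chrom == cn, , drop = FALSE]
        pos <- rc$pos; sig <- rc$sig
        blockId <- cumsum(c(TRUE, diff(pos) > maxGap))
        for (bl in split(seq_along(pos), blockId)) {
            sigIdx <- bl[sig[bl]]
            if (length(sigIdx) < minSig) next
            cs <- cumsum(sig)            # prefix sums over the chromosome
            cand <- list()
            for (a in seq_along(sigIdx)) for (b in seq.int(a, length(sigIdx))) {
                i <- sigIdx[a]; j <- sigIdx[b]
                nSig <- cs[j] - (if (i > 1L) cs[i - 1L] else 0L)
                nCpg <- j - i + 1L
                if (pos[j] - pos[i] + 1L < minLen) next
                if (nSig < minSig) next
                if (nSig / nCpg <= minFrac) next
                cand[[length(cand) + 1L]] <- c(i, j, nSig)
            }
            if (!length(cand)) next
            cm <- do.call(rbind, cand)
            ## maximality: drop intervals contained in another qualifying one
            keep <- vapply(seq_len(nrow(cm)), function(q) {
                !any(cm[, 1] <= cm[q, 1] & cm[, 2] >= cm[q, 2] &
                     (cm[, 1] != cm[q, 1] | cm[, 2] != cm[q, 2]))
            }, logical(1))
            cm <- cm[keep, , drop = FALSE]
            ## overlap resolution: n_sig desc, length desc, start asc
            lens <- pos[cm[, 2]] - pos[cm[, 1]] + 1L
            ord <- order(-cm[, 3], -lens, pos[cm[, 1]])
            taken <- logical(length(pos))
            for (q in ord) {
                span <- seq.int(cm[q, 1], cm[q, 2])
                if (any(taken[span])) next
                taken[span] <- TRUE
                rec <- .dmrRecord(cn, pos, rc$slope, rc$p, cm[q, 1], cm[q, 2])
                rec$n_sig <- cm[q, 3]
                rec$frac_sig <- cm[q, 3] / rec$n_cpg
                rec$members <- I(list(pos[span]))
                out[[length(out) + 1L]] <- rec
            }
        }
    }
    dmrs <- if (length(out)) do.call(rbind, out) else .emptyDmrFrame()
    dmrs <- dmrs[order(dmrs$chrom, dmrs$start), , drop = FALSE]
    rownames(dmrs) <- NULL
    .assertDmrCriteria(dmrs, minLen, minSig, minFrac)
    dmrs
}

.emptyDmrFrame <- function()
    data.frame(chrom = character(), start = integer(), end = integer(),
               length_bp = integer(), n_cpg = integer(), n_sig = integer(),
               frac_sig = numeric(), mean_slope = numeric(),
               min_p = numeric(), members = I(list()))

## Post-hoc soundness check, independent of how regions were built.
.assertDmrCriteria <- function(dmrs, minLen, minSig, minFrac) {
    if (!nrow(dmrs)) return(invisible(TRUE))
    stopifnot(all(dmrs$length_bp >= minLen),
              all(dmrs$n_sig >= minSig),
              all(dmrs$frac_sig > minFrac),
              all(dmrs$end - dmrs$start + 1L == dmrs$length_bp))
    invisible(TRUE)
}

#' Exhaustive DMR search (verification oracle)
#'
#' Enumerates every contiguous CpG interval, trims its ends to significant
#' CpGs, keeps intervals meeting all region criteria and the gap
#' constraint (checked by direct scanning, no prefix sums), reduces to
#' maximal intervals and resolves overlaps with the same preference order
#' as [callDmrs()]. Written naively and independently so the two paths can
#' be compared region-for-region; refuses instances above `maxSites`
#' because it is quadratic-to-cubic and meant for tests.
#'
#' @inheritParams callDmrs
#' @param maxSites guard on instance size (default 300).
#' @return Same shape as [callDmrs()].
#' @export
bruteForceDmrs <- function(results, sigThreshold = 5e-8, minLen = 100L,
                           minSig = 3L, minFrac = 0.8, maxGap = 250L,
                           maxSites = 300L) {
    if (nrow(results) > maxSites)
        stop("instance too large for the brute-force oracle (",
             nrow(results), " > ", maxSites, " sites)")
    r <- .dmrPrep(results, sigThreshold)
    out <- list()
    for (cn in unique(r$chrom)) {
        rc <- r[r$chrom == cn, , drop = FALSE]
        pos <- rc$pos; sig <- rc$sig
        m <- length(pos)
        seen <- matrix(FALSE, m, m)
        cand <- list()
        for (i0 in seq_len(m)) for (j0 in seq.int(i0, m)) {
            i <- i0; j <- j0
            while (i <= j && !sig[i]) i <- i + 1L      # trim to significant ends
            while (j >= i && !sig[j]) j <- j - 1L
            if (i > j) next
            if (seen[i, j]) next
            seen[i, j] <- TRUE
            ok <- TRUE
            if (j > i) for (q in seq.int(i + 1L, j))   # gap constraint, scanned
                if (pos[q] - pos[q - 1L] > maxGap) { ok <- FALSE; break }
            if (!ok) next
            nSig <- 0L
            for (q in seq.int(i, j)) if (sig[q]) nSig <- nSig + 1L
            nCpg <- j - i + 1L
            if (pos[j] - pos[i] + 1L >= minLen && nSig >= minSig &&
                nSig / nCpg > minFrac)
                cand[[length(cand) + 1L]] <- c(i, j, nSig)
        }
        if (!length(cand)) next
        cm <- unique(do.call(rbind, cand))
        keep <- rep(TRUE, nrow(cm))
        for (q1 in seq_len(nrow(cm))) for (q2 in seq_len(nrow(cm)))
            if (q1 != q2 && cm[q2, 1] <= cm[q1, 1] && cm[q2, 2] >= cm[q1, 2] &&
                !(cm[q2, 1] == cm[q1, 1] && cm[q2, 2] == cm[q1, 2]))
                keep[q1] <- FALSE
        cm <- cm[keep, , drop = FALSE]
        lens <- pos[cm[, 2]] - pos[cm[, 1]] + 1L
        ord <- order(-cm[, 3], -lens, pos[cm[, 1]])
        taken <- logical(m)
        for (q in ord) {
            span <- seq.int(cm[q, 1], cm[q, 2])
            if (any(taken[span])) next
            taken[span] <- TRUE
            rec <- .dmrRecord(cn, pos, rc$slope, rc$p, cm[q, 1], cm[q, 2])
            rec$n_sig <- cm[q, 3]
            rec$frac_sig <- cm[q, 3] / rec$n_cpg
            rec$members <- I(list(pos[span]))
            out[[length(out) + 1L]] <- rec
        }
    }
    dmrs <- if (length(out)) do.call(rbind, out) else .emptyDmrFrame()
    dmrs <- dmrs[order(dmrs$chrom, dmrs$start), , drop = FALSE]
    rownames(dmrs) <- NULL
    dmrs
}
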