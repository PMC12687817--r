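## On-disk conventions, stated once and asserted in tests:
##  - internal coordinates are 1-based inclusive;
##  - BED files are 0-based half-open (start = pos - 1, end = pos);
##  - Bismark ".cov" files are 1-based with start == end;
##  - every writer emits "#"-prefixed provenance header lines, every reader
##    skips them.

.headerLines <- function(params = NULL) {
    h <- paste0("# methdose ",
                as.character(utils::packageVersion("methdose")))
    if (length(params))
        h <- c(h, paste0("# ", names(params), "=",
                         vapply(params, function(x)
                             paste(format(x, digits = 15), collapse = ","),
                             character(1))))
    h
}

.fmtNum <- function(x) {
    out <- vapply(x, function(v) {
        if (is.na(v)) "NA" else formatC(v, digits = 15, format = "g")
    }, character(1))
    out
}

#' Read a sample sheet
#'
#' Reads a delimiter-separated sample sheet with one row per donor. The
#' header must name at least `sample_id`, `years_of_play`, `age_at_death`
#' and `smoking_history`; any further numeric columns are kept as extra
#' covariates. `years_of_play` is the exposure (concurrent years of
#' contact-sports play, 0 for unexposed donors); `exposed` is derived as
#' `years_of_play > 0`.
#'
#' @param path file path.
#' @param sep field delimiter (default tab).
#' @return data.frame with validated types and a logical `exposed` column.
#' @export
readSampleSheet <- function(path, sep = "\t") {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            comment.char = "#", stringsAsFactors = FALSE,
                            check.names = FALSE)
    req <- c("sample_id", "years_of_play", "age_at_death", "smoking_history")
    miss <- setdiff(req, colnames(df))
    if (length(miss))
        stop("sample sheet is missing required column(s): ",
             paste(miss, collapse = ", "))
    df$sample_id <- as.character(df$sample_id)
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample_id in sample sheet: ",
             df$sample_id[duplicated(df$sample_id)][1])
    for (col in c("years_of_play", "age_at_death", "smoking_history")) {
        v <- suppressWarnings(as.numeric(df[[col]]))
        bad <- which(is.na(v) & !is.na(df[[col]]))
        if (length(bad))
            stop("non-numeric value in column '", col, "' at data row ",
                 bad[1])
        df[[col]] <- v
    }
    if (any(df$years_of_play < 0)) stop("years_of_play must be >= 0")
    if (!all(df$smoking_history %in% c(0, 1)))
        stop("smoking_history must be binary 0/1")
    df$years_of_play <- as.integer(df$years_of_play)
    df$smoking_history <- as.integer(df$smoking_history)
    df$exposed <- df$years_of_play > 0L
    df
}

#' Write a sample sheet
#'
#' @param samples data.frame as returned by [readSampleSheet()] or
#'   [simulateCohort()].
#' @param path output path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
writeSampleSheet <- function(samples, path, sep = "\t") {
    df <- samples[, setdiff(colnames(samples), "exposed"), drop = FALSE]
    con <- file(path, "w"); on.exit(close(con))
    writeLines(.headerLines(), con)
    utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a Bismark-style coverage file
#'
#' Reads the de facto RRBS interchange format (Bismark `.cov`): one row per
#' CpG with `chrom start end percent meth_count unmeth_count`, 1-based with
#' `start == end`. The percent column is ignored and recomputed from counts
#' downstream. Rows with `meth + unmeth == 0` are retained with
#' `total_reads = 0` (they become missing at QC).
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `pos`, `meth`, `total`.
#' @export
readBismarkCov <- function(path) {
    lines <- readLines(path)
    keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
    if (!any(keep))
        return(data.frame(chrom = character(), pos = integer(),
                          meth = integer(), total = integer()))
    idx <- which(keep)
    parts <- strsplit(trimws(lines[idx]), "[ \t]+")
    nf <- lengths(parts)
    if (any(nf != 6L))
        stop("malformed coverage row at line ", idx[which(nf != 6L)[1]],
             ": expected 6 fields")
    m <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
    num <- suppressWarnings(apply(m[, c(2, 3, 5, 6), drop = FALSE], 2,
                                  as.numeric))
    num <- matrix(num, ncol = 4L)
    badRow <- which(apply(num, 1, anyNA))
    if (length(badRow))
        stop("malformed coverage row at line ", idx[badRow[1]],
             ": non-numeric field")
    if (any(num[, 1] != num[, 2]))
        stop("coverage rows must have start == end (1-based .cov dialect); ",
             "first offender at line ", idx[which(num[, 1] != num[, 2])[1]])
    if (any(num[, 1] < 1))
        stop("positions are 1-based and must be >= 1")
    data.frame(chrom = m[, 1], pos = as.integer(num[, 1]),
               meth = as.integer(num[, 3]),
               total = as.integer(num[, 3] + num[, 4]))
}

#' Write a Bismark-style coverage file
#'
#' @param obs data.frame with columns `chrom`, `pos`, `meth`, `total`
#'   (missing cells must be dropped beforehand).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBismarkCov <- function(obs, path) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(.headerLines(), con)
    if (nrow(obs)) {
        unmeth <- obs$total - obs$meth
        pct <- ifelse(obs$total > 0, 100 * obs$meth / obs$total, 0)
        writeLines(paste(obs$chrom, obs$pos, obs$pos,
                         formatC(pct, digits = 10, format = "g"),
                         obs$meth, unmeth, sep = "\t"), con)
    }
    invisible(path)
}

#' Assemble per-sample observations into a MethylExperiment
#'
#' Takes one observation table per sample (as from [readBismarkCov()]) and
#' builds the union-of-sites count matrix; cells absent in a sample are
#' missing (`NA`).
#'
#' @param obsList named list of data.frames (`chrom`, `pos`, `meth`,
#'   `total`), one per sample; names are sample ids.
#' @param sampleData optional data.frame of per-sample covariates with a
#'   `sample_id` column matching `names(obsList)`.
#' @return A [MethylExperiment-class].
#' @export
assembleMatrix <- function(obsList, sampleData = NULL) {
    if (is.null(names(obsList)) || any(!nzchar(names(obsList))))
        stop("'obsList' must be a named list (sample ids)")
    for (id in names(obsList)) {
        o <- obsList[[id]]
        if (anyDuplicated(paste0(o$chrom, ":", o$pos)))
            stop("duplicate position within sample '", id, "'")
    }
    allKeys <- unique(unlist(lapply(obsList, function(o)
        paste0(o$chrom, ":", o$pos)), use.names = FALSE))
    allChrom <- sub(":.*$", "", allKeys)
    allPos <- as.integer(sub("^.*:", "", allKeys))
    o <- order(allChrom, allPos)
    allKeys <- allKeys[o]; allChrom <- allChrom[o]; allPos <- allPos[o]
    n <- length(allKeys); s <- length(obsList)
    meth <- matrix(NA_integer_, n, s)
    total <- matrix(NA_integer_, n, s)
    for (j in seq_len(s)) {
        ob <- obsList[[j]]
        idx <- match(paste0(ob$chrom, ":", ob$pos), allKeys)
        meth[idx, j] <- ob$meth
        total[idx, j] <- ob$total
    }
    colnames(meth) <- colnames(total) <- names(obsList)
    if (!is.null(sampleData)) {
        if (!all(names(obsList) %in% sampleData$sample_id))
            stop("sampleData lacks rows for some samples")
        sampleData <- sampleData[match(names(obsList), sampleData$sample_id), ,
                                 drop = FALSE]
    }
    MethylExperiment(meth, total,
                     sites = data.frame(chrom = allChrom, pos = allPos),
                     sampleData = sampleData)
}

#' Read a BED-like interval track
#'
#' Reads BED3/BED6 (0-based half-open on disk) into a 1-based inclusive
#' `GRanges`; `#` comment lines are skipped. Columns beyond the sixth are
#' ignored.
#'
#' @param path file path.
#' @return `GRanges` with `name` (and `score`) metadata where present.
#' @export
readBedTrack <- function(path) {
    df <- tryCatch(
        utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE),
        error = function(e) NULL)
    if (is.null(df) || !nrow(df))
        return(GenomicRanges::GRanges())
    if (ncol(df) < 3) stop("BED file needs at least 3 columns: ", path)
    start0 <- as.integer(df[[2]]); end0 <- as.integer(df[[3]])
    if (any(start0 >= end0)) stop("BED intervals must have start < end")
    gr <- GenomicRanges::GRanges(
        df[[1]], IRanges::IRanges(start0 + 1L, end0),
        strand = if (ncol(df) >= 6) df[[6]] else "*")
    if (ncol(df) >= 4) gr$name <- as.character(df[[4]])
    if (ncol(df) >= 5) gr$score <- suppressWarnings(as.numeric(df[[5]]))
    gr
}

#' Write intervals or DMRs as BED
#'
#' Internal 1-based inclusive coordinates are converted to the BED 0-based
#' half-open convention (`start - 1`, `end`). For DMR tables (from
#' [callDmrs()]) the name field carries annotated gene names where present
#' and the score is `-log10` of the smallest member p-value.
#'
#' @param x `GRanges`, or a DMR data.frame with `chrom`, `start`, `end`.
#' @param path output path.
#' @param params optional named list echoed into the header.
#' @return `path`, invisibly.
#' @export
writeBed <- function(x, path, params = NULL) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(.headerLines(params), con)
    if (is(x, "GRanges")) {
        if (length(x)) {
            nm <- if (!is.null(x$name)) x$name
                  else if (!is.null(x$gene)) x$gene else "."
            sc <- if (!is.null(x$score)) .fmtNum(x$score) else "0"
            writeLines(paste(as.character(GenomicRanges::seqnames(x)),
                             GenomicRanges::start(x) - 1L,
                             GenomicRanges::end(x), nm, sc,
                             as.character(GenomicRanges::strand(x)),
                             sep = "\t"), con)
        }
    } else if (nrow(x)) {
        nm <- if ("genes" %in% colnames(x))
            vapply(x$genes, function(g)
                if (length(g)) paste(g, collapse = ",") else ".",
                character(1))
        else "."
        sc <- if ("min_p" %in% colnames(x)) .fmtNum(-log10(x$min_p)) else "0"
        writeLines(paste(x$chrom, x$start - 1L, x$end, nm, sc, ".",
                         sep = "\t"), con)
    }
    invisible(path)
}

#' Write / read a per-site results table
#'
#' Writes EWAS results (one row per CpG) as a tab-separated file with a
#' deterministic column order and full numeric precision (12+ significant
#' digits), preceded by provenance header lines. `readResultsTable()`
#' inverts it.
#'
#' @param results data.frame from [runEwas()] (extra columns are kept,
#'   after the canonical ones).
#' @param path file path.
#' @param params optional named list echoed into the header.
#' @return `path` invisibly (writer); data.frame (reader).
#' @export
writeResultsTable <- function(results, path, params = NULL) {
    canonical <- c("chrom", "pos", "slope", "se", "t", "p", "n_used",
                   "direction", "gw_significant")
    cols <- c(intersect(canonical, colnames(results)),
              setdiff(colnames(results), canonical))
    df <- results[, cols, drop = FALSE]
    for (col in colnames(df))
        if (is.numeric(df[[col]]) && !is.integer(df[[col]]))
            df[[col]] <- .fmtNum(df[[col]])
    con <- file(path, "w"); on.exit(close(con))
    writeLines(.headerLines(params), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeResultsTable
#' @export
readResultsTable <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
    for (col in c("slope", "se", "t", "p"))
        if (col %in% colnames(df)) df[[col]] <- as.numeric(df[[col]])
    if ("gw_significant" %in% colnames(df))
        df$gw_significant <- as.logical(df$gw_significant)
    df
}
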