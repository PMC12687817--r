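#' Percentage with half-even rounding
#'
#' `100 * count / total` rounded to `decimals` places (banker's rounding,
#' as in table formatting such as "19 (21.3%)").
#'
#' @param count,total non-negative integers, `count <= total`, `total > 0`.
#' @param decimals digits after the point (default 1).
#' @return numeric percentage.
#' @examples
#' percentOf(19, 89)   # 21.3
#' percentOf(30, 43)   # 69.8
#' @export
percentOf <- function(count, total, decimals = 1L) {
    if (any(total == 0)) stop("total must be > 0")
    if (any(count < 0) || any(count > total))
        stop("count must be in [0, total]")
    round(100 * count / total, decimals)
}

#' Two-sample t-test for continuous variables
#'
#' Welch's two-tailed independent-sample t-test by default (robust to the
#' unequal group sizes typical of exposed-vs-control designs); set
#' `pooled = TRUE` for the equal-variance test.
#'
#' @param valuesA,valuesB numeric vectors, each with >= 2 finite values.
#' @param pooled use the pooled-variance test instead of Welch.
#' @return list: `t`, `df`, `p`.
#' @export
compareContinuous <- function(valuesA, valuesB, pooled = FALSE) {
    valuesA <- valuesA[is.finite(valuesA)]
    valuesB <- valuesB[is.finite(valuesB)]
    if (length(valuesA) < 2 || length(valuesB) < 2)
        stop("each group needs at least 2 finite values")
    if (stats::var(valuesA) == 0 && stats::var(valuesB) == 0)
        stop("degenerate variance in both groups")
    ht <- stats::t.test(valuesA, valuesB, var.equal = pooled)
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}

#' Pearson chi-squared test for categorical variables
#'
#' Pearson's chi-squared without continuity correction on a 2 x k count
#' table; warns when any expected count is below 5.
#'
#' @param counts 2 x k matrix of counts.
#' @return list: `chi2`, `df`, `p`.
#' @export
compareCategorical <- function(counts) {
    counts <- as.matrix(counts)
    if (nrow(counts) != 2) stop("counts must be a 2 x k table")
    if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
        stop("zero margin in the contingency table")
    expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
    if (any(expected < 5))
        warning("expected count below 5; chi-squared approximation is poor")
    ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}

#' Cohort descriptive table
#'
#' Summarizes a sample sheet in the style of a clinical Table 1: for each
#' variable, the overall and per-group (exposed vs control) mean (SD) for
#' continuous variables or % (n) for binaries, with a Welch t-test or
#' chi-squared comparison p-value. Exposure grouping is
#' `years_of_play > 0`.
#'
#' @param samples data.frame from [readSampleSheet()] /
#'   [simulateCohort()].
#' @param continuous,binary character vectors of column names to
#'   summarize (defaults: age at death; smoking history).
#' @return data.frame: `variable`, `type`, `overall`, `control`,
#'   `exposed`, `test`, `p`.
#' @export
cohortTable <- function(samples, continuous = "age_at_death",
                        binary = "smoking_history") {
    grp <- samples$years_of_play > 0
    fmtMean <- function(v) sprintf("%.1f (%.1f)", mean(v), stats::sd(v))
    fmtPct <- function(v) sprintf("%.1f (%d)", percentOf(sum(v), length(v)),
                                  sum(v))
    rows <- list(data.frame(
        variable = "n", type = "count",
        overall = as.character(nrow(samples)),
        control = as.character(sum(!grp)),
        exposed = sprintf("%d (%.1f%%)", sum(grp),
                          percentOf(sum(grp), nrow(samples))),
        test = "", p = NA_real_))
    yrs <- samples$years_of_play[grp]
    rows[[length(rows) + 1L]] <- data.frame(
        variable = "years_of_play", type = "continuous",
        overall = "--", control = "0",
        exposed = if (length(yrs)) sprintf("%.2f (%.2f) [%d-%d]", mean(yrs),
                                           stats::sd(yrs), min(yrs), max(yrs))
                  else "--",
        test = "", p = NA_real_)
    for (v in continuous) {
        ht <- tryCatch(compareContinuous(samples[[v]][!grp],
                                         samples[[v]][grp]),
                       error = function(e) list(p = NA_real_))
        rows[[length(rows) + 1L]] <- data.frame(
            variable = v, type = "continuous",
            overall = fmtMean(samples[[v]]),
            control = fmtMean(samples[[v]][!grp]),
            exposed = fmtMean(samples[[v]][grp]),
            test = "welch_t", p = ht$p)
    }
    for (v in binary) {
        x <- as.integer(samples[[v]])
        tab <- rbind(c(sum(x[!grp] == 1), sum(x[!grp] == 0)),
                     c(sum(x[grp] == 1), sum(x[grp] == 0)))
        ht <- tryCatch(suppressWarnings(compareCategorical(tab)),
                       error = function(e) list(p = NA_real_))
        rows[[length(rows) + 1L]] <- data.frame(
            variable = v, type = "binary",
            overall = fmtPct(x), control = fmtPct(x[!grp]),
            exposed = fmtPct(x[grp]),
            test = "chi_squared", p = ht$p)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Write a cohort table
#'
#' @param table data.frame from [cohortTable()].
#' @param path output path.
#' @param sep delimiter.
#' @return `path`, invisibly.
#' @export
writeCohortTable <- function(table, path, sep = "\t") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(.headerLines(), con)
    df <- table
    df$p <- .fmtNum(df$p)
    utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(path)
}
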