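#' Bonferroni genome-wide significance threshold
#'
#' `alpha / nIndependentTests`; with the conventional assumption of one
#' million independent CpG sites and family-wise alpha 0.05 this is the
#' genome-wide significance threshold 5e-8.
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param nIndependentTests assumed number of independent tests, >= 1.
#' @return The per-test threshold.
#' @examples
#' bonferroniThreshold()            # 5e-8
#' bonferroniThreshold(0.01, 100)   # 1e-4
#' @export
bonferroniThreshold <- function(alpha = 0.05, nIndependentTests = 1e6) {
    if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
        stop("alpha must be in (0, 1)")
    if (!is.finite(nIndependentTests) || nIndependentTests < 1)
        stop("nIndependentTests must be >= 1")
    alpha / nIndependentTests
}

## Grouped OLS over a sites x samples outcome matrix. Sites sharing a
## missingness pattern are fit in one matrix operation (one QR per
## pattern). X: samples x p design, exposure in column 2.
.fitMany <- function(Y, X) {
    n <- nrow(Y); p <- ncol(X)
    out <- data.frame(slope = rep(NA_real_, n), se = NA_real_,
                      t = NA_real_, p = NA_real_, n_used = 0L,
                      degenerate = TRUE)
    pattern <- apply(!is.na(Y), 1, function(r) paste(which(r), collapse = ","))
    for (pat in unique(pattern)) {
        sites <- which(pattern == pat)
        used <- as.integer(strsplit(pat, ",")[[1]])
        nUsed <- length(used)
        out$n_used[sites] <- nUsed
        if (nUsed < p + 2L) next
        Xg <- X[used, , drop = FALSE]
        qrX <- qr(Xg)
        if (qrX$rank < p) next                       # rank-deficient design
        Yg <- t(Y[sites, used, drop = FALSE])        # samples x sites
        beta <- qr.coef(qrX, Yg)
        res <- Yg - Xg %*% beta
        df <- nUsed - p
        sigma2 <- colSums(res^2) / df
        xtxinv22 <- chol2inv(qr.R(qrX))[2L, 2L]
        se <- sqrt(sigma2 * xtxinv22)
        tstat <- beta[2L, ] / se
        pval <- 2 * stats::pt(-abs(tstat), df)
        constantY <- apply(Yg, 2, function(y) max(y) - min(y) == 0)
        out$slope[sites] <- ifelse(constantY, 0, beta[2L, ])
        out$se[sites] <- ifelse(constantY, NA_real_, se)
        out$t[sites] <- ifelse(constantY, NA_real_, tstat)
        out$p[sites] <- ifelse(constantY, NA_real_, pval)
        out$degenerate[sites] <- constantY
    }
    out$direction <- ifelse(is.na(out$slope) | out$slope == 0, "none",
                            ifelse(out$slope < 0, "hypo", "hyper"))
    out
}

.buildDesign <- function(samples, covariates) {
    years <- samples$years_of_play
    X <- cbind(`(Intercept)` = 1, years_of_play = years)
    for (cv in covariates) {
        if (!cv %in% colnames(samples))
            stop("covariate '", cv, "' not found in the sample sheet")
        v <- as.numeric(samples[[cv]])
        X <- cbind(X, scale(v, scale = FALSE)[, 1])  # centred for stability
        colnames(X)[ncol(X)] <- cv
    }
    X
}

#' Fit the dose-response model at one CpG
#'
#' Ordinary least squares of a site's per-sample methylation level on
#' years of play plus covariates (age at death and smoking history by
#' default), on the non-missing samples. The reported slope, standard
#' error, t statistic and two-sided p-value (t distribution on
#' `n_used - p` degrees of freedom) are for the years-of-play coefficient;
#' its sign gives the direction (`hypo` for negative). Covariates are
#' centred internally, which does not change the slope or p.
#'
#' A site with zero outcome variance, a rank-deficient design, or fewer
#' than `p + 2` usable observations is flagged `degenerate` with `p = NA`
#' (excluded from tallies and DMR input downstream). Zero variance in the
#' exposure among used samples is design misuse and errors.
#'
#' @param levels numeric vector of per-sample methylation levels (NA =
#'   missing).
#' @param samples data.frame with `years_of_play` and the covariate
#'   columns, rows aligned to `levels`.
#' @param covariates character vector of covariate column names.
#' @return One-row data.frame: `slope`, `se`, `t`, `p`, `n_used`,
#'   `degenerate`, `direction`.
#' @export
fitSite <- function(levels, samples,
                    covariates = c("age_at_death", "smoking_history")) {
    if (length(levels) != nrow(samples))
        stop("levels and samples differ in length")
    X <- .buildDesign(samples, covariates)
    used <- !is.na(levels)
    if (sum(used) >= 2 && stats::var(samples$years_of_play[used]) == 0)
        stop("zero variance in years_of_play among used samples")
    .fitMany(matrix(levels, nrow = 1), X)
}

#' Epigenome-wide dose-response scan
#'
#' Fits [fitSite()]'s model at every retained CpG and flags genome-wide
#' significance at `p < alphaGW` (strict; equality at the threshold is not
#' significant). The outcome is the `"level"` assay if present (raw or
#' smoothed), else raw levels computed on the fly. With
#' `scale = "logit"` the outcome is the empirical logit
#' `log((meth + 0.5) / (unmeth + 0.5))` from the counts (or
#' `qlogis` of levels clamped to `[0.01, 0.99]` when only smoothed levels
#' are available), putting the slope on the logit scale used by the
#' simulator's ground truth.
#'
#' @param object a QC'd [MethylExperiment-class].
#' @param samples optional sample sheet; defaults to `colData(object)`.
#' @param covariates covariate column names (default age at death and
#'   smoking history).
#' @param alphaGW genome-wide significance threshold (default
#'   [bonferroniThreshold()] = 5e-8).
#' @param scale `"proportion"` (default) or `"logit"`.
#' @return data.frame, one row per site in (chrom, pos) order: `chrom`,
#'   `pos`, `slope`, `se`, `t`, `p`, `n_used`, `direction`,
#'   `gw_significant`, `degenerate`.
#' @aliases runEwas
#' @export
setMethod("runEwas", "MethylExperiment",
          function(object, samples = NULL,
                   covariates = c("age_at_death", "smoking_history"),
                   alphaGW = 5e-8, scale = c("proportion", "logit")) {
    scale <- match.arg(scale)
    if (is.null(samples))
        samples <- as.data.frame(SummarizedExperiment::colData(object))
    if (!"years_of_play" %in% colnames(samples))
        stop("sample sheet lacks 'years_of_play'")
    if (nrow(object) == 0L) {
        warning("empty matrix; no sites to test")
        return(data.frame(chrom = character(), pos = integer(),
                          slope = numeric(), se = numeric(), t = numeric(),
                          p = numeric(), n_used = integer(),
                          direction = character(), gw_significant = logical(),
                          degenerate = logical()))
    }
    if (stats::var(samples$years_of_play) == 0)
        stop("zero variance in years_of_play")
    meth <- SummarizedExperiment::assay(object, "meth")
    total <- SummarizedExperiment::assay(object, "total")
    hasLevel <- "level" %in% SummarizedExperiment::assayNames(object)
    smoothed <- identical(S4Vectors::metadata(object)$levelMethod, "smoothed")
    if (scale == "proportion") {
        Y <- if (hasLevel) SummarizedExperiment::assay(object, "level")
             else meth / total
    } else {
        Y <- if (hasLevel && smoothed) {
            lev <- SummarizedExperiment::assay(object, "level")
            stats::qlogis(pmin(pmax(lev, 0.01), 0.99))
        } else {
            log((meth + 0.5) / (total - meth + 0.5))
        }
    }
    X <- .buildDesign(samples, covariates)
    fit <- .fitMany(Y, X)
    st <- siteTable(object)
    res <- cbind(st, fit)
    res$gw_significant <- !is.na(res$p) & res$p < alphaGW
    res[order(res$chrom, res$pos), ]
})

#' Tally direction of change among nominally significant sites
#'
#' Among non-degenerate sites with `p < pCut`, the percentage with
#' negative slope (hypomethylated with increasing exposure) and positive
#' slope (hypermethylated). Sites with exactly zero slope are counted
#' separately and excluded from the percentages, which therefore sum
#' to 100.
#'
#' @param results data.frame from [runEwas()].
#' @param pCut nominal p-value cutoff (default 0.05).
#' @return list: `pct_hypo`, `pct_hyper`, `n` (tallied sites), `n_zero`.
#'   Percentages are `NA` when no site passes.
#' @export
directionTally <- function(results, pCut = 0.05) {
    pass <- !is.na(results$p) & !results$degenerate & results$p < pCut
    slopes <- results$slope[pass]
    nNeg <- sum(slopes < 0); nPos <- sum(slopes > 0); nZero <- sum(slopes == 0)
    n <- nNeg + nPos
    if (n == 0)
        return(list(pct_hypo = NA_real_, pct_hyper = NA_real_, n = 0L,
                    n_zero = nZero))
    list(pct_hypo = 100 * nNeg / n, pct_hyper = 100 * nPos / n,
         n = as.integer(n), n_zero = as.integer(nZero))
}

#' Cross-cohort direction consistency
#'
#' For every key shared between two result sets (CpG position by default,
#' or any annotation column such as a gene name), compares the sign of the
#' mean slope; a key is consistent when the signs agree. Used to check
#' whether a replication cohort shows the same direction of methylation
#' change with duration of play.
#'
#' @param resultsA,resultsB data.frames from [runEwas()], optionally
#'   annotated.
#' @param key `"site"` (chrom:pos) or the name of a shared column.
#' @return list: `table` (key, mean_slope_a, mean_slope_b, consistent),
#'   `n`, `n_consistent`, `pct_consistent`.
#' @export
compareDirections <- function(resultsA, resultsB, key = "site") {
    keyOf <- function(r) {
        if (key == "site") paste0(r$chrom, ":", r$pos)
        else {
            if (!key %in% colnames(r)) stop("key column '", key, "' missing")
            as.character(r[[key]])
        }
    }
    ka <- keyOf(resultsA); kb <- keyOf(resultsB)
    okA <- !is.na(resultsA$slope) & !resultsA$degenerate & !is.na(ka)
    okB <- !is.na(resultsB$slope) & !resultsB$degenerate & !is.na(kb)
    ma <- tapply(resultsA$slope[okA], ka[okA], mean)
    mb <- tapply(resultsB$slope[okB], kb[okB], mean)
    shared <- sort(intersect(names(ma), names(mb)))
    if (!length(shared)) {
        warning("no shared keys between result sets")
        return(list(table = data.frame(key = character(),
                                       mean_slope_a = numeric(),
                                       mean_slope_b = numeric(),
                                       consistent = logical()),
                    n = 0L, n_consistent = 0L, pct_consistent = NA_real_))
    }
    tab <- data.frame(key = shared,
                      mean_slope_a = as.numeric(ma[shared]),
                      mean_slope_b = as.numeric(mb[shared]))
    tab$consistent <- sign(tab$mean_slope_a) == sign(tab$mean_slope_b)
    list(table = tab, n = nrow(tab),
         n_consistent = sum(tab$consistent),
         pct_consistent = 100 * mean(tab$consistent))
}

#' Manhattan-plot export table
#'
#' @param results data.frame from [runEwas()].
#' @return data.frame `chrom`, `pos`, `neg_log10_p` for external plotting.
#' @export
manhattanTable <- function(results) {
    ok <- !is.na(results$p)
    data.frame(chrom = results$chrom[ok], pos = results$pos[ok],
               neg_log10_p = -log10(results$p[ok]))
}
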