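## Independent closed-form oracles. These deliberately re-derive every
## statistic from first principles (normal equations, Welch and Pearson
## formulas, naive loops) so the package implementations are checked
## against a different code path.

## OLS of y on X (first column intercept, second the exposure), complete
## cases, via explicit normal equations.
olsOracle <- function(y, X) {
    use <- stats::complete.cases(y, X)
    y <- y[use]; X <- X[use, , drop = FALSE]
    n <- length(y); p <- ncol(X)
    XtX <- t(X) %*% X
    beta <- solve(XtX, t(X) %*% y)
    res <- y - X %*% beta
    sigma2 <- sum(res^2) / (n - p)
    se <- sqrt(sigma2 * solve(XtX)[2, 2])
    tstat <- beta[2] / se
    list(slope = beta[2], se = se, t = tstat,
         p = 2 * stats::pt(-abs(tstat), n - p), n_used = n)
}

welchOracle <- function(a, b) {
    na <- length(a); nb <- length(b)
    va <- stats::var(a); vb <- stats::var(b)
    tstat <- (mean(a) - mean(b)) / sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
        ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

chisqOracle <- function(tab) {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    chi2 <- sum((tab - expected)^2 / expected)
    df <- (nrow(tab) - 1) * (ncol(tab) - 1)
    list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

## Naive nested-loop matrix assembly: union of sites, cell-by-cell lookup.
naiveAssemble <- function(obsList) {
    keys <- character()
    for (ob in obsList)
        for (r in seq_len(nrow(ob)))
            keys <- union(keys, paste0(ob$chrom[r], ":", ob$pos[r]))
    chrom <- sub(":.*", "", keys); pos <- as.integer(sub(".*:", "", keys))
    o <- order(chrom, pos)
    keys <- keys[o]; chrom <- chrom[o]; pos <- pos[o]
    meth <- matrix(NA_integer_, length(keys), length(obsList))
    total <- matrix(NA_integer_, length(keys), length(obsList))
    for (j in seq_along(obsList)) {
        ob <- obsList[[j]]
        for (r in seq_len(nrow(ob))) {
            i <- which(keys == paste0(ob$chrom[r], ":", ob$pos[r]))
            meth[i, j] <- ob$meth[r]; total[i, j] <- ob$total[r]
        }
    }
    list(chrom = chrom, pos = pos, meth = meth, total = total)
}

## Hand-coded tricube weighted-ratio smoother for a single chromosome,
## following the window definition independently of the package code.
smoothOracle <- function(pos, meth, total, windowBp, minSites) {
    m <- length(pos)
    out <- numeric(m)
    h0 <- windowBp / 2
    k <- min(minSites, m)
    for (i in seq_len(m)) {
        d <- abs(pos - pos[i])
        h <- max(h0, sort(d)[k])
        w <- ifelse(d <= h, (1 - (d / (h + 1))^3)^3, 0)
        ok <- !is.na(total)
        out[i] <- sum(w[ok] * meth[ok]) / sum(w[ok] * total[ok])
    }
    out
}

## Small simulated experiment for pipeline-level tests.
smallSimExperiment <- function(seed = 1, nSamples = 30, nSites = 200, ...) {
    cfg <- simConfig(nSamples = nSamples, nSites = nSites, nChroms = 2,
                     seed = seed, ...)
    cohort <- simulateCohort(cfg)
    landscape <- simulateLandscape(cfg)
    list(cfg = cfg, cohort = cohort, landscape = landscape,
         me = simulateCounts(landscape, cohort, cfg))
}

## Random small EWAS-results instance for DMR oracle tests.
randomDmrInstance <- function(nSites, sigProb = 0.35) {
    chrom <- sort(sample(c("chr1", "chr2"), nSites, replace = TRUE))
    pos <- unlist(lapply(split(seq_len(nSites), chrom), function(idx)
        cumsum(sample(c(5:60, 150, 200, 260, 300), length(idx),
                      replace = TRUE)) + 100L), use.names = FALSE)
    sig <- stats::runif(nSites) < sigProb
    data.frame(chrom = chrom, pos = pos,
               slope = stats::rnorm(nSites, 0, 0.01),
               p = ifelse(sig, 1e-10, stats::runif(nSites, 0.1, 1)),
               degenerate = FALSE)
}

expectDmrEqual <- function(a, b) {
    cols <- c("chrom", "start", "end", "length_bp", "n_cpg", "n_sig")
    expect_equal(a[cols], b[cols], ignore_attr = TRUE)
    expect_equal(a$frac_sig, b$frac_sig, tolerance = 1e-12)
    expect_equal(unname(a$members), unname(b$members), ignore_attr = TRUE)
}
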