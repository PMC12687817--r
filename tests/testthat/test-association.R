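test_that("Bonferroni threshold arithmetic and domain checks", {
    expect_equal(bonferroniThreshold(0.05, 1e6), 5e-8, tolerance = 1e-12)
    expect_identical(bonferroniThreshold(0.05, 1), 0.05)
    expect_equal(bonferroniThreshold(0.01, 100), 1e-4, tolerance = 1e-12)
    expect_error(bonferroniThreshold(0), "alpha")
    expect_error(bonferroniThreshold(0.05, 0), "nIndependentTests")
})

randomSamples <- function(n) {
    data.frame(sample_id = sprintf("s%02d", 1:n),
               years_of_play = sample(0:19, n, TRUE),
               age_at_death = rnorm(n, 80, 10),
               smoking_history = rbinom(n, 1, 0.4))
}

test_that("fitSite matches the normal-equations oracle on 100 random designs", {
    set.seed(41)
    for (rep in 1:100) {
        n <- sample(12:40, 1)
        samples <- randomSamples(n)
        y <- rnorm(n, 0.5, 0.1)
        y[sample(n, sample(0:3, 1))] <- NA
        fit <- fitSite(y, samples)
        X <- cbind(1, samples$years_of_play,
                   samples$age_at_death - mean(samples$age_at_death),
                   samples$smoking_history - mean(samples$smoking_history))
        oracle <- olsOracle(y, X)
        expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
        expect_equal(fit$se, oracle$se, tolerance = 1e-10)
        expect_equal(fit$t, oracle$t, tolerance = 1e-10)
        expect_equal(fit$p, oracle$p, tolerance = 1e-10)
        expect_equal(fit$n_used, oracle$n_used)
    }
})

test_that("a 12-sample toy fit agrees with the oracle and flags degeneracies", {
    samples <- data.frame(
        sample_id = sprintf("s%02d", 1:12),
        years_of_play = c(0L, 0L, 0L, 0L, 0L, 0L, 2L, 5L, 8L, 11L, 15L, 19L),
        age_at_death = c(81, 74, 90, 68, 85, 77, 88, 72, 83, 79, 91, 70),
        smoking_history = c(0L, 1L, 0L, 0L, 1L, 1L, 0L, 1L, 0L, 0L, 1L, 0L))
    levels <- c(0.61, 0.58, 0.64, 0.55, 0.60, 0.57,
                0.52, 0.49, 0.45, 0.44, 0.38, 0.33)
    fit <- fitSite(levels, samples)
    X <- cbind(1, samples$years_of_play,
               samples$age_at_death - mean(samples$age_at_death),
               samples$smoking_history - mean(samples$smoking_history))
    oracle <- olsOracle(levels, X)
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
    expect_equal(fit$p, oracle$p, tolerance = 1e-10)
    expect_equal(fit$direction, "hypo")

    ## constant outcome -> degenerate, slope 0, p missing
    const <- fitSite(rep(0.5, 12), samples)
    expect_true(const$degenerate)
    expect_equal(const$slope, 0)
    expect_true(is.na(const$p))

    ## zero exposure variance among used samples is design misuse
    noVar <- samples; noVar$years_of_play <- 5L
    expect_error(fitSite(levels, noVar), "variance")

    ## rank-deficient design -> degenerate flag, not an error
    collinear <- samples; collinear$age_at_death <- samples$years_of_play * 2
    fitC <- fitSite(levels, collinear)
    expect_true(fitC$degenerate)
})

test_that("runEwas flags genome-wide significance strictly below the threshold", {
    sim <- smallSimExperiment(seed = 43, nSamples = 20, nSites = 100)
    me <- rawLevels(filterFewSamples(filterLowCoverage(sim$me), 10L))
    res <- runEwas(me)
    expect_equal(res$gw_significant, !is.na(res$p) & res$p < 5e-8)
    expect_equal(res, res[order(res$chrom, res$pos), ])
    expect_equal(nrow(res), nrow(me))

    ## strictness at the boundary via the tally rule itself
    fake <- data.frame(chrom = "chr1", pos = c(1L, 2L),
                       slope = c(-1, -1), se = 1, t = -1,
                       p = c(4e-8, 5e-8), n_used = 20L,
                       degenerate = FALSE)
    fake$gw_significant <- fake$p < 5e-8
    expect_equal(fake$gw_significant, c(TRUE, FALSE))

    empty <- me[0, ]
    expect_warning(res0 <- runEwas(empty), "empty")
    expect_equal(nrow(res0), 0)
})

test_that("direction tallies and cross-cohort consistency behave", {
    res <- data.frame(chrom = "chr1", pos = 1:4,
                      slope = c(-0.01, -0.02, -0.03, 0.04),
                      p = c(0.01, 0.001, 0.04, 0.02), degenerate = FALSE)
    tl <- directionTally(res, 0.05)
    expect_equal(tl$pct_hypo, 75)
    expect_equal(tl$pct_hyper, 25)
    expect_equal(tl$n, 4L)

    allNeg <- directionTally(transform(res, slope = -abs(slope)), 0.05)
    expect_equal(allNeg$pct_hypo, 100)

    none <- directionTally(transform(res, p = 0.9), 0.05)
    expect_true(is.na(none$pct_hypo))
    expect_equal(none$n, 0L)

    cmp <- compareDirections(res, res)
    expect_equal(cmp$pct_consistent, 100)
    flipped <- transform(res, slope = -slope)
    expect_equal(compareDirections(res, flipped)$pct_consistent, 0)
    other <- transform(res, chrom = "chr9")
    expect_warning(cmp0 <- compareDirections(res, other), "shared")
    expect_equal(cmp0$n, 0L)
})

test_that("null p-values are uniform and effect estimates unbiased (small scale)", {
    ## small type-I sanity check (the full-size one lives in acceptance)
    sim <- smallSimExperiment(seed = 47, nSamples = 40, nSites = 400,
                              fracEffectSites = 0)
    me <- rawLevels(filterFewSamples(filterLowCoverage(sim$me), 10L))
    res <- runEwas(me)
    p <- res$p[!res$degenerate & !is.na(res$p)]
    expect_gt(stats::ks.test(p, "punif")$p.value, 0.001)

    ## covariate adjustment beats no adjustment under age confounding
    set.seed(48)
    cfg <- simConfig(nSamples = 150, nSites = 150, nChroms = 1,
                     fracEffectSites = 0, ageEffectSd = 0.03,
                     missingRate = 0, seed = 49)
    co <- simulateCohort(cfg)
    co$age_at_death <- 60 + 1.4 * co$years_of_play + rnorm(150, 0, 3)
    ls1 <- simulateLandscape(cfg)
    me <- rawLevels(filterFewSamples(filterLowCoverage(
        simulateCounts(ls1, co, cfg)), 10L))
    adj <- runEwas(me, scale = "logit")
    unadj <- runEwas(me, covariates = character(0), scale = "logit")
    ## truth slope is 0 everywhere: adjusted estimates should sit closer to 0
    expect_lt(mean(abs(adj$slope), na.rm = TRUE),
              mean(abs(unadj$slope), na.rm = TRUE))
})

test_that("replication cohorts from one truth agree in direction above chance", {
    cfgA <- simConfig(nSamples = 60, nSites = 150, nChroms = 1,
                      fracEffectSites = 1, effectSlopeSd = 0.08,
                      missingRate = 0, seed = 51)
    cfgB <- simConfig(nSamples = 60, nSites = 150, nChroms = 1,
                      fracEffectSites = 1, effectSlopeSd = 0.08,
                      missingRate = 0, seed = 52)
    ls1 <- simulateLandscape(cfgA)
    meA <- rawLevels(filterFewSamples(filterLowCoverage(
        simulateCounts(ls1, simulateCohort(cfgA), cfgA)), 10L))
    meB <- rawLevels(filterFewSamples(filterLowCoverage(
        simulateCounts(ls1, simulateCohort(cfgB), cfgB)), 10L))
    cmp <- compareDirections(runEwas(meA), runEwas(meB))
    expect_gt(cmp$n, 100)
    ## one-sided binomial test against the 50% null expectation
    expect_lt(stats::binom.test(cmp$n_consistent, cmp$n, 0.5,
                                alternative = "greater")$p.value, 1e-6)
})
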