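## Random streams: each generator stage seeds its own stream
## (seed + fixed offset) so e.g. changing nSites never perturbs the cohort.
.SEED_COHORT <- 101L
.SEED_LANDSCAPE <- 202L
.SEED_COUNTS <- 303L

#' Simulation configuration
#'
#' Constructs a validated [SimConfig-class]. Defaults are the study
#' conditions the generator emulates: an 89-donor autopsy cohort with 21.3%
#' exposed to repetitive head impacts (years of contact-sports play uniform
#' integers on 2-19 for exposed donors), age at death ~ Normal(84, 10.2)
#' truncated at 40 years, smoking prevalence 0.36; RRBS-like counts with
#' negative-binomial coverage (mean 30, size 4) and beta-binomial
#' overdispersion rho = 0.05; 5% of sites carry a per-year effect on the
#' logit of methylation with 70.7% of effects negative (hypomethylation
#' with increasing play).
#'
#' @param nSamples cohort size (>= 4).
#' @param pExposed probability a donor is exposed (played contact sports).
#' @param yearsRange integer pair; exposed donors' years of play are drawn
#'   uniformly on this range. Note the resulting mean (~10.5 under the
#'   default 2-19) is deliberately not matched to any empirical cohort mean.
#' @param ageMean,ageSd,ageMin age-at-death normal parameters (years) and
#'   lower truncation point.
#' @param smokingPrev smoking-history prevalence.
#' @param nSites,nChroms number of CpG sites and chromosomes.
#' @param meanGapBp mean gap between neighbouring CpGs (geometric-like).
#' @param fracIslandSites fraction of sites placed inside generated CpG
#'   islands.
#' @param fracEffectSites fraction of sites carrying a true exposure effect
#'   (exact without-replacement sample of `round(fracEffectSites * nSites)`
#'   sites, so truth counts are deterministic).
#' @param effectSlopeSd half-normal scale of true slopes, logit-units per
#'   year of play.
#' @param fracNegativeEffects probability a true effect is negative.
#' @param baseShape1,baseShape2 Beta parameters of per-site baseline
#'   methylation levels.
#' @param ageEffectSd,smokeEffectSd normal scales of per-site nuisance
#'   coefficients (0 by default so the null is clean; enable for
#'   confounding studies).
#' @param coverageMean,coverageDispersion negative-binomial coverage mean
#'   and size.
#' @param betaBinomialRho intra-class correlation of the beta-binomial
#'   count model, in `[0, 1)`; 0 degenerates to binomial.
#' @param missingRate probability a cell is independently unprofiled.
#' @param seed integer master seed.
#' @return A [SimConfig-class].
#' @examples
#' cfg <- simConfig(nSamples = 20, nSites = 100, seed = 7)
#' cohort <- simulateCohort(cfg)
#' @export
simConfig <- function(nSamples = 89L, pExposed = 0.213,
                      yearsRange = c(2L, 19L),
                      ageMean = 84, ageSd = 10.2, ageMin = 40,
                      smokingPrev = 0.36,
                      nSites = 2000L, nChroms = 2L, meanGapBp = 100,
                      fracIslandSites = 0.2,
                      fracEffectSites = 0.05, effectSlopeSd = 0.05,
                      fracNegativeEffects = 0.707,
                      baseShape1 = 2, baseShape2 = 2,
                      ageEffectSd = 0, smokeEffectSd = 0,
                      coverageMean = 30, coverageDispersion = 4,
                      betaBinomialRho = 0.05, missingRate = 0.05,
                      seed = 1L) {
    new("SimConfig",
        nSamples = as.integer(nSamples), pExposed = pExposed,
        yearsRange = as.integer(yearsRange),
        ageMean = ageMean, ageSd = ageSd, ageMin = ageMin,
        smokingPrev = smokingPrev,
        nSites = as.integer(nSites), nChroms = as.integer(nChroms),
        meanGapBp = meanGapBp, fracIslandSites = fracIslandSites,
        fracEffectSites = fracEffectSites, effectSlopeSd = effectSlopeSd,
        fracNegativeEffects = fracNegativeEffects,
        baseShape1 = baseShape1, baseShape2 = baseShape2,
        ageEffectSd = ageEffectSd, smokeEffectSd = smokeEffectSd,
        coverageMean = coverageMean,
        coverageDispersion = coverageDispersion,
        betaBinomialRho = betaBinomialRho, missingRate = missingRate,
        seed = as.integer(seed))
}

#' Simulate a cohort sample sheet
#'
#' Each donor is exposed with probability `pExposed`; exposed donors draw
#' integer years of play uniformly on `yearsRange`, unexposed donors have 0.
#' Age at death is normal truncated below at `ageMin`; smoking history is
#' Bernoulli. Fully reproducible given the config seed.
#'
#' @param config a [SimConfig-class].
#' @return data.frame with columns `sample_id`, `years_of_play`,
#'   `age_at_death`, `smoking_history`, `exposed`.
#' @export
simulateCohort <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    n <- config@nSamples
    if (n < 4L) stop("nSamples must be >= 4")
    set.seed(config@seed + .SEED_COHORT)
    exposed <- stats::rbinom(n, 1L, config@pExposed) == 1L
    years <- integer(n)
    if (any(exposed))
        years[exposed] <- sample(
            seq.int(config@yearsRange[1], config@yearsRange[2]),
            sum(exposed), replace = TRUE)
    age <- stats::rnorm(n, config@ageMean, config@ageSd)
    while (any(age < config@ageMin))      # truncate by resampling
        age[age < config@ageMin] <- stats::rnorm(sum(age < config@ageMin),
                                                 config@ageMean, config@ageSd)
    smoke <- stats::rbinom(n, 1L, config@smokingPrev)
    data.frame(sample_id = sprintf("S%03d", seq_len(n)),
               years_of_play = years,
               age_at_death = round(age, 1),
               smoking_history = smoke,
               exposed = exposed)
}

#' Simulate a CpG landscape with ground-truth effects
#'
#' Lays out CpG positions with geometric-like gaps on `nChroms`
#' chromosomes, builds CpG islands as contiguous site runs covering about
#' `fracIslandSites` of sites, tiles stranded gene models (with exons, so
#' promoter / 1-5 kb upstream / exon / intron / intergenic are all
#' realisable), and assigns true effects: an exact without-replacement
#' sample of `round(fracEffectSites * nSites)` sites receives a half-normal
#' slope (logit-units per year), signed negative with probability
#' `fracNegativeEffects`.
#'
#' @param config a [SimConfig-class]; `nSites >= 10` required.
#' @return list with elements `sites` (GRanges), `islands` (GRanges),
#'   `genes` ([GeneTrack-class]) and `truth` (data.frame: `chrom`, `pos`,
#'   `is_effect`, `true_slope`, `base_level`, `age_coef`, `smoke_coef`).
#' @export
simulateLandscape <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    n <- config@nSites
    if (n < 10L) stop("nSites must be >= 10")
    set.seed(config@seed + .SEED_LANDSCAPE)
    perChrom <- diff(floor(seq(0, n, length.out = config@nChroms + 1L)))
    chromNames <- paste0("chr", seq_len(config@nChroms))
    chrom <- rep(chromNames, perChrom)
    pos <- unlist(lapply(perChrom, function(m) {
        gaps <- 1L + stats::rgeom(m, 1 / config@meanGapBp)
        1000L + cumsum(gaps)
    }), use.names = FALSE)
    sites <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))

    islands <- .makeIslands(chromNames, perChrom, pos, chrom,
                            config@fracIslandSites)
    genes <- .makeGeneModels(chromNames, pos, chrom)

    nEffect <- round(config@fracEffectSites * n)
    isEffect <- rep(FALSE, n)
    if (nEffect > 0) isEffect[sample.int(n, nEffect)] <- TRUE
    slope <- numeric(n)
    if (nEffect > 0) {
        mag <- abs(stats::rnorm(nEffect, 0, config@effectSlopeSd))
        sgn <- ifelse(stats::rbinom(nEffect, 1L,
                                    config@fracNegativeEffects) == 1L, -1, 1)
        slope[isEffect] <- sgn * mag
    }
    base <- stats::rbeta(n, config@baseShape1, config@baseShape2)
    ageCoef <- if (config@ageEffectSd > 0)
        stats::rnorm(n, 0, config@ageEffectSd) else numeric(n)
    smokeCoef <- if (config@smokeEffectSd > 0)
        stats::rnorm(n, 0, config@smokeEffectSd) else numeric(n)
    truth <- data.frame(chrom = chrom, pos = pos, is_effect = isEffect,
                        true_slope = slope, base_level = base,
                        age_coef = ageCoef, smoke_coef = smokeCoef)
    list(sites = sites, islands = islands, genes = genes, truth = truth)
}

## Islands are contiguous runs of ~30 sites, evenly spaced along each
## chromosome so that shores, shelves and open sea all exist between them.
.makeIslands <- function(chromNames, perChrom, pos, chrom, frac) {
    if (frac <= 0) return(GenomicRanges::GRanges())
    parts <- list()
    for (ci in seq_along(chromNames)) {
        p <- pos[chrom == chromNames[ci]]
        m <- length(p)
        runLen <- min(30L, max(3L, m %/% 3L))
        k <- max(1L, round(frac * m / runLen))
        if (m < runLen + 2L) next
        starts <- unique(floor(seq(1L, m - runLen + 1L, length.out = k)))
        gr <- GenomicRanges::GRanges(
            chromNames[ci],
            IRanges::IRanges(pmax(1L, p[starts] - 50L),
                             p[starts + runLen - 1L] + 50L))
        parts[[length(parts) + 1L]] <- GenomicRanges::reduce(gr)
    }
    out <- if (length(parts)) suppressWarnings(do.call(c, parts))
           else GenomicRanges::GRanges()
    if (length(out)) out$name <- sprintf("CGI_%03d", seq_along(out))
    out
}

## Genes tile ~half of each chromosome span in alternating
## gene/intergenic segments of >= ~12.5 kb, strands alternating, three
## exons per gene; guarantees room for promoter and 1-5 kb upstream calls.
.makeGeneModels <- function(chromNames, pos, chrom) {
    geneParts <- list(); exonParts <- list()
    gid <- 0L
    for (cn in chromNames) {
        p <- pos[chrom == cn]
        if (!length(p)) next
        lo <- min(p); hi <- max(p)
        span <- hi - lo
        g <- max(1L, span %/% 25000L)
        w <- span / (2 * g)
        for (i in seq_len(g)) {
            gid <- gid + 1L
            gs <- round(lo + (2 * i - 1) * w)
            ge <- round(lo + 2 * i * w)
            if (ge - gs < 100) next
            strand <- if (gid %% 2L == 1L) "+" else "-"
            name <- sprintf("GENE%03d", gid)
            geneParts[[length(geneParts) + 1L]] <- GenomicRanges::GRanges(
                cn, IRanges::IRanges(gs, ge), strand = strand, gene = name)
            fifth <- (ge - gs) / 5
            es <- round(gs + c(0, 2, 4) * fifth)
            ee <- round(gs + c(1, 3, 5) * fifth)
            exonParts[[length(exonParts) + 1L]] <- GenomicRanges::GRanges(
                cn, IRanges::IRanges(es, ee), strand = strand, gene = name)
        }
    }
    combine <- function(parts) {
        if (!length(parts)) return(GenomicRanges::GRanges())
        suppressWarnings(do.call(c, parts))
    }
    geneTrack(combine(geneParts), combine(exonParts))
}

#' Simulate RRBS methylation counts
#'
#' Generates the count matrix for a landscape/cohort pair. For site i and
#' sample j the methylation probability is
#' `p_ij = plogis(qlogis(base_i) + slope_i * years_j +
#' ageCoef_i * (age_j - mean(age)) + smokeCoef_i * smoke_j)`; coverage is
#' negative-binomial (`mu = coverageMean`, `size = coverageDispersion`) and
#' the methylated count is beta-binomial with mean `p_ij` and intra-class
#' correlation `betaBinomialRho` (binomial when rho = 0). Cells are then
#' independently set missing with `missingRate`. Reproducible given the
#' config seed.
#'
#' @param landscape result of [simulateLandscape()].
#' @param cohort result of [simulateCohort()] (same config).
#' @param config the shared [SimConfig-class].
#' @return A [MethylExperiment-class] with the cohort as `colData` and the
#'   truth table in `metadata(x)$truth`.
#' @export
simulateCounts <- function(landscape, cohort, config) {
    stopifnot(is(config, "SimConfig"))
    truth <- landscape$truth
    n <- nrow(truth); s <- nrow(cohort)
    if (n != config@nSites || s != config@nSamples)
        stop("cohort/landscape sizes do not match the config")
    set.seed(config@seed + .SEED_COUNTS)
    eta <- outer(truth$true_slope, cohort$years_of_play) +
        outer(truth$age_coef, cohort$age_at_death - mean(cohort$age_at_death)) +
        outer(truth$smoke_coef, as.numeric(cohort$smoking_history)) +
        matrix(stats::qlogis(truth$base_level), n, s)
    p <- stats::plogis(eta)
    cov <- matrix(stats::rnbinom(n * s, mu = config@coverageMean,
                                 size = config@coverageDispersion), n, s)
    rho <- config@betaBinomialRho
    if (rho > 0) {
        a <- p * (1 - rho) / rho
        b <- (1 - p) * (1 - rho) / rho
        pcell <- matrix(stats::rbeta(n * s, a, b), n, s)
        pcell[a == 0] <- 0          # degenerate Beta at p = 0 or 1
        pcell[b == 0] <- 1
        meth <- matrix(stats::rbinom(n * s, cov, pcell), n, s)
    } else {
        meth <- matrix(stats::rbinom(n * s, cov, p), n, s)
    }
    if (config@missingRate > 0) {
        miss <- matrix(stats::runif(n * s) < config@missingRate, n, s)
        meth[miss] <- NA_integer_
        cov[miss] <- NA_integer_
    }
    colnames(meth) <- colnames(cov) <- cohort$sample_id
    me <- MethylExperiment(meth, cov,
                           sites = data.frame(chrom = truth$chrom,
                                              pos = truth$pos),
                           sampleData = cohort)
    S4Vectors::metadata(me)$truth <- truth
    S4Vectors::metadata(me)$simConfig <- config
    me
}

#' Simulate a full on-disk dataset
#'
#' Runs cohort, landscape and count simulation and writes everything a
#' pipeline run needs: `sample_sheet.tsv`, per-sample Bismark coverage
#' files under `coverage/`, `truth.tsv`, `islands.bed`, `genes.bed` and
#' `exons.bed`. Outputs are byte-identical across runs with the same
#' config (no timestamps in headers).
#'
#' @param config a [SimConfig-class].
#' @param dir output directory.
#' @param overwrite logical; error if `dir` exists and is non-empty unless
#'   TRUE.
#' @return Invisibly, a list with the in-memory objects and file paths.
#' @export
simulateDataset <- function(config, dir, overwrite = FALSE) {
    if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
        stop("output directory exists and is non-empty: ", dir,
             " (use overwrite = TRUE)")
    dir.create(file.path(dir, "coverage"), recursive = TRUE,
               showWarnings = FALSE)
    cohort <- simulateCohort(config)
    landscape <- simulateLandscape(config)
    me <- simulateCounts(landscape, cohort, config)
    writeSampleSheet(cohort, file.path(dir, "sample_sheet.tsv"))
    meth <- methReads(me); total <- totalReads(me); st <- siteTable(me)
    covPaths <- vapply(seq_len(ncol(me)), function(j) {
        keep <- !is.na(total[, j])
        writeBismarkCov(data.frame(chrom = st$chrom[keep],
                                   pos = st$pos[keep],
                                   meth = meth[keep, j],
                                   total = total[keep, j]),
                        file.path(dir, "coverage",
                                  paste0(cohort$sample_id[j], ".cov")))
    }, character(1))
    truthPath <- file.path(dir, "truth.tsv")
    con <- file(truthPath, "w")
    writeLines(.headerLines(list(seed = config@seed,
                                 n_sites = config@nSites,
                                 n_samples = config@nSamples)), con)
    tdf <- landscape$truth
    for (col in c("true_slope", "base_level", "age_coef", "smoke_coef"))
        tdf[[col]] <- .fmtNum(tdf[[col]])
    utils::write.table(tdf, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    writeBed(landscape$islands, file.path(dir, "islands.bed"))
    writeBed(landscape$genes@genes, file.path(dir, "genes.bed"))
    writeBed(landscape$genes@exons, file.path(dir, "exons.bed"))
    invisible(list(cohort = cohort, landscape = landscape, experiment = me,
                   dir = dir, coverageFiles = covPaths))
}
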