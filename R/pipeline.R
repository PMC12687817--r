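#' Default run configuration
#'
#' Returns the full default configuration for [runPipeline()] as a nested
#' list; any subset of the same structure (e.g. from a YAML file via
#' [readRunConfig()], or the `overrides` argument) is merged over it, with
#' explicit settings taking precedence over file settings over defaults.
#'
#' @param overrides nested list merged over the defaults.
#' @return Nested configuration list with blocks `paths`, `qc`,
#'   `smoothing`, `association`, `dmr`, `annotation` and `seed`.
#' @export
runConfig <- function(overrides = list()) {
    defaults <- list(
        paths = list(sample_sheet = NULL, coverage_dir = NULL,
                     genes_bed = NULL, exons_bed = NULL, islands_bed = NULL,
                     out_dir = NULL),
        qc = list(min_reads = 10L, min_samples = 10L),
        smoothing = list(enabled = FALSE, window_bp = 1000L, min_sites = 70L,
                         max_gap_bp = 10000L),
        association = list(covariates = c("age_at_death", "smoking_history"),
                           alpha_gw = 5e-8, p_cut = 0.05,
                           scale = "proportion"),
        dmr = list(sig_threshold = 5e-8, min_len = 100L, min_sig = 3L,
                   min_frac = 0.8, max_gap = 250L),
        seed = 1L)
    .mergeConfig(defaults, overrides)
}

.mergeConfig <- function(base, over) {
    for (k in names(over)) {
        base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
            .mergeConfig(base[[k]], over[[k]])
        else over[[k]]
    }
    base
}

#' Read a YAML run configuration
#'
#' @param path YAML file with any subset of the [runConfig()] structure.
#' @param overrides nested list applied on top of the file (CLI-style
#'   precedence: overrides > file > defaults).
#' @return Merged configuration list.
#' @export
readRunConfig <- function(path, overrides = list()) {
    runConfig(.mergeConfig(yaml::read_yaml(path), overrides))
}

.stageLog <- function(stage, ...) {
    message(sprintf("[methdose] %-10s %s", stage, paste0(...)))
}

#' Run the full analysis pipeline
#'
#' Executes the fixed stage order QC (coverage filter, then sample-count
#' filter) -> level estimation (raw or smoothed) -> per-CpG dose-response
#' regression -> DMR calling -> annotation -> summary tables, and writes
#' `results.tsv`, `dmrs.bed`, `qc_report.yaml`, `annotation_summary.tsv`,
#' `cohort_table.tsv` and a `manifest.yaml` (echoing the configuration)
#' under `paths$out_dir`. Inputs are a sample sheet, a directory of
#' per-sample Bismark coverage files named `<sample_id>.cov`, and BED
#' tracks for genes/exons/islands. Deterministic given the configuration
#' and inputs; any stage error aborts with the stage name.
#'
#' @param config nested list from [runConfig()] / [readRunConfig()].
#' @return Invisibly, a list with the experiment, results, dmrs,
#'   annotation, summaries and the QC report.
#' @export
runPipeline <- function(config) {
    p <- config$paths
    for (need in c("sample_sheet", "coverage_dir", "out_dir"))
        if (is.null(p[[need]])) stop("config$paths$", need, " is required")
    dir.create(p$out_dir, recursive = TRUE, showWarnings = FALSE)
    stage <- function(name, expr) {
        .stageLog(name, "...")
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    samples <- stage("read", readSampleSheet(p$sample_sheet))
    obsList <- stage("read", {
        files <- file.path(p$coverage_dir, paste0(samples$sample_id, ".cov"))
        miss <- !file.exists(files)
        if (any(miss)) stop("missing coverage file(s): ",
                            paste(basename(files[miss]), collapse = ", "))
        stats::setNames(lapply(files, readBismarkCov), samples$sample_id)
    })
    me <- stage("assemble", assembleMatrix(obsList, samples))
    me <- stage("qc", {
        me <- filterLowCoverage(me, config$qc$min_reads)
        filterFewSamples(me, config$qc$min_samples)
    })
    report <- qcReport(me)
    .stageLog("qc", report@nSitesOut, " of ", report@nSitesIn,
              " sites retained")
    if (nrow(me) == 0L) {
        writeLines(yaml::as.yaml(qcReportAsList(report)),
                   file.path(p$out_dir, "qc_report.yaml"))
        warning("no sites survive QC; writing QC report only")
        return(invisible(list(experiment = me, qc = report)))
    }
    me <- stage("levels", if (isTRUE(config$smoothing$enabled))
        smoothLevels(me, config$smoothing$window_bp,
                     config$smoothing$min_sites, config$smoothing$max_gap_bp)
    else rawLevels(me))
    results <- stage("ewas", runEwas(
        me, covariates = config$association$covariates,
        alphaGW = config$association$alpha_gw,
        scale = config$association$scale))
    dmrs <- stage("dmr", callDmrs(
        results, sigThreshold = config$dmr$sig_threshold,
        minLen = config$dmr$min_len, minSig = config$dmr$min_sig,
        minFrac = config$dmr$min_frac, maxGap = config$dmr$max_gap))
    annot <- NULL; annSummary <- NULL
    if (!is.null(p$genes_bed) && !is.null(p$islands_bed)) {
        gt <- stage("annotate", readGeneTrack(p$genes_bed, p$exons_bed))
        islands <- stage("annotate", readBedTrack(p$islands_bed))
        annot <- stage("annotate", annotateSites(results, gt, islands))
        annSummary <- annotationSummary(annot, config$association$p_cut)
        dmrs <- stage("annotate", annotateDmr(dmrs, gt))
    }
    tally <- directionTally(results, config$association$p_cut)
    cohort <- cohortTable(samples)
    params <- list(qc_min_reads = config$qc$min_reads,
                   qc_min_samples = config$qc$min_samples,
                   smoothing = if (isTRUE(config$smoothing$enabled))
                       "smoothed" else "raw",
                   alpha_gw = config$association$alpha_gw,
                   scale = config$association$scale)
    stage("write", {
        writeResultsTable(if (is.null(annot)) results else annot,
                          file.path(p$out_dir, "results.tsv"), params)
        writeBed(dmrs, file.path(p$out_dir, "dmrs.bed"),
                 params = config$dmr)
        writeLines(yaml::as.yaml(qcReportAsList(report)),
                   file.path(p$out_dir, "qc_report.yaml"))
        if (!is.null(annSummary))
            writeResultsTable(annSummary,
                              file.path(p$out_dir, "annotation_summary.tsv"))
        writeCohortTable(cohort, file.path(p$out_dir, "cohort_table.tsv"))
        writeLines(yaml::as.yaml(list(
            config = config,
            n_sites_tested = nrow(results),
            n_gws = sum(results$gw_significant),
            n_dmrs = nrow(dmrs),
            direction_tally = tally)),
            file.path(p$out_dir, "manifest.yaml"))
    })
    .stageLog("done", nrow(results), " sites tested, ",
              sum(results$gw_significant), " genome-wide significant, ",
              nrow(dmrs), " DMRs")
    invisible(list(experiment = me, results = results, dmrs = dmrs,
                   annotation = annot, annotation_summary = annSummary,
                   direction_tally = tally, cohort_table = cohort,
                   qc = report))
}
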