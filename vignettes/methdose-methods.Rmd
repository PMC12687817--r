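---
title: "methdose: models and methods"
author: "methdose authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methdose: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdose)
```

# The scientific problem

Repetitive head impacts (RHI) sustained through contact-sports play have
been linked to neurodegenerative changes in post-mortem brain tissue.
One molecular readout is DNA methylation: reduced representation
bisulfite sequencing (RRBS) measures, at single-CpG resolution, how many
reads carry a methylated versus unmethylated cytosine in each donor.
`methdose` implements a dose-response epigenome-wide association study
(EWAS) for this design: per-CpG regression of methylation level on a
*continuous* exposure — years of contact-sports play — with covariate
adjustment, followed by differentially methylated region (DMR) calling,
genomic/CpG-island annotation and cohort descriptive statistics. Because
the motivating cohort data sit behind controlled access, the package
ships a fully specified generative simulator so every stage is testable
against known ground truth.

# Data model and containers

Counts live in a `MethylExperiment`, an S4 class extending
`RangedSummarizedExperiment` with two integer assays, `meth` and
`total`, over a sites-by-samples grid. A cell that was not profiled in a
sample is `NA` in both assays; this "missing" state is deliberately
distinct from an observed cell with zero coverage (`total == 0`), which
only becomes missing when QC blanks it. Sites are width-1 positions,
1-based, sorted by chromosome then position; the sample sheet (exposure
and covariates) is the `colData`. On disk the package reads and writes
Bismark-style `.cov` files (1-based, `start == end`), the de facto RRBS
interchange format, and BED (0-based half-open) for all interval tracks;
the two coordinate conventions are converted exactly once at the I/O
boundary and round-trip bijectively (asserted in the tests). Strand is
ignored throughout: CpGs on opposite strands are distinct positions.

# Quality control

Two filters, applied in a fixed order:

1. **Coverage filter** (`filterLowCoverage`, default `minReads = 10`):
   any per-sample observation with fewer than 10 reads is blanked. The
   threshold is interpreted per cell, not per site aggregate — the
   companion sample-count filter only makes sense if low-coverage
   observations first become "unprofiled".
2. **Sample-count filter** (`filterFewSamples`, default
   `minSamples = 10`): sites profiled in fewer than 10 samples after
   step 1 are dropped.

Both comparisons are strict (`< 10` removed, `>= 10` kept), both
thresholds configurable, and both filters idempotent. A `QCReport`
records every removal.

# Level estimation and smoothing

`rawLevels()` is the passthrough estimator `meth/total`.
`smoothLevels()` is a kernel-weighted coverage-ratio smoother: for each
sample and site the level is `sum(w_k meth_k) / sum(w_k total_k)` over
neighbours within a window, with tricube weights in genomic distance.
The half-width is `windowBp/2` (default 1000 bp), widened where needed
to cover at least `minSites` CpGs (default 70, capped at what the local
block offers); windows never cross chromosomes and break at gaps above
`maxGapBp` (default 10 kb) so no strength is borrowed across
unsequenced deserts. This estimator is a deliberate simplification of
local-likelihood smoothers for bisulfite data: it keeps their key
behaviours — coverage weighting, locality, guaranteed `[0,1]` range,
exact constant preservation — with far less machinery, and the pipeline
can run entirely unsmoothed, which is also the default. No attempt is
made to match any published smoother numerically.

# The association model

At each retained CpG, ordinary least squares of

```
level ~ intercept + years_of_play + age_at_death + smoking_history
```

on the non-missing samples; the reported slope, SE, t and two-sided
p-value (t distribution, `n_used - p` df) are for the years-of-play
coefficient, and its sign gives the direction: *hypomethylation* for
negative slopes (methylation decreasing with increasing play),
*hypermethylation* for positive. Covariates are centred internally for
numerical stability, which changes neither slope nor p. Genome-wide
significance uses the Bonferroni threshold for an assumed one million
independent CpG sites, `0.05 / 1e6 = 5e-8`, compared strictly
(`p < 5e-8`; equality is not significant — an arbitrary but documented
choice). Degenerate sites (zero outcome variance, rank-deficient
design, too few observations) carry `p = NA` and are excluded from
tallies and DMR input, because their p-values are undefined.

Two outcome scales are offered, since the appropriate scale is a
genuinely open choice: proportions (the default — levels as emitted by
the estimator) and `scale = "logit"`, the empirical logit
`log((meth+0.5)/(unmeth+0.5))`, which matches the simulator's
ground-truth slope units and is the scale used by the recovery tests.
No per-site coverage weighting is applied in the OLS (coverage already
informs smoothing); a weighted mode is left as future work.

Implementation note: sites sharing a missingness pattern are fitted in
one QR decomposition (grouped normal equations), so a 5,000-site scan
at n = 89 takes seconds; correctness is pinned to an independently
coded normal-equations oracle at 1e-10 in the tests.

# DMR calling

A region qualifies when, on a span whose ends coincide with significant
member CpGs: length (`end - start + 1`, 1-based inclusive) is at least
100 bp; at least 3 member CpGs are significant; and *strictly more*
than 80% of all retained CpGs inside the span are significant (exactly
80% is rejected — the wording "over 80%" is taken literally, as is
"≥ 100 bp"). "Significant" defaults to the genome-wide 5e-8 but is
configurable. The criteria define regions but not an algorithm, so the
construction is the package's own: candidate spans are scanned inside
gap-delimited blocks (no inter-CpG gap above `maxGap = 250` bp, a
configurable choice — no published gap cap exists for this rule),
reduced to maximal qualifying intervals, and remaining overlaps
resolved preferring more significant CpGs, then longer spans, then
leftmost start, yielding a deterministic, disjoint set. An exhaustive
brute-force enumerator (`bruteForceDmrs`) written as naively as
possible is shipped alongside and the two are compared
region-for-region on random instances — this oracle equivalence is the
module's core test. Every emitted region is additionally re-checked
against the criteria by an assertion independent of the construction
path.

# Annotation

Each site gets exactly one category per axis. Genic axis, priority
`promoter > 1to5kb_upstream > exon > intron > intergenic`, with the
promoter as the strand-aware 1 kb window upstream of the TSS and
`1to5kb_upstream` the next 4 kb; CGI axis `island / shore / shelf /
open_sea` with 2 kb shores and 2-4 kb shelves. The paper trail for
these widths is conventional (UCSC/annotatr-style), since no standard
defines them precisely; all are arguments. Gene tracks supply one TSS
per gene model; isoform resolution is the track-builder's concern. DMRs
are annotated with every gene whose body or promoter overlaps the span.
Interval logic is `GenomicRanges` throughout, cross-checked against
naive all-pairs scanning in the tests.

# Cohort statistics

`cohortTable()` renders a clinical-style summary: mean (SD) per group
with Welch's two-tailed t-test for continuous variables (Welch rather
than pooled because exposed/control groups are typically very unequal,
e.g. 19 vs 70; pooled available behind a flag), and % (n) with
Pearson's chi-squared without continuity correction for binaries.
Percentages round half-even. Published tables of this kind sometimes
use exact or corrected variants without saying so; for that reason no
printed p-value from any particular cohort table is treated as a
reference value anywhere in this package.

# The simulator: what it emulates, and what it does not

`simConfig()` defaults encode the emulated study conditions: 89 donors,
21.3% exposed, exposed years uniform integers on 2-19, age at death ~
Normal(84, 10.2) truncated at 40, smoking prevalence 0.36. Counts:
negative-binomial coverage (mean 30, size 4 — overdispersed around the
5-30x depths typical of RRBS), beta-binomial methylated counts with
intra-class correlation `rho = 0.05` (rho = 0 degenerates to binomial,
tested), per-cell missingness 5%. Effects: an *exact*
without-replacement sample of `round(fracEffectSites * nSites)` sites
(so truth counts are deterministic and testable) receives half-normal
slopes on the logit scale, negative with probability 0.707 — the
hypo/hyper sign split the pipeline's direction tally should recover.
Baseline levels are Beta(2, 2): intermediate methylation, where a
logit-linear dose response is identifiable at realistic coverage.

Known departures from real RRBS, by design:

* Real genome-wide methylation is strongly bimodal (most CpGs near 0 or
  1); Beta(2, 2) concentrates mass at intermediate levels. Passing
  recovery tests therefore speak to the estimator's behaviour where
  dose-response signal is measurable, not to saturated sites, where any
  level-scale regression has little power.
* Exposed years are uniform on the printed 2-19 range; the resulting
  mean (~10.5) deliberately does not match any empirical cohort mean
  (~6), which would require a skewed distribution the source does not
  specify.
* Age/smoking nuisance coefficients default to zero so the null is
  clean for type-I-error studies; confounding is switched on explicitly
  in the covariate-adjustment tests.
* Coverage is independent of methylation state and position; no
  fragment-level or strand structure is simulated.
* Effect sites are placed uniformly at random, so they rarely form the
  dense runs a DMR needs; the DMR caller is therefore validated by
  exhaustive-oracle equivalence on constructed instances rather than by
  recovery from this generator.

Randomness is split into one stream per stage (cohort, landscape,
counts), seeded `seed + offset`, so changing `nSites` never perturbs
the cohort; with a fixed seed, on-disk datasets are byte-identical
across runs (no timestamps anywhere in output headers).

# Numerical and design choices

* Missingness-pattern-grouped QR for the EWAS; `solve`-based normal
  equations only in the test oracles.
* Tricube weights use `h + 1` in the denominator so a site exactly at
  the window edge gets (negligible but defined) weight; a window
  containing only the focal site reproduces the raw level exactly.
* Smoothed levels are only defined where the focal cell was observed;
  neighbours' missing cells are excluded from the weighted sums.
* The empirical-logit transform uses the 0.5/0.5 count correction; when
  only smoothed proportions are available, `qlogis` of levels clamped
  to [0.01, 0.99] is used instead.
* DMR tie-breaks (more significant sites, then longer, then leftmost)
  make the greedy overlap resolution deterministic; ties below that
  level cannot change the emitted set because candidates are unique by
  (start, end).
* Writers emit full precision (15 significant digits); results tables
  round-trip to 1e-12 relative.

# Problem sizes in the shipped checks

The test-suite simulations use 5,000 null CpGs at n = 89 for type-I
error (nominal 5% hit within 3 Monte-Carlo SEs; Kolmogorov-Smirnov
uniformity at alpha 0.01), 200 effect sites at n = 500 and slope -0.1
logit-units/year for recovery (mean estimate within 10% of truth), 300
sites per slope magnitude for the power-monotonicity check at n = 89,
3,000 sites for the direction-split emulation, and 100 random instances
of up to 200 CpGs for DMR oracle equivalence. These sizes were chosen
as the smallest at which the binomial/Monte-Carlo error bands are
meaningfully narrower than the effects being checked.

# Limitations

* The smoother is not a reimplementation of any published
  local-likelihood method and its outputs are not comparable to one.
* OLS on proportions is heteroskedastic by construction; with coverage
  independent of exposure the classical standard errors remain
  asymptotically valid (and the type-I checks confirm calibration at
  n = 89), but no sandwich/weighted option is provided yet.
* No mixed models, cell-type deconvolution or genomic-control
  correction; the underlying design does not call for them.
* Gene-ontology enrichment and any image-derived analyses are out of
  scope.

# A minimal run

```{r example, eval = FALSE}
cfg <- simConfig(nSamples = 30, nSites = 500, seed = 7)
dir <- tempfile()
simulateDataset(cfg, dir)

run <- runPipeline(runConfig(list(paths = list(
    sample_sheet = file.path(dir, "sample_sheet.tsv"),
    coverage_dir = file.path(dir, "coverage"),
    genes_bed    = file.path(dir, "genes.bed"),
    exons_bed    = file.path(dir, "exons.bed"),
    islands_bed  = file.path(dir, "islands.bed"),
    out_dir      = file.path(dir, "out")))))

head(run$results)
run$direction_tally
```
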