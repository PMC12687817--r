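#' @rdname filterLowCoverage
#' @export
setGeneric("filterLowCoverage",
           function(object, minReads = 10L) standardGeneric("filterLowCoverage"))

#' @rdname filterFewSamples
#' @export
setGeneric("filterFewSamples",
           function(object, minSamples = 10L) standardGeneric("filterFewSamples"))

#' @rdname qcReport
#' @export
setGeneric("qcReport", function(object) standardGeneric("qcReport"))

#' @rdname rawLevels
#' @export
setGeneric("rawLevels", function(object) standardGeneric("rawLevels"))

#' @rdname smoothLevels
#' @export
setGeneric("smoothLevels",
           function(object, windowBp = 1000L, minSites = 70L,
                    maxGapBp = 10000L) standardGeneric("smoothLevels"))

#' @rdname methReads
#' @export
setGeneric("methReads", function(object) standardGeneric("methReads"))

#' @rdname methReads
#' @export
setGeneric("totalReads", function(object) standardGeneric("totalReads"))

#' @rdname methReads
#' @export
setGeneric("methLevels", function(object) standardGeneric("methLevels"))

#' @rdname methReads
#' @export
setGeneric("siteTable", function(object) standardGeneric("siteTable"))

#' @rdname runEwas
#' @export
setGeneric("runEwas",
           function(object, samples = NULL,
                    covariates = c("age_at_death", "smoking_history"),
                    alphaGW = 5e-8, scale = c("proportion", "logit"))
               standardGeneric("runEwas"))
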