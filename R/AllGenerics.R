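#' @rdname IgASeqExperiment-accessors
#' @export
setGeneric("igaPosAbundance", function(x) standardGeneric("igaPosAbundance"))

#' @rdname IgASeqExperiment-accessors
#' @export
setGeneric("igaNegAbundance", function(x) standardGeneric("igaNegAbundance"))

#' @rdname IgASeqExperiment-accessors
#' @export
setGeneric("presortAbundance", function(x) standardGeneric("presortAbundance"))

#' @rdname IgASeqExperiment-accessors
#' @export
setGeneric("posFractionSizes", function(x) standardGeneric("posFractionSizes"))

#' @rdname IgASeqExperiment-accessors
#' @export
setGeneric("negFractionSizes", function(x) standardGeneric("negFractionSizes"))

#' @rdname IgASeqExperiment-accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname IgASeqExperiment-accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname normalizeAbundances
#' @export
setGeneric("normalizeAbundances", function(x, ...)
    standardGeneric("normalizeAbundances"))

#' @rdname IgAScoreMatrix-accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname IgAScoreMatrix-accessors
#' @export
setGeneric("scoreMethod", function(x) standardGeneric("scoreMethod"))

#' @rdname IgAScoreMatrix-accessors
#' @export
setGeneric("pseudoCount", function(x) standardGeneric("pseudoCount"))

#' @rdname IgAScoreMatrix-accessors
#' @export
setGeneric("isScaled", function(x) standardGeneric("isScaled"))

#' @rdname igaScore
#' @export
setGeneric("igaScore", function(x, method, ...) standardGeneric("igaScore"))

#' @rdname IgASeqSimulation-accessors
#' @export
setGeneric("trueBindingMeans", function(x) standardGeneric("trueBindingMeans"))

#' @rdname IgASeqSimulation-accessors
#' @export
setGeneric("experiment", function(x) standardGeneric("experiment"))
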