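#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   assayNames colData
NULL

.ENTITIES <- c("presort", "igapos", "iganeg")
.SCORE_METHODS <- c("palm", "kau", "igapos_prob", "iganeg_prob", "prob_ratio")
.SUM_TOL <- 1e-6

#' IgASeqExperiment: container for one IgA-Seq experiment
#'
#' An `IgASeqExperiment` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' and holds the taxa-by-sample relative-abundance tables of a single IgA-Seq
#' experiment as assays named `"presort"`, `"igapos"` and `"iganeg"`. The
#' pre-sort assay describes the whole community before sorting; the `igapos`
#' and `iganeg` assays describe the IgA-bound and unbound sorted fractions.
#' Per-sample flow-cytometry gate proportions (the fraction of sorted
#' bacteria falling in each gate) live in `colData` columns `pos_size` and
#' `neg_size`, and an optional two-level grouping in column `group`.
#'
#' Only the `igapos` assay is mandatory: each scoring method declares which
#' of the other components it needs. All present assays share one taxon set
#' (rows) and one sample set (columns); the constructor aligns inputs to the
#' union of taxa (zero-filling taxa unobserved in a table, since an
#' unobserved taxon legitimately has relative abundance zero) and the
#' intersection of samples (a sample missing a fraction cannot be scored).
#'
#' @section Validity:
#' All abundance values must be finite and non-negative. When the object is
#' flagged normalized (see [isNormalized()]), every sample column of every
#' assay must sum to 1 within `1e-6`, except all-zero columns, which are
#' permitted so that empty sorted fractions are retained rather than
#' silently dropped. Fraction sizes must lie in `[0, 1]` and, where both
#' gates are recorded, `pos_size + neg_size <= 1` (the gates capture
#' disjoint tails of the IgA-staining distribution).
#'
#' @seealso [IgASeqExperiment()] for construction from matrices or files,
#'   [igaScore()] for scoring.
#' @export
setClass("IgASeqExperiment", contains = "SummarizedExperiment")

setValidity("IgASeqExperiment", function(object) {
    msgs <- character()
    an <- assayNames(object)
    if (!all(an %in% .ENTITIES))
        msgs <- c(msgs, sprintf("assay names must be among %s",
                                paste(.ENTITIES, collapse = ", ")))
    if (!"igapos" %in% an)
        msgs <- c(msgs, "an 'igapos' assay is required")
    if (anyDuplicated(rownames(object)))
        msgs <- c(msgs, "taxon identifiers (rownames) must be unique")
    if (anyDuplicated(colnames(object)))
        msgs <- c(msgs, "sample identifiers (colnames) must be unique")
    for (nm in an) {
        a <- assay(object, nm)
        if (anyNA(a) || any(!is.finite(a)))
            msgs <- c(msgs, sprintf("assay '%s' contains NA/non-finite values", nm))
        else if (any(a < 0))
            msgs <- c(msgs, sprintf("assay '%s' contains negative values", nm))
        else if (isTRUE(metadata(object)$normalized)) {
            cs <- colSums(a)
            bad <- abs(cs - 1) > .SUM_TOL & cs != 0
            if (any(bad))
                msgs <- c(msgs, sprintf(
                    "assay '%s': sample(s) %s do not sum to 1",
                    nm, paste(colnames(object)[bad], collapse = ", ")))
        }
    }
    cd <- colData(object)
    for (sz in c("pos_size", "neg_size")) {
        if (sz %in% names(cd)) {
            v <- cd[[sz]]
            if (any(!is.na(v) & (v < 0 | v > 1)))
                msgs <- c(msgs, sprintf("%s values must lie in [0, 1]", sz))
        }
    }
    if (all(c("pos_size", "neg_size") %in% names(cd))) {
        tot <- cd$pos_size + cd$neg_size
        if (any(!is.na(tot) & tot > 1 + .SUM_TOL))
            msgs <- c(msgs, "pos_size + neg_size exceeds 1 for some sample(s)")
    }
    if ("group" %in% names(cd) && !is.character(cd$group))
        msgs <- c(msgs, "group labels must be character")
    if (length(msgs)) msgs else TRUE
})

#' IgAScoreMatrix: taxa-by-sample binding scores from one method
#'
#' Holds the score matrix produced by one IgA-Seq scoring method together
#' with the provenance needed to interpret it: the method tag, the
#' pseudo count used (if the method uses one), and whether capping
#' (posterior probabilities) or scaling (probability ratio) was applied.
#' Cells that could not be scored -- a taxon with zero abundance in both
#' sorted fractions carries no information about binding -- hold `NA`,
#' which downstream statistics exclude pairwise; `NA` is never conflated
#' with a score of 0.
#'
#' @section Score bounds:
#' Capped posterior probabilities are validated to lie in `[0, 1]` and
#' scaled probability ratios in `[-1, 1]`; both bounds are consequences of
#' the formulas. The Kau index lies in `[-1, 1]` whenever both shifted
#' abundances `x + c` stay at or below 1, which holds for any pseudo count
#' below the smallest nonzero abundance provided no fraction column is a
#' single-taxon community; the marginal overshoot in that corner case is
#' reported as computed rather than clamped, so no hard bound is enforced
#' by the class.
#'
#' @slot scores numeric matrix, taxa as rows, samples as columns.
#' @slot method one of `"palm"`, `"kau"`, `"igapos_prob"`, `"iganeg_prob"`,
#'   `"prob_ratio"`.
#' @slot pseudoCount the pseudo count `c` used, or `NA` for methods that
#'   take none.
#' @slot scaled for `"prob_ratio"`, whether scores were divided by the
#'   scaler `log2((1 + c) / c)` that bounds them in `[-1, 1]`.
#' @slot capped for the posterior probabilities, whether the denominator was
#'   floored at the numerator so estimates stay in `[0, 1]`.
#' @export
setClass("IgAScoreMatrix",
    representation(scores = "matrix", method = "character",
                   pseudoCount = "numeric", scaled = "logical",
                   capped = "logical"),
    prototype(pseudoCount = NA_real_, scaled = FALSE, capped = FALSE))

setValidity("IgAScoreMatrix", function(object) {
    msgs <- character()
    if (length(object@method) != 1L || !object@method %in% .SCORE_METHODS)
        msgs <- c(msgs, sprintf("method must be one of %s",
                                paste(.SCORE_METHODS, collapse = ", ")))
    s <- object@scores
    if (!is.numeric(s))
        msgs <- c(msgs, "scores must be a numeric matrix")
    if (anyDuplicated(rownames(s)) || anyDuplicated(colnames(s)))
        msgs <- c(msgs, "taxon and sample identifiers must be unique")
    ok <- s[!is.na(s)]
    tol <- 1e-9
    if (length(object@method) == 1L && length(ok)) {
        ## no bound is enforced for the Kau index: its [-1, 1] range is
        ## guaranteed only while every shifted abundance stays <= 1, which a
        ## single-taxon fraction column narrowly violates
        if (object@method %in% c("igapos_prob", "iganeg_prob") &&
            isTRUE(object@capped) && any(ok < -tol | ok > 1 + tol))
            msgs <- c(msgs, "capped probabilities must lie in [0, 1]")
        if (object@method == "prob_ratio" && isTRUE(object@scaled) &&
            any(ok < -1 - tol | ok > 1 + tol))
            msgs <- c(msgs, "scaled probability ratios must lie in [-1, 1]")
    }
    if (length(msgs)) msgs else TRUE
})

#' IgASeqSimulation: a simulated IgA-Seq experiment with known ground truth
#'
#' Couples a simulated [IgASeqExperiment] with the per-species true mean
#' binding values that generated it and the configuration used, so that
#' score benchmarks can compare estimates against a known answer.
#'
#' @slot experiment the simulated [IgASeqExperiment].
#' @slot trueBindingMeans named numeric; each species' mean of the normal
#'   distribution its per-bacterium IgA-binding values were drawn from.
#'   These are arbitrary units expressing relative binding between species.
#' @slot config list of the simulation parameters used (see
#'   [simulateIgASeq()]).
#' @export
setClass("IgASeqSimulation",
    representation(experiment = "IgASeqExperiment",
                   trueBindingMeans = "numeric", config = "list"))

setValidity("IgASeqSimulation", function(object) {
    msgs <- character()
    tb <- object@trueBindingMeans
    if (any(tb <= 0)) msgs <- c(msgs, "true binding means must be positive")
    if (length(tb) != nrow(object@experiment))
        msgs <- c(msgs, "one binding mean per species is required")
    if (length(msgs)) msgs else TRUE
})

#' FilterReport: audit trail of a filtering step
#'
#' Records what a QC filtering operation removed or zeroed so analyses stay
#' auditable: which taxa were dropped by blank-control matching or by the
#' abundance threshold, how many fraction cells the pre-sort presence
#' screen zeroed, and what share of the total pre-filter observation mass
#' survived.
#'
#' @slot taxaRemovedBlank taxa dropped because they appeared in the blank
#'   control.
#' @slot taxaRemovedThreshold taxa dropped because no abundance anywhere
#'   reached the threshold.
#' @slot cellsZeroedPresortScreen count of fraction cells zeroed because the
#'   taxon was absent pre-sort in that sample.
#' @slot fractionRetained proportion of total pre-filter abundance mass
#'   retained, in `[0, 1]`.
#' @slot thresholdUsed the abundance threshold applied (`NA` if none).
#' @export
setClass("FilterReport",
    representation(taxaRemovedBlank = "character",
                   taxaRemovedThreshold = "character",
                   cellsZeroedPresortScreen = "integer",
                   fractionRetained = "numeric",
                   thresholdUsed = "numeric"),
    prototype(taxaRemovedBlank = character(), taxaRemovedThreshold = character(),
              cellsZeroedPresortScreen = 0L, fractionRetained = 1,
              thresholdUsed = NA_real_))

setValidity("FilterReport", function(object) {
    if (object@fractionRetained < 0 || object@fractionRetained > 1)
        "fractionRetained must lie in [0, 1]"
    else TRUE
})
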