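## Contamination screening for sorted-fraction abundance tables. Sorted
## fractions are low-biomass material, so reagent and index-hopping
## contaminants loom far larger there than in the pre-sort sample; the
## recipe is blank-control removal, then an abundance threshold, then a
## per-sample pre-sort presence screen. Tables are renormalized after
## every step so downstream scores still see relative abundances.

.applyToAssays <- function(x, f) {
    for (nm in assayNames(x))
        assay(x, nm, withDimnames = FALSE) <- f(assay(x, nm), nm)
    x
}

.renormalizeAssays <- function(x) {
    .applyToAssays(x, function(m, nm)
        .normalizeColumns(m, sprintf("assay '%s'", nm), allowEmpty = TRUE))
}

.totalMass <- function(x) {
    sum(vapply(assays(x), sum, numeric(1)))
}

#' Remove taxa observed in a blank control
#'
#' Drops the listed taxa from every table and renormalizes. Taxa seen in a
#' no-sample extraction/library blank are reagent or cross-over
#' contaminants; their reads are removed wholesale.
#'
#' @param x an [IgASeqExperiment].
#' @param blankTaxa character vector of taxon identifiers observed in the
#'   blank control; identifiers not present in `x` are ignored.
#' @return list with elements `experiment` (the filtered
#'   [IgASeqExperiment]) and `report` (a [FilterReport]).
#' @export
removeBlankTaxa <- function(x, blankTaxa) {
    stopifnot(is(x, "IgASeqExperiment"), is.character(blankTaxa))
    hit <- intersect(rownames(x), blankTaxa)
    keep <- setdiff(rownames(x), hit)
    if (length(keep) == 0L)
        stop("blank-control list removes every taxon")
    before <- .totalMass(x)
    out <- x[keep, ]
    out <- .renormalizeAssays(out)
    validObject(out)
    report <- new("FilterReport", taxaRemovedBlank = hit,
                  fractionRetained = .totalMass(x[keep, ]) / before)
    list(experiment = out, report = report)
}

#' Apply a minimum-abundance threshold
#'
#' Zeroes every abundance value below `threshold` in every table, cell by
#' cell, drops taxa that become all-zero across all tables and samples,
#' and renormalizes. Cell-wise zeroing handles the sample-wise nature of
#' sorted-fraction contamination: a contaminant can be predominant in one
#' sample's fraction yet absent elsewhere. The report records the fraction
#' of total pre-filter observation mass retained, supporting a threshold
#' choice that removes rare taxa while retaining the large majority of
#' observations.
#'
#' @param x an [IgASeqExperiment].
#' @param threshold abundance below which values are zeroed; in `[0, 1)`.
#' @return list with `experiment` and `report` as in [removeBlankTaxa()].
#' @export
filterMinAbundance <- function(x, threshold) {
    stopifnot(is(x, "IgASeqExperiment"), is.numeric(threshold),
              length(threshold) == 1L, threshold >= 0, threshold < 1)
    before <- .totalMass(x)
    zeroed <- .applyToAssays(x, function(m, nm) {
        m[m < threshold] <- 0
        m
    })
    allZero <- Reduce(`&`, lapply(assays(zeroed), function(m)
        rowSums(m) == 0))
    dropped <- rownames(x)[allZero]
    if (all(allZero))
        stop("threshold removes every taxon")
    kept <- zeroed[!allZero, ]
    retained <- if (before > 0) .totalMass(kept) / before else 1
    out <- .renormalizeAssays(kept)
    validObject(out)
    report <- new("FilterReport", taxaRemovedThreshold = dropped,
                  fractionRetained = retained, thresholdUsed = threshold)
    list(experiment = out, report = report)
}

#' Screen fractions against pre-sort presence
#'
#' Per sample, any taxon with zero pre-sort abundance has its IgA+ and
#' IgA- abundances set to zero, and the fraction columns are renormalized.
#' A taxon that was not observed in a mouse's own pre-sort community but
#' appears in its sorted fractions is contamination (the fractions are
#' subsets of the pre-sort community); the screen applies per sample
#' rather than dropping taxa globally, since a taxon can be genuine in one
#' animal and contaminant in another. Idempotent.
#'
#' @param x an [IgASeqExperiment] carrying a presort table.
#' @return list with `experiment` and `report` as in [removeBlankTaxa()].
#' @export
screenAgainstPresort <- function(x) {
    stopifnot(is(x, "IgASeqExperiment"))
    pre <- presortAbundance(x)
    if (is.null(pre))
        stop("pre-sort screen requires a presort table")
    before <- .totalMass(x)
    zeroedCells <- 0L
    out <- .applyToAssays(x, function(m, nm) {
        if (nm == "presort") return(m)
        hit <- pre == 0 & m > 0
        zeroedCells <<- zeroedCells + sum(hit)
        m[hit] <- 0
        m
    })
    retained <- if (before > 0) .totalMass(out) / before else 1
    out <- .renormalizeAssays(out)
    validObject(out)
    report <- new("FilterReport", cellsZeroedPresortScreen = zeroedCells,
                  fractionRetained = retained)
    list(experiment = out, report = report)
}

#' Survey candidate abundance thresholds
#'
#' For each candidate threshold, reports how many taxa and what fraction
#' of the total observation mass would survive [filterMinAbundance()].
#' Threshold choice stays a human decision; this table is the evidence it
#' rests on.
#'
#' @param x an [IgASeqExperiment].
#' @param thresholds ascending numeric vector of candidate thresholds.
#' @return data.frame with columns `threshold`, `taxa_retained`,
#'   `mass_retained`.
#' @export
thresholdReport <- function(x, thresholds) {
    stopifnot(is(x, "IgASeqExperiment"), is.numeric(thresholds),
              !is.unsorted(thresholds), all(thresholds >= 0),
              all(thresholds < 1))
    before <- .totalMass(x)
    rows <- lapply(thresholds, function(th) {
        masses <- lapply(assays(x), function(m) {
            m[m < th] <- 0
            m
        })
        allZero <- Reduce(`&`, lapply(masses, function(m) rowSums(m) == 0))
        data.frame(threshold = th,
                   taxa_retained = sum(!allZero),
                   mass_retained = if (before > 0)
                       sum(vapply(masses, sum, numeric(1))) / before else 1)
    })
    do.call(rbind, rows)
}

setMethod("show", "FilterReport", function(object) {
    cat("FilterReport\n")
    if (length(object@taxaRemovedBlank))
        cat("  removed (blank control):",
            paste(object@taxaRemovedBlank, collapse = ", "), "\n")
    if (length(object@taxaRemovedThreshold))
        cat("  removed (threshold", format(object@thresholdUsed), "):",
            paste(object@taxaRemovedThreshold, collapse = ", "), "\n")
    if (object@cellsZeroedPresortScreen > 0L)
        cat("  cells zeroed by pre-sort screen:",
            object@cellsZeroedPresortScreen, "\n")
    cat(sprintf("  observation mass retained: %.4f\n",
                object@fractionRetained))
})
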