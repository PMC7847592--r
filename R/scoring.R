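## The four IgA-Seq binding scores. All operate cell-wise on aligned
## taxa-by-sample relative-abundance matrices; cells that carry no binding
## information (zero abundance in both sorted fractions) are NA, never 0.

.checkAligned <- function(a, b, na, nb) {
    if (!identical(dimnames(a), dimnames(b)))
        stop(sprintf("'%s' and '%s' must share identical taxa and samples; align them via IgASeqExperiment()",
                     na, nb), call. = FALSE)
}

.checkSizes <- function(sizes, samples, what) {
    if (is.null(names(sizes)))
        stop(sprintf("'%s' must be a named vector", what), call. = FALSE)
    miss <- setdiff(samples, names(sizes))
    if (length(miss))
        stop(sprintf("'%s' is missing sample(s): %s", what,
                     paste(miss, collapse = ", ")), call. = FALSE)
    if (any(sizes < 0 | sizes > 1))
        stop(sprintf("'%s' must hold proportions in [0, 1]", what),
             call. = FALSE)
    sizes[samples]
}

#' Default pseudo count from observed abundances
#'
#' The pseudo count `c` guards ratios and logarithms against zero
#' abundances. It is chosen of a similar magnitude to, but strictly below,
#' the smallest nonzero abundance observed in any supplied table: the
#' largest power of ten strictly less than that minimum. With a smallest
#' abundance of 2.3e-3 this returns 1e-3; with exactly 1e-6 it returns
#' 1e-7 (strictly below).
#'
#' @param ... one or more taxa-by-sample abundance matrices, or a single
#'   [IgASeqExperiment] (all its tables are scanned).
#' @return a single power of ten.
#' @export
defaultPseudoCount <- function(...) {
    tabs <- list(...)
    if (length(tabs) == 1L && is(tabs[[1L]], "IgASeqExperiment"))
        tabs <- assays(tabs[[1L]])
    vals <- unlist(lapply(tabs, function(m) m[m > 0]), use.names = FALSE)
    if (length(vals) == 0L)
        stop("no nonzero abundance found in the supplied tables")
    m <- min(vals)
    p <- 10^floor(log10(m))
    if (p >= m) p <- p / 10
    p
}

.newScoreMatrix <- function(values, method, pseudoCount = NA_real_,
                            scaled = FALSE, capped = FALSE) {
    new("IgAScoreMatrix", scores = values, method = method,
        pseudoCount = pseudoCount, scaled = scaled, capped = capped)
}

#' Palm index: ratio of sorted-fraction abundances
#'
#' For taxon i in sample j the Palm index is the ratio of its relative
#' abundance in the IgA+ fraction to that in the IgA- fraction. When the
#' IgA- abundance is zero the pseudo count is added to the denominator
#' (only then) to avoid division by zero. Taxa absent from both fractions
#' are not scored (`NA`).
#'
#' @param igapos,iganeg aligned, normalized taxa-by-sample abundance
#'   matrices of the two sorted fractions.
#' @param pseudoCount positive pseudo count `c`; see
#'   [defaultPseudoCount()].
#' @return an [IgAScoreMatrix] with method `"palm"`.
#' @export
palmIndex <- function(igapos, iganeg, pseudoCount) {
    .checkAligned(igapos, iganeg, "igapos", "iganeg")
    if (!is.numeric(pseudoCount) || length(pseudoCount) != 1L ||
        pseudoCount <= 0)
        stop("'pseudoCount' must be a single positive number")
    denom <- ifelse(iganeg == 0, iganeg + pseudoCount, iganeg)
    out <- igapos / denom
    out[igapos == 0 & iganeg == 0] <- NA_real_
    .newScoreMatrix(out, "palm", pseudoCount)
}

#' Kau index: centred log-contrast of sorted-fraction abundances
#'
#' The Kau index contrasts the log-transformed IgA+ and IgA- abundances
#' relative to their total:
#' `-(log(pos + c) - log(neg + c)) / (log(pos + c) + log(neg + c))`.
#' The log transform makes scores comparable between rare and common taxa,
#' and the centring bounds them in `[-1, 1]` with positive values marking
#' taxa enriched in the IgA+ fraction. The score does not depend on the
#' base of the logarithm (the base cancels between numerator and
#' denominator); natural logarithms are used. Taxa absent from both
#' fractions are not scored; a denominator of exactly zero (possible only
#' when both shifted abundances equal 1) also yields `NA`, with a warning.
#'
#' @inheritParams palmIndex
#' @return an [IgAScoreMatrix] with method `"kau"`.
#' @export
kauIndex <- function(igapos, iganeg, pseudoCount) {
    .checkAligned(igapos, iganeg, "igapos", "iganeg")
    if (!is.numeric(pseudoCount) || length(pseudoCount) != 1L ||
        pseudoCount <= 0)
        stop("'pseudoCount' must be a single positive number")
    lp <- log(igapos + pseudoCount)
    ln <- log(iganeg + pseudoCount)
    den <- lp + ln
    zero <- den == 0
    if (any(zero)) {
        warning("Kau index undefined (zero denominator) for some cell(s); returned NA")
        den[zero] <- NA_real_
    }
    out <- -(lp - ln) / den
    out[igapos == 0 & iganeg == 0] <- NA_real_
    .newScoreMatrix(out, "kau", pseudoCount)
}

.posterior <- function(frac, presort, sizes, cap, fracName) {
    .checkAligned(frac, presort, fracName, "presort")
    sizes <- .checkSizes(sizes, colnames(frac), "sizes")
    num <- sweep(frac, 2, sizes, "*")
    den <- if (cap) pmax(presort, num) else presort
    out <- num / den
    contaminated <- presort == 0 & frac > 0
    if (!cap && any(contaminated)) {
        warning(sprintf(
            "%d cell(s) with zero pre-sort abundance but nonzero %s abundance; not scored (uncapped). Consider pre-sort screening.",
            sum(contaminated), fracName))
        out[contaminated] <- NA_real_
    }
    out[presort == 0 & frac == 0] <- NA_real_
    out
}

#' IgA+ posterior binding probability
#'
#' By Bayes' theorem, the probability that a bacterium is bound to IgA
#' strongly enough to fall in the IgA+ sort gate, given that it belongs to
#' taxon i, is `igapos[i, j] * posSize[j] / presort[i, j]`: the taxon's
#' abundance in the IgA+ fraction (the probability of the taxon given IgA+),
#' times the proportion of sorted bacteria in the IgA+ gate (the prior
#' probability of being IgA+), normalised by the taxon's pre-sort abundance.
#' This estimate is unaffected by the abundances of other taxa, unlike the
#' Palm and Kau indices.
#'
#' Technical biases in amplicon data can make the numerator exceed the
#' pre-sort abundance; with `cap = TRUE` (default) the denominator is
#' floored at the numerator, assigning probability 1 in that case. With
#' `cap = FALSE` the raw ratio is returned (values above 1 possible) and
#' cells with a zero pre-sort abundance but nonzero fraction abundance are
#' not scored, with a warning, since the ratio is undefined. Taxa absent
#' both pre-sort and in the fraction are not scored.
#'
#' @param igapos normalized abundance matrix of the IgA+ fraction.
#' @param presort normalized abundance matrix of the unsorted community.
#' @param posSizes named per-sample proportion of sorted bacteria in the
#'   IgA+ gate.
#' @param cap logical; floor the denominator so probabilities stay in
#'   `[0, 1]`.
#' @return an [IgAScoreMatrix] with method `"igapos_prob"`.
#' @export
igaPosProbability <- function(igapos, presort, posSizes, cap = TRUE) {
    out <- .posterior(igapos, presort, posSizes, cap, "igapos")
    .newScoreMatrix(out, "igapos_prob", capped = cap)
}

#' IgA- posterior probability
#'
#' The converse of [igaPosProbability()]: the probability that a bacterium
#' of taxon i is sufficiently unbound to fall in the IgA- gate, obtained by
#' substituting the IgA- abundances and gate size into the same posterior.
#'
#' @param iganeg normalized abundance matrix of the IgA- fraction.
#' @param negSizes named per-sample proportion of sorted bacteria in the
#'   IgA- gate.
#' @inheritParams igaPosProbability
#' @return an [IgAScoreMatrix] with method `"iganeg_prob"`.
#' @export
igaNegProbability <- function(iganeg, presort, negSizes, cap = TRUE) {
    out <- .posterior(iganeg, presort, negSizes, cap, "iganeg")
    .newScoreMatrix(out, "iganeg_prob", capped = cap)
}

#' IgA probability ratio
#'
#' The log2 ratio of the IgA+ to IgA- posterior-probability numerators:
#' `log2((igapos * posSize + c) / (iganeg * negSize + c))`. Because both
#' posteriors share the pre-sort abundance as denominator it cancels, so
#' the score corrects for pre-sort composition without requiring the
#' pre-sort sample to be sequenced. Positive values mean a bacterium of
#' that taxon is more likely to be found in the IgA+ gate than the IgA-
#' gate. The pseudo count keeps taxa absent from one fraction finite.
#'
#' The attainable range depends on the pseudo count; with `scaled = TRUE`
#' (default) scores are divided by `log2((1 + c) / c)`, the value attained
#' in the extreme case that all sorted bacteria sit in a single fraction
#' and belong to a single taxon, bounding scores in `[-1, 1]`.
#'
#' @param igapos,iganeg aligned normalized abundance matrices of the two
#'   sorted fractions.
#' @param posSizes,negSizes named per-sample gate proportions.
#' @param pseudoCount positive pseudo count `c`.
#' @param scaled logical; divide by the scaler `log2((1 + c) / c)`.
#' @return an [IgAScoreMatrix] with method `"prob_ratio"`.
#' @export
probabilityRatio <- function(igapos, iganeg, posSizes, negSizes, pseudoCount,
                             scaled = TRUE) {
    .checkAligned(igapos, iganeg, "igapos", "iganeg")
    if (!is.numeric(pseudoCount) || length(pseudoCount) != 1L ||
        pseudoCount <= 0)
        stop("'pseudoCount' must be a single positive number")
    posSizes <- .checkSizes(posSizes, colnames(igapos), "posSizes")
    negSizes <- .checkSizes(negSizes, colnames(igapos), "negSizes")
    num <- sweep(igapos, 2, posSizes, "*") + pseudoCount
    den <- sweep(iganeg, 2, negSizes, "*") + pseudoCount
    out <- log2(num / den)
    if (scaled) out <- out / log2((1 + pseudoCount) / pseudoCount)
    out[igapos == 0 & iganeg == 0] <- NA_real_
    .newScoreMatrix(out, "prob_ratio", pseudoCount, scaled = scaled)
}

#' Score an IgA-Seq experiment
#'
#' Single entry point dispatching to the individual scoring functions,
#' checking that the experiment carries the components the chosen method
#' needs: `"palm"` and `"kau"` need both sorted fractions; `"igapos_prob"`
#' needs the IgA+ fraction, the pre-sort table and the IgA+ gate sizes
#' (`"iganeg_prob"` correspondingly); `"prob_ratio"` needs both fractions
#' and both gate sizes, but no pre-sort table.
#'
#' @param x an [IgASeqExperiment]; must be normalized (see
#'   [normalizeAbundances()]).
#' @param method one of `"palm"`, `"kau"`, `"igapos_prob"`,
#'   `"iganeg_prob"`, `"prob_ratio"`.
#' @param pseudoCount pseudo count for the methods that use one; defaults
#'   to [defaultPseudoCount()] over all tables present.
#' @param cap for the posterior probabilities; see [igaPosProbability()].
#' @param scaled for the probability ratio; see [probabilityRatio()].
#' @param ... unused.
#' @return an [IgAScoreMatrix].
#' @rdname igaScore
#' @export
setMethod("igaScore", "IgASeqExperiment", function(x, method,
                                                   pseudoCount = NULL,
                                                   cap = TRUE, scaled = TRUE,
                                                   ...) {
    method <- match.arg(method, .SCORE_METHODS)
    if (!isNormalized(x))
        stop("experiment is not normalized; call normalizeAbundances() first")
    need <- function(component, what) {
        if (is.null(component))
            stop(sprintf("method '%s' requires %s", method, what),
                 call. = FALSE)
        component
    }
    pc <- function() {
        if (is.null(pseudoCount)) defaultPseudoCount(x) else pseudoCount
    }
    switch(method,
        palm = palmIndex(need(igaPosAbundance(x), "the igapos table"),
                         need(igaNegAbundance(x), "the iganeg table"), pc()),
        kau = kauIndex(need(igaPosAbundance(x), "the igapos table"),
                       need(igaNegAbundance(x), "the iganeg table"), pc()),
        igapos_prob = igaPosProbability(
            need(igaPosAbundance(x), "the igapos table"),
            need(presortAbundance(x), "the presort table"),
            need(posFractionSizes(x), "pos_sizes"), cap = cap),
        iganeg_prob = igaNegProbability(
            need(igaNegAbundance(x), "the iganeg table"),
            need(presortAbundance(x), "the presort table"),
            need(negFractionSizes(x), "neg_sizes"), cap = cap),
        prob_ratio = probabilityRatio(
            need(igaPosAbundance(x), "the igapos table"),
            need(igaNegAbundance(x), "the iganeg table"),
            need(posFractionSizes(x), "pos_sizes"),
            need(negFractionSizes(x), "neg_sizes"),
            pc(), scaled = scaled))
})

#' Accessors for IgAScoreMatrix
#'
#' `scores()` returns the taxa-by-sample score matrix (`NA` marks cells
#' that could not be scored); `scoreMethod()` the method tag;
#' `pseudoCount()` the pseudo count used (`NA` when none); `isScaled()`
#' whether a probability ratio was scaled to `[-1, 1]`.
#'
#' @param x an [IgAScoreMatrix].
#' @name IgAScoreMatrix-accessors
NULL

#' @rdname IgAScoreMatrix-accessors
#' @export
setMethod("scores", "IgAScoreMatrix", function(x) x@scores)

#' @rdname IgAScoreMatrix-accessors
#' @export
setMethod("scoreMethod", "IgAScoreMatrix", function(x) x@method)

#' @rdname IgAScoreMatrix-accessors
#' @export
setMethod("pseudoCount", "IgAScoreMatrix", function(x) x@pseudoCount)

#' @rdname IgAScoreMatrix-accessors
#' @export
setMethod("isScaled", "IgAScoreMatrix", function(x) x@scaled)

setMethod("show", "IgAScoreMatrix", function(object) {
    s <- object@scores
    cat(sprintf("IgAScoreMatrix (%s): %d taxa x %d samples\n",
                object@method, nrow(s), ncol(s)))
    if (!is.na(object@pseudoCount))
        cat("  pseudo count:", format(object@pseudoCount), "\n")
    if (object@method == "prob_ratio")
        cat("  scaled:", object@scaled, "\n")
    if (object@method %in% c("igapos_prob", "iganeg_prob"))
        cat("  capped:", object@capped, "\n")
    cat(sprintf("  not scored: %d / %d cells\n", sum(is.na(s)), length(s)))
})
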