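## In-silico IgA-Seq experiments with known ground-truth binding.
##
## Each species carries a mean IgA-binding value; every simulated bacterium
## draws its own binding from a normal distribution around its species mean.
## Gating the pooled binding distribution at fixed thresholds defines the
## IgA+ and IgA- fractions, exactly mirroring how a cytometer gates the
## upper and lower tails of the IgA-staining distribution.

#' Draw per-species mean binding values
#'
#' Species means are `2^X` with `X ~ Exponential(rate)`: the
#' exponentiation spreads the species out so a community holds a few
#' strongly bound species and many weakly bound ones, as observed in real
#' IgA-Seq data. The values are arbitrary units encoding only relative
#' binding between species.
#'
#' @param nSpecies number of species (at least 2).
#' @param rate rate of the exponential draw.
#' @return named numeric vector of length `nSpecies`; all values are at
#'   least 1 because the exponential draw is non-negative.
#' @export
drawSpeciesMeans <- function(nSpecies = 10, rate = 1) {
    stopifnot(nSpecies >= 2, rate > 0)
    stats::setNames(2^stats::rexp(nSpecies, rate),
                    paste0("Species", seq_len(nSpecies)))
}

#' Draw pre-sort community compositions
#'
#' Per sample, `nSpecies` independent log-normal draws normalized to sum
#' to 1, giving right-skewed compositions typical of 16S relative
#' abundances.
#'
#' @param nSpecies,nSamples community and cohort sizes.
#' @param meanlog,sdlog log-normal parameters.
#' @return species-by-sample matrix of relative abundances, columns
#'   summing to 1.
#' @export
drawPresortAbundances <- function(nSpecies = 10, nSamples = 30, meanlog = 0,
                                  sdlog = 1) {
    stopifnot(nSpecies >= 2, nSamples >= 1, sdlog >= 0)
    m <- matrix(stats::rlnorm(nSpecies * nSamples, meanlog, sdlog),
                nrow = nSpecies,
                dimnames = list(paste0("Species", seq_len(nSpecies)),
                                paste0("Sample", seq_len(nSamples))))
    sweep(m, 2, colSums(m), "/")
}

#' Boost one species' abundance and renormalize
#'
#' Models a consistent compositional difference between conditions: a fixed
#' amount of relative abundance is added to one species in each column,
#' after which the column is renormalized to sum to 1. The pairwise ratios
#' of all other species are preserved (they are rescaled uniformly).
#'
#' @param presort species-by-sample matrix of relative abundances.
#' @param speciesIndex row index (or name) of the boosted species.
#' @param addedAbundance non-negative amount added before renormalizing.
#' @return matrix of the same shape, columns summing to 1.
#' @export
applyCaseBoost <- function(presort, speciesIndex, addedAbundance) {
    if (is.character(speciesIndex))
        speciesIndex <- match(speciesIndex, rownames(presort))
    if (is.na(speciesIndex) || speciesIndex < 1 ||
        speciesIndex > nrow(presort))
        stop("'speciesIndex' out of range")
    stopifnot(addedAbundance >= 0)
    presort[speciesIndex, ] <- presort[speciesIndex, ] + addedAbundance
    sweep(presort, 2, colSums(presort), "/")
}

#' Simulate an IgA-Seq experiment with known ground truth
#'
#' Generates a full in-silico IgA-Seq experiment. Per species, a mean
#' binding value is drawn ([drawSpeciesMeans()]); per sample, a pre-sort
#' composition is drawn ([drawPresortAbundances()]). Case samples (the
#' last `nCaseSamples` of the cohort) additionally receive the boost in
#' `caseBoost` to their pre-sort composition, modelling a case-control
#' study with an inherent compositional difference. Then, per sample:
#'
#' 1. `nBacteria` bacteria are assigned to species by a multinomial draw on
#'    the sample's pre-sort composition;
#' 2. each bacterium draws an IgA-binding value from
#'    `Normal(species mean, bindingSd)`;
#' 3. bacteria with binding above `posThreshold` form the IgA+ fraction and
#'    those below `negThreshold` the IgA- fraction, mirroring cytometry
#'    gates on the tails of the pooled binding distribution;
#' 4. fraction sizes are the gated counts over `nBacteria`, and each
#'    fraction's species counts are converted to relative abundances.
#'
#' The observed (multinomial) species counts, not the drawing
#' probabilities, define the pre-sort table, so the three tables share one
#' sampling noise process. A fraction that catches no bacteria in a sample
#' is kept as an all-zero column with a warning rather than dropped, so
#' benchmarks see the failure. One RNG stream drives species means, then
#' abundances, then per-sample binding draws, in that order; set a seed
#' beforehand for reproducibility.
#'
#' @param nSpecies number of species (default 10).
#' @param nSamples total number of samples (default 30).
#' @param nBacteria bacteria profiled per sample (default 100000, a
#'   realistic magnitude for a 16S run).
#' @param bindingSd standard deviation of each species' binding
#'   distribution (default 1).
#' @param posThreshold,negThreshold binding values gating the IgA+ (above)
#'   and IgA- (below) fractions; defaults 4 and 2, cutting the upper and
#'   lower tails of the pooled distribution under the default binding-mean
#'   draw.
#' @param expRate rate of the exponential species-mean draw (default 1).
#' @param abundanceLogmean,abundanceLogsd log-normal parameters of the
#'   pre-sort composition draw (defaults 0 and 1).
#' @param nCaseSamples how many samples (the last ones) are cases
#'   receiving the boost (default 0: no case-control structure).
#' @param caseBoost list or vector with elements `speciesIndex` and
#'   `addedAbundance` (default species `nSpecies`, 0.5).
#' @return an [IgASeqSimulation]; its experiment carries all three tables,
#'   both gate-size vectors, and (when `nCaseSamples > 0`) control/case
#'   group labels.
#' @examples
#' set.seed(42)
#' sim <- simulateIgASeq(nSamples = 4, nBacteria = 1000)
#' trueBindingMeans(sim)
#' igaScore(experiment(sim), "prob_ratio")
#' @export
simulateIgASeq <- function(nSpecies = 10, nSamples = 30, nBacteria = 100000,
                           bindingSd = 1, posThreshold = 4, negThreshold = 2,
                           expRate = 1, abundanceLogmean = 0,
                           abundanceLogsd = 1, nCaseSamples = 0,
                           caseBoost = list(speciesIndex = nSpecies,
                                            addedAbundance = 0.5)) {
    stopifnot(nSpecies >= 2, nSamples >= 1, nBacteria >= 1, bindingSd > 0,
              posThreshold > negThreshold,
              nCaseSamples >= 0, nCaseSamples <= nSamples)
    config <- list(nSpecies = nSpecies, nSamples = nSamples,
                   nBacteria = nBacteria, bindingSd = bindingSd,
                   posThreshold = posThreshold, negThreshold = negThreshold,
                   expRate = expRate, abundanceLogmean = abundanceLogmean,
                   abundanceLogsd = abundanceLogsd,
                   nCaseSamples = nCaseSamples,
                   caseBoost = if (nCaseSamples > 0) caseBoost)

    means <- drawSpeciesMeans(nSpecies, expRate)
    presortProb <- drawPresortAbundances(nSpecies, nSamples, abundanceLogmean,
                                         abundanceLogsd)
    groups <- NULL
    if (nCaseSamples > 0) {
        caseIdx <- seq.int(nSamples - nCaseSamples + 1L, nSamples)
        presortProb[, caseIdx] <- applyCaseBoost(
            presortProb[, caseIdx, drop = FALSE],
            caseBoost$speciesIndex, caseBoost$addedAbundance)
        groups <- stats::setNames(rep("control", nSamples),
                                  colnames(presortProb))
        groups[caseIdx] <- "case"
    }

    presort <- igapos <- iganeg <- presortProb * 0
    posSizes <- negSizes <- stats::setNames(numeric(nSamples),
                                            colnames(presortProb))
    for (j in seq_len(nSamples)) {
        counts <- as.vector(stats::rmultinom(1, nBacteria, presortProb[, j]))
        binding <- stats::rnorm(nBacteria, mean = rep(means, counts),
                                sd = bindingSd)
        species <- rep(seq_len(nSpecies), counts)
        posCounts <- tabulate(species[binding > posThreshold], nSpecies)
        negCounts <- tabulate(species[binding < negThreshold], nSpecies)
        presort[, j] <- counts / nBacteria
        posSizes[j] <- sum(posCounts) / nBacteria
        negSizes[j] <- sum(negCounts) / nBacteria
        igapos[, j] <- if (sum(posCounts) > 0) posCounts / sum(posCounts)
                       else 0
        iganeg[, j] <- if (sum(negCounts) > 0) negCounts / sum(negCounts)
                       else 0
    }
    emptyPos <- colSums(igapos) == 0
    emptyNeg <- colSums(iganeg) == 0
    if (any(emptyPos | emptyNeg))
        warning(sprintf(
            "empty sorted fraction(s) in sample(s) %s; kept as all-zero columns",
            paste(colnames(presort)[emptyPos | emptyNeg], collapse = ", ")))

    exp <- IgASeqExperiment(igapos = igapos, iganeg = iganeg,
                            presort = presort, posSizes = posSizes,
                            negSizes = negSizes, groups = groups,
                            normalized = TRUE)
    out <- new("IgASeqSimulation", experiment = exp, trueBindingMeans = means,
               config = config)
    validObject(out)
    out
}

#' Accessors for IgASeqSimulation
#'
#' `experiment()` returns the simulated [IgASeqExperiment];
#' `trueBindingMeans()` the named per-species ground-truth mean binding
#' values the benchmark scores are compared against.
#'
#' @param x an [IgASeqSimulation].
#' @name IgASeqSimulation-accessors
NULL

#' @rdname IgASeqSimulation-accessors
#' @export
setMethod("trueBindingMeans", "IgASeqSimulation", function(x)
    x@trueBindingMeans)

#' @rdname IgASeqSimulation-accessors
#' @export
setMethod("experiment", "IgASeqSimulation", function(x) x@experiment)

setMethod("show", "IgASeqSimulation", function(object) {
    cfg <- object@config
    cat(sprintf("IgASeqSimulation: %d species, %d samples, %d bacteria/sample\n",
                cfg$nSpecies, cfg$nSamples, cfg$nBacteria))
    cat(sprintf("  gates: IgA+ > %g, IgA- < %g\n", cfg$posThreshold,
                cfg$negThreshold))
    if (cfg$nCaseSamples > 0)
        cat(sprintf("  case-control: %d cases, species %s boosted by %g\n",
                    cfg$nCaseSamples, cfg$caseBoost$speciesIndex,
                    cfg$caseBoost$addedAbundance))
    cat("  true binding means:",
        paste(format(object@trueBindingMeans, digits = 3), collapse = " "),
        "\n")
})
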