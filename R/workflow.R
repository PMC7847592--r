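## File-level workflow steps: simulate -> score -> filter -> compare.
## Each step reads/writes the package's tab-separated formats, never
## mutates its inputs, and drops a JSON provenance sidecar recording the
## resolved parameters, package version and seed, so a run can be replayed
## exactly. A thin command-line wrapper over these functions is installed
## at system.file("scripts", "igaseq", package = "IgASeqTools").

.writeProvenance <- function(dir, command, params) {
    sidecar <- list(command = command,
                    package = "IgASeqTools",
                    version = as.character(utils::packageVersion("IgASeqTools")),
                    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                    params = params)
    jsonlite::write_json(sidecar, file.path(dir, paste0(command,
                                                        "_provenance.json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

.writeSizes <- function(pos, neg, path) {
    df <- data.frame(sample = names(pos),
                     igapos_size = format(unname(pos), digits = 17),
                     iganeg_size = format(unname(neg), digits = 17))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

#' Simulate an experiment and write it to disk
#'
#' Runs [simulateIgASeq()] and writes `presort.tsv`, `igapos.tsv`,
#' `iganeg.tsv`, `sizes.tsv`, `truth.tsv` (the ground-truth species
#' binding means), `groups.tsv` (when case-control), and a JSON provenance
#' sidecar into `outDir`.
#'
#' @param outDir output directory, created if absent.
#' @param seed integer RNG seed; the same seed reproduces the outputs
#'   byte-identically.
#' @param ... parameters forwarded to [simulateIgASeq()].
#' @return the [IgASeqSimulation], invisibly.
#' @export
runSimulate <- function(outDir, seed = 1, ...) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    set.seed(seed)
    sim <- simulateIgASeq(...)
    x <- experiment(sim)
    writeAbundanceTable(presortAbundance(x), file.path(outDir, "presort.tsv"))
    writeAbundanceTable(igaPosAbundance(x), file.path(outDir, "igapos.tsv"))
    writeAbundanceTable(igaNegAbundance(x), file.path(outDir, "iganeg.tsv"))
    .writeSizes(posFractionSizes(x), negFractionSizes(x),
                file.path(outDir, "sizes.tsv"))
    truth <- data.frame(species = names(trueBindingMeans(sim)),
                        binding_mean = format(unname(trueBindingMeans(sim)),
                                              digits = 17))
    utils::write.table(truth, file.path(outDir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    g <- sampleGroups(x)
    if (!is.null(g))
        utils::write.table(data.frame(sample = names(g), group = unname(g)),
                           file.path(outDir, "groups.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    .writeProvenance(outDir, "simulate", c(list(seed = seed),
                                           sim@config))
    invisible(sim)
}

#' Score tables on disk
#'
#' Reads the tables a method requires, scores them with [igaScore()], and
#' writes the score matrix (`scores_<method>.tsv`, `NA` for unscored
#' cells) plus a provenance sidecar recording the method, the pseudo count
#' actually used, and the options.
#'
#' @param outDir output directory.
#' @param igapos,iganeg,presort,sizes paths to the input tables; only
#'   those the method requires need be given.
#' @param method scoring method; see [igaScore()].
#' @param pseudoCount pseudo count; default derives it from the supplied
#'   tables via [defaultPseudoCount()].
#' @param cap,scaled method options; see [igaScore()].
#' @return the [IgAScoreMatrix], invisibly.
#' @export
runScore <- function(outDir, igapos, iganeg = NULL, presort = NULL,
                     sizes = NULL, method = "prob_ratio", pseudoCount = NULL,
                     cap = TRUE, scaled = TRUE) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    x <- readIgASeqExperiment(igapos, iganeg, presort, sizes)
    sm <- igaScore(x, method, pseudoCount = pseudoCount, cap = cap,
                   scaled = scaled)
    writeAbundanceTable(sm, file.path(outDir,
                                      paste0("scores_", method, ".tsv")))
    .writeProvenance(outDir, "score",
                     list(method = method,
                          pseudo_count = pseudoCount(sm),
                          cap = cap, scaled = scaled,
                          inputs = list(igapos = igapos, iganeg = iganeg,
                                        presort = presort, sizes = sizes)))
    invisible(sm)
}

#' Filter tables on disk
#'
#' Applies the contamination-screening recipe -- blank-control removal,
#' minimum-abundance threshold, pre-sort presence screen -- in that order,
#' skipping steps whose inputs are absent (`blankTaxa = NULL` skips blank
#' removal; `threshold = 0` is the identity; the screen is skipped without
#' a presort table). Writes the filtered tables, a combined JSON
#' `filter_report.json`, and a provenance sidecar.
#'
#' @param outDir output directory.
#' @param igapos,iganeg,presort,sizes input table paths.
#' @param blankTaxa character vector of contaminant taxa, or a path to a
#'   one-taxon-per-line text file, or `NULL`.
#' @param threshold minimum abundance (default 0).
#' @param screenPresort apply the pre-sort presence screen when a presort
#'   table is available (default `TRUE`).
#' @return the filtered [IgASeqExperiment], invisibly.
#' @export
runFilter <- function(outDir, igapos, iganeg = NULL, presort = NULL,
                      sizes = NULL, blankTaxa = NULL, threshold = 0,
                      screenPresort = TRUE) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    x <- readIgASeqExperiment(igapos, iganeg, presort, sizes)
    reports <- list()
    if (!is.null(blankTaxa)) {
        if (length(blankTaxa) == 1L && file.exists(blankTaxa))
            blankTaxa <- readLines(blankTaxa)
        step <- removeBlankTaxa(x, blankTaxa)
        x <- step$experiment
        reports$blank <- list(taxa_removed = step$report@taxaRemovedBlank)
    }
    if (threshold > 0) {
        step <- filterMinAbundance(x, threshold)
        x <- step$experiment
        reports$threshold <- list(
            threshold = threshold,
            taxa_removed = step$report@taxaRemovedThreshold,
            mass_retained = step$report@fractionRetained)
    }
    if (screenPresort && !is.null(presortAbundance(x))) {
        step <- screenAgainstPresort(x)
        x <- step$experiment
        reports$presort_screen <- list(
            cells_zeroed = step$report@cellsZeroedPresortScreen)
    }
    writeAbundanceTable(igaPosAbundance(x), file.path(outDir, "igapos.tsv"))
    if (!is.null(igaNegAbundance(x)))
        writeAbundanceTable(igaNegAbundance(x),
                            file.path(outDir, "iganeg.tsv"))
    if (!is.null(presortAbundance(x)))
        writeAbundanceTable(presortAbundance(x),
                            file.path(outDir, "presort.tsv"))
    jsonlite::write_json(reports, file.path(outDir, "filter_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    .writeProvenance(outDir, "filter",
                     list(blank_taxa = blankTaxa, threshold = threshold,
                          screen_presort = screenPresort))
    invisible(x)
}

#' Compare groups on disk
#'
#' Reads a score matrix and a group-label file, runs
#' [exactPermutationTest()], and writes the per-taxon results as
#' `comparison.tsv` plus a JSON summary of taxa significant at `alpha`
#' (on FDR-adjusted p-values) and a provenance sidecar.
#'
#' @param outDir output directory.
#' @param scores path to a score matrix written by [runScore()].
#' @param groups path to a sample/group table.
#' @param minPerGroup,alternative see [exactPermutationTest()].
#' @param alpha significance level applied to adjusted p-values in the
#'   summary (default 0.05).
#' @return the comparison data.frame, invisibly.
#' @export
runCompare <- function(outDir, scores, groups, minPerGroup = 3,
                       alternative = "two.sided", alpha = 0.05) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    sm <- readScoreMatrix(scores)
    g <- readGroupLabels(groups)
    res <- exactPermutationTest(sm, g, minPerGroup = minPerGroup,
                                alternative = alternative)
    utils::write.table(res, file.path(outDir, "comparison.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sig <- res$taxon[res$tested & !is.na(res$p_adjusted) &
                     res$p_adjusted < alpha]
    jsonlite::write_json(
        list(alpha = alpha, n_tested = sum(res$tested),
             significant_taxa = sig),
        file.path(outDir, "comparison_summary.json"), auto_unbox = TRUE,
        pretty = TRUE, digits = NA)
    .writeProvenance(outDir, "compare",
                     list(scores = scores, groups = groups,
                          min_per_group = minPerGroup,
                          alternative = alternative, alpha = alpha))
    invisible(res)
}

#' Read a score matrix written by [runScore()]
#'
#' Like [readAbundanceTable()] but permitting `NA` cells, which mark taxa
#' that could not be scored.
#'
#' @param path file path.
#' @return numeric matrix with `NA` for unscored cells.
#' @export
readScoreMatrix <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, quote = "",
                            comment.char = "")
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    storage.mode(m) <- "double"
    m
}
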