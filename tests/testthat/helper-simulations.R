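# Default-condition simulations are shared between the benchmark tests;
# they are computed once per test run and cached here.

.simCache <- new.env(parent = emptyenv())

cachedDefaultSims <- function(seeds = 1:10) {
    key <- paste0("default_", paste(seeds, collapse = "_"))
    if (is.null(.simCache[[key]])) {
        .simCache[[key]] <- lapply(seeds, function(s) {
            set.seed(s)
            suppressWarnings(simulateIgASeq())
        })
    }
    .simCache[[key]]
}

cachedCaseControlSims <- function(seeds = 1:10) {
    key <- paste0("cc_", paste(seeds, collapse = "_"))
    if (is.null(.simCache[[key]])) {
        .simCache[[key]] <- lapply(seeds, function(s) {
            set.seed(s)
            suppressWarnings(simulateIgASeq(nSamples = 60, nCaseSamples = 30))
        })
    }
    .simCache[[key]]
}

# all three relative-binding scores for one simulated experiment, with the
# pseudo count derived from the data as in a real analysis
allScores <- function(x) {
    pc <- defaultPseudoCount(x)
    list(palm = igaScore(x, "palm", pseudoCount = pc),
         kau = igaScore(x, "kau", pseudoCount = pc),
         prob_ratio = igaScore(x, "prob_ratio", pseudoCount = pc))
}
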