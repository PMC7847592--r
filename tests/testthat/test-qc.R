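qcBundle <- function() {
    pos <- matrix(c(0.55, 0.3, 0.1, 0.05,
                    0.6, 0.2995, 0.1, 0.0005), 4,
                  dimnames = list(c("a", "b", "c", "contam"),
                                  c("s1", "s2")))
    neg <- matrix(c(0.25, 0.25, 0.45, 0.05,
                    0.4, 0.3, 0.3, 0), 4, dimnames = dimnames(pos))
    pre <- matrix(c(0.5, 0.3, 0.2, 0,
                    0.45, 0.35, 0.2, 0), 4, dimnames = dimnames(pos))
    IgASeqExperiment(igapos = pos, iganeg = neg, presort = pre,
                     normalized = TRUE)
}

test_that("blank-control taxa are removed everywhere and tables renormalized", {
    x <- qcBundle()
    out <- removeBlankTaxa(x, c("contam", "not_present"))
    expect_false("contam" %in% rownames(out$experiment))
    expect_identical(out$report@taxaRemovedBlank, "contam")
    for (nm in assayNames(out$experiment))
        expect_equal(unname(colSums(assay(out$experiment, nm))), c(1, 1),
                     tolerance = 1e-12)
    # empty blank list leaves the bundle unchanged
    id <- removeBlankTaxa(x, character())
    expect_equal(assays(id$experiment), assays(x))
    expect_error(removeBlankTaxa(x, c("a", "b", "c", "contam")),
                 "every taxon")
})

test_that("abundance thresholding zeroes cells, drops dead taxa, renormalizes", {
    pre <- matrix(c(0.7, 0.2995, 0.0005), 3, 1,
                  dimnames = list(c("a", "b", "c"), "s1"))
    x <- IgASeqExperiment(igapos = pre, iganeg = pre, presort = pre,
                          normalized = TRUE)
    out <- filterMinAbundance(x, 1e-3)
    expect_identical(out$report@taxaRemovedThreshold, "c")
    expect_equal(assay(out$experiment, "igapos")[, 1],
                 c(a = 0.7, b = 0.2995) / 0.9995, tolerance = 1e-12)
    expect_equal(out$report@fractionRetained, 0.9995, tolerance = 1e-12)
    # threshold 0 is the identity
    id <- filterMinAbundance(x, 0)
    expect_equal(assays(id$experiment), assays(x))
    expect_equal(id$report@fractionRetained, 1)
    expect_error(filterMinAbundance(x, 0.9), "every taxon")
})

test_that("pre-sort screen zeroes fraction cells per sample and is idempotent", {
    x <- qcBundle()
    out <- screenAgainstPresort(x)
    y <- out$experiment
    # contam absent pre-sort in both samples: zeroed in both fractions
    expect_equal(unname(igaPosAbundance(y)["contam", ]), c(0, 0))
    expect_equal(unname(igaNegAbundance(y)["contam", ]), c(0, 0))
    # 3 nonzero fraction cells had zero pre-sort abundance
    expect_identical(out$report@cellsZeroedPresortScreen, 3L)
    # presort table untouched, fraction columns renormalized
    expect_identical(presortAbundance(y), presortAbundance(x))
    expect_equal(unname(colSums(igaPosAbundance(y))), c(1, 1),
                 tolerance = 1e-12)
    again <- screenAgainstPresort(y)
    expect_equal(assays(again$experiment), assays(y))
    expect_identical(again$report@cellsZeroedPresortScreen, 0L)
    noPre <- IgASeqExperiment(igapos = igaPosAbundance(x), normalized = TRUE)
    expect_error(screenAgainstPresort(noPre), "presort")
})

test_that("threshold report matches hand enumeration and is monotone", {
    pre <- matrix(c(0.7, 0.2995, 0.0005), 3, 1,
                  dimnames = list(c("a", "b", "c"), "s1"))
    x <- IgASeqExperiment(igapos = pre, normalized = TRUE)
    rep <- thresholdReport(x, c(0, 1e-3, 0.5))
    expect_equal(rep$mass_retained, c(1, 0.9995, 0.7), tolerance = 1e-12)
    expect_equal(rep$taxa_retained, c(3, 2, 1))
    set.seed(31)
    b <- randomBundle(nTaxa = 8, nSamples = 4)
    xb <- IgASeqExperiment(igapos = b$igapos, iganeg = b$iganeg,
                           presort = b$presort, normalized = TRUE)
    rp <- thresholdReport(xb, c(0, 1e-4, 1e-3, 1e-2, 0.1))
    expect_true(all(diff(rp$mass_retained) <= 1e-12))
    expect_true(all(diff(rp$taxa_retained) <= 0))
})

test_that("filtering commutes with taxon and sample reordering", {
    x <- qcBundle()
    perm <- x[c(3, 1, 4, 2), c(2, 1)]
    a <- filterMinAbundance(x, 1e-3)$experiment
    b <- filterMinAbundance(perm, 1e-3)$experiment
    common <- intersect(rownames(a), rownames(b))
    for (nm in assayNames(a))
        expect_equal(assay(b, nm)[common, colnames(a)],
                     assay(a, nm)[common, ], tolerance = 1e-12)
})

test_that("the full recipe clears contaminants absent pre-sort from simulator output", {
    set.seed(77)
    sim <- simulateIgASeq(nSamples = 8, nBacteria = 20000)
    x <- experiment(sim)
    # spike two contaminants into the sorted fractions only: a reagent
    # contaminant (to be caught by the blank list) and a low-level
    # cross-over contaminant (to be caught by threshold + screen)
    spike <- function(m, taxon, level) {
        m <- rbind(m, level)
        rownames(m)[nrow(m)] <- taxon
        sweep(m, 2, colSums(m), "/")
    }
    pos <- spike(spike(igaPosAbundance(x), "reagent", 0.15),
                 "crossover", 5e-4)
    neg <- spike(spike(igaNegAbundance(x), "reagent", 0.2),
                 "crossover", 4e-4)
    pre <- presortAbundance(x)   # contaminants absent: zero-filled on alignment
    dirty <- IgASeqExperiment(igapos = pos, iganeg = neg, presort = pre,
                              posSizes = posFractionSizes(x),
                              negSizes = negFractionSizes(x),
                              normalized = TRUE)
    step1 <- removeBlankTaxa(dirty, "reagent")
    step2 <- filterMinAbundance(step1$experiment, 1e-3)
    step3 <- screenAgainstPresort(step2$experiment)
    clean <- step3$experiment
    contams <- intersect(c("reagent", "crossover"), rownames(clean))
    for (tx in contams) {
        expect_equal(unname(igaPosAbundance(clean)[tx, ]),
                     rep(0, ncol(clean)))
        expect_equal(unname(igaNegAbundance(clean)[tx, ]),
                     rep(0, ncol(clean)))
    }
    for (nm in assayNames(clean)) {
        cs <- colSums(assay(clean, nm))
        expect_true(all(abs(cs - 1) < 1e-6))
    }
})
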