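mat1 <- function(v, taxa = "t1", sample = "s1")
    matrix(v, length(taxa), length(sample), dimnames = list(taxa, sample))

test_that("default pseudo count is the largest power of ten below the minimum abundance", {
    tab <- function(m) mat1(c(m, 1 - m), taxa = c("a", "b"))
    expect_equal(defaultPseudoCount(tab(2.3e-3)), 1e-3)
    expect_equal(defaultPseudoCount(tab(1e-6)), 1e-7)    # strictly below
    expect_equal(defaultPseudoCount(mat1(1)), 0.1)
    # the minimum is taken across all supplied tables
    expect_equal(defaultPseudoCount(tab(0.3), tab(4e-5)), 1e-5)
    expect_error(defaultPseudoCount(mat1(0)), "nonzero")
})

test_that("Palm index matches hand-derived values and NA semantics", {
    pos <- mat1(c(0.4, 0.3, 0.5, 0), taxa = paste0("t", 1:4))
    neg <- mat1(c(0.2, 0.3, 0, 0), taxa = paste0("t", 1:4))
    s <- scores(palmIndex(pos, neg, 1e-6))
    expect_equal(s["t1", "s1"], 2)
    expect_equal(s["t2", "s1"], 1)
    expect_equal(s["t3", "s1"], 5e5)       # pseudo count only when neg = 0
    expect_true(is.na(s["t4", "s1"]))      # absent from both fractions
    expect_error(palmIndex(pos, neg, 0), "positive")
})

test_that("Kau index matches hand-derived values, bounds and NA semantics", {
    pos <- mat1(c(0.5, 0.3, 0), taxa = paste0("t", 1:3))
    neg <- mat1(c(0.05, 0.3, 0), taxa = paste0("t", 1:3))
    s <- scores(kauIndex(pos, neg, 1e-3))
    expect_equal(s["t1", "s1"], 0.6230519, tolerance = 1e-6)
    expect_equal(s["t2", "s1"], 0)
    expect_true(is.na(s["t3", "s1"]))
    # degenerate denominator (both shifted abundances equal 1) warns, not crashes
    one <- mat1(1); c0 <- 0.5
    expect_warning(out <- kauIndex(mat1(0.5), mat1(0.5), c0), "denominator")
    expect_true(is.na(scores(out)[1, 1]))
})

test_that("IgA+ posterior probability follows Bayes' theorem with capping", {
    pre <- mat1(c(0.2, 0.2, 0.6), taxa = paste0("t", 1:3))
    pos <- mat1(c(0.8, 0.2, 0), taxa = paste0("t", 1:3))
    s <- scores(igaPosProbability(pos, pre, c(s1 = 0.1)))
    expect_equal(s["t1", "s1"], 0.4)
    expect_equal(s["t3", "s1"], 0)
    # numerator above the pre-sort abundance caps at probability 1
    s2 <- scores(igaPosProbability(mat1(1), mat1(0.05), c(s1 = 0.3)))
    expect_equal(s2[1, 1], 1)
    # whole sample gated positive: probability 1
    s3 <- scores(igaPosProbability(mat1(1), mat1(1), c(s1 = 1)))
    expect_equal(s3[1, 1], 1)
    # uncapped form returns the raw ratio
    s4 <- scores(igaPosProbability(mat1(1), mat1(0.05), c(s1 = 0.3),
                                   cap = FALSE))
    expect_equal(s4[1, 1], 6)
    # zero pre-sort with nonzero fraction abundance: NA + warning uncapped
    expect_warning(
        s5 <- scores(igaPosProbability(mat1(c(0.6, 0.4), taxa = c("a", "b")),
                                       mat1(c(0, 1), taxa = c("a", "b")),
                                       c(s1 = 0.1), cap = FALSE)),
        "pre-sort")
    expect_true(is.na(s5["a", "s1"]))
})

test_that("IgA- posterior probability mirrors the IgA+ form", {
    s <- scores(igaNegProbability(mat1(0.6), mat1(0.4), c(s1 = 0.5)))
    expect_equal(s[1, 1], 0.75)
    s2 <- scores(igaNegProbability(mat1(0), mat1(0.4), c(s1 = 0.5)))
    expect_equal(s2[1, 1], 0)
})

test_that("probability ratio matches hand values, scaling and NA semantics", {
    pos <- mat1(c(0.5, 0.2, 0), taxa = paste0("t", 1:3))
    neg <- mat1(c(0.1, 0.5, 0), taxa = paste0("t", 1:3))
    ps <- c(s1 = 0.2); ns <- c(s1 = 0.5)
    s <- scores(probabilityRatio(pos, neg, ps, ns, 1e-3))
    expect_equal(s["t1", "s1"], log2(0.101 / 0.051) / log2(1001))
    expect_true(is.na(s["t3", "s1"]))
    # equal posterior numerators give zero
    s0 <- scores(probabilityRatio(mat1(0.5), mat1(0.2), c(s1 = 0.2),
                                  c(s1 = 0.5), 1e-3))
    expect_equal(s0[1, 1], 0)
    # one taxon holding every sorted bacterium attains the bound
    s1 <- scores(probabilityRatio(mat1(1), mat1(0), c(s1 = 1), c(s1 = 0.7),
                                  1e-4))
    expect_equal(s1[1, 1], 1)
    # unscaled value is the raw log2 ratio
    sr <- scores(probabilityRatio(pos, neg, ps, ns, 1e-3, scaled = FALSE))
    expect_equal(sr["t1", "s1"], log2(0.101 / 0.051))
})

test_that("igaScore dispatches and enforces per-method requirements", {
    b <- randomBundle()
    full <- IgASeqExperiment(igapos = b$igapos, iganeg = b$iganeg,
                             presort = b$presort, posSizes = b$posSizes,
                             negSizes = b$negSizes, normalized = TRUE)
    for (m in c("palm", "kau", "igapos_prob", "iganeg_prob", "prob_ratio"))
        expect_s4_class(igaScore(full, m), "IgAScoreMatrix")
    noNeg <- IgASeqExperiment(igapos = b$igapos, presort = b$presort,
                              posSizes = b$posSizes, normalized = TRUE)
    expect_error(igaScore(noNeg, "palm"), "iganeg")
    expect_error(igaScore(noNeg, "prob_ratio"), "iganeg")
    noPre <- IgASeqExperiment(igapos = b$igapos, iganeg = b$iganeg,
                              posSizes = b$posSizes, normalized = TRUE)
    expect_error(igaScore(noPre, "igapos_prob"), "presort")
    expect_error(
        igaScore(IgASeqExperiment(igapos = b$igapos, iganeg = b$iganeg,
                                  posSizes = b$posSizes, normalized = TRUE),
                 "prob_ratio"),
        "neg_sizes")
    raw <- IgASeqExperiment(igapos = b$igapos * 2, iganeg = b$iganeg * 2)
    expect_error(igaScore(raw, "palm"), "not normalized")
    # provenance is recorded on the result
    sm <- igaScore(full, "kau", pseudoCount = 1e-3)
    expect_identical(scoreMethod(sm), "kau")
    expect_identical(pseudoCount(sm), 1e-3)
    # degenerate single-taxon community: both fractions all one taxon
    one <- IgASeqExperiment(igapos = mat1(1), iganeg = mat1(1),
                            normalized = TRUE)
    expect_equal(scores(igaScore(one, "palm", pseudoCount = 1e-6))[1, 1], 1)
})

test_that("every score matches its brute-force oracle on random bundles", {
    set.seed(101)
    for (rep in seq_len(100)) {
        b <- randomBundle(nTaxa = sample(2:6, 1), nSamples = sample(1:4, 1))
        c <- 10^sample(-6:-2, 1)
        expect_equal(scores(palmIndex(b$igapos, b$iganeg, c)),
                     oraclePalm(b$igapos, b$iganeg, c), tolerance = 1e-12)
        expect_equal(scores(kauIndex(b$igapos, b$iganeg, c)),
                     oracleKau(b$igapos, b$iganeg, c), tolerance = 1e-12)
        expect_equal(scores(igaPosProbability(b$igapos, b$presort,
                                              b$posSizes)),
                     oraclePosProb(b$igapos, b$presort, b$posSizes),
                     tolerance = 1e-12)
        expect_equal(scores(probabilityRatio(b$igapos, b$iganeg, b$posSizes,
                                             b$negSizes, c)),
                     oracleProbRatio(b$igapos, b$iganeg, b$posSizes,
                                     b$negSizes, c), tolerance = 1e-12)
    }
})

test_that("posterior probability recovers true binding probabilities exactly", {
    # build a sample analytically from known per-taxon binding
    # probabilities p and arbitrary pre-sort composition a:
    # gate size = sum(a * p), fraction abundance = a * p / sum(a * p).
    # The posterior must return p exactly, independent of a.
    set.seed(202)
    for (rep in seq_len(25)) {
        n <- sample(3:8, 1)
        a <- rgamma(n, 1); a <- a / sum(a)
        p <- runif(n)
        fs <- sum(a * p)
        pos <- matrix(a * p / fs, n,
                      dimnames = list(paste0("t", 1:n), "s1"))
        pre <- matrix(a, n, dimnames = dimnames(pos))
        got <- scores(igaPosProbability(pos, pre, c(s1 = fs)))[, "s1"]
        expect_equal(unname(got), p, tolerance = 1e-12)
    }
})

test_that("score bounds, sign coherence and base invariance hold under fuzzing", {
    set.seed(303)
    for (rep in seq_len(60)) {
        b <- randomBundle(nTaxa = sample(2:8, 1), nSamples = sample(1:4, 1))
        # valid pseudo count: strictly below the smallest nonzero abundance
        c <- defaultPseudoCount(b$igapos, b$iganeg)
        kau <- scores(kauIndex(b$igapos, b$iganeg, c))
        pr <- scores(probabilityRatio(b$igapos, b$iganeg, b$posSizes,
                                      b$negSizes, c))
        pp <- scores(igaPosProbability(b$igapos, b$presort, b$posSizes))
        expect_true(all(abs(kau) <= 1 + 1e-12, na.rm = TRUE))
        expect_true(all(abs(pr) <= 1 + 1e-12, na.rm = TRUE))
        expect_true(all(pp >= 0 & pp <= 1, na.rm = TRUE))
        # kau > 0 iff IgA+ abundance exceeds IgA- abundance
        d <- b$igapos - b$iganeg
        expect_identical(sign(kau)[!is.na(kau)], sign(d)[!is.na(kau)])
        # prob_ratio > 0 iff IgA+ posterior numerator dominates
        dn <- sweep(b$igapos, 2, b$posSizes, "*") -
              sweep(b$iganeg, 2, b$negSizes, "*")
        expect_identical(sign(pr)[!is.na(pr)], sign(dn)[!is.na(pr)])
        # the Kau oracle uses log10; equality doubles as base invariance
        expect_equal(kau, oracleKau(b$igapos, b$iganeg, c),
                     tolerance = 1e-12)
    }
})

test_that("scores are non-decreasing in IgA+ abundance, all else fixed", {
    c <- 1e-4
    posGrid <- seq(0, 1, by = 0.05)
    neg <- mat1(0.3); pre <- mat1(0.5)
    ps <- c(s1 = 0.2); ns <- c(s1 = 0.4)
    evalAt <- function(p) {
        pos <- mat1(p)
        c(palm = scores(palmIndex(pos, neg, c))[1, 1],
          kau = scores(kauIndex(pos, neg, c))[1, 1],
          prob = scores(igaPosProbability(pos, pre, ps))[1, 1],
          pr = scores(probabilityRatio(pos, neg, ps, ns, c))[1, 1])
    }
    vals <- t(vapply(posGrid, evalAt, numeric(4)))
    for (col in colnames(vals))
        expect_true(all(diff(vals[, col]) >= -1e-12))
})
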