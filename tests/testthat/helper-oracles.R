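# Independent brute-force oracles: plain scalar loops over cells, written
# straight from the score definitions, sharing no code with the package.
# The Kau oracle deliberately uses log base 10 (the index is base-invariant).

oraclePalm <- function(pos, neg, c) {
    out <- pos * NA_real_
    for (i in seq_len(nrow(pos))) for (j in seq_len(ncol(pos))) {
        p <- pos[i, j]; n <- neg[i, j]
        if (p == 0 && n == 0) next
        out[i, j] <- p / (if (n == 0) n + c else n)
    }
    out
}

oracleKau <- function(pos, neg, c) {
    out <- pos * NA_real_
    for (i in seq_len(nrow(pos))) for (j in seq_len(ncol(pos))) {
        p <- pos[i, j]; n <- neg[i, j]
        if (p == 0 && n == 0) next
        den <- log10(p + c) + log10(n + c)
        if (den == 0) next
        out[i, j] <- -(log10(p + c) - log10(n + c)) / den
    }
    out
}

oraclePosProb <- function(frac, pre, sizes, cap = TRUE) {
    out <- frac * NA_real_
    for (i in seq_len(nrow(frac))) for (j in seq_len(ncol(frac))) {
        f <- frac[i, j]; a <- pre[i, j]
        num <- f * sizes[colnames(frac)[j]]
        if (a == 0 && f == 0) next
        if (cap) out[i, j] <- num / max(a, num)
        else if (a > 0) out[i, j] <- num / a
    }
    out
}

oracleProbRatio <- function(pos, neg, posSizes, negSizes, c, scaled = TRUE) {
    out <- pos * NA_real_
    for (i in seq_len(nrow(pos))) for (j in seq_len(ncol(pos))) {
        p <- pos[i, j]; n <- neg[i, j]
        if (p == 0 && n == 0) next
        sj <- colnames(pos)[j]
        v <- log2((p * posSizes[sj] + c) / (n * negSizes[sj] + c))
        if (scaled) v <- v / log2((1 + c) / c)
        out[i, j] <- v
    }
    out
}

# exact permutation p by enumerating every label vector as a bitmask:
# an approach unrelated to the package's combn-based enumeration
oraclePermP <- function(x1, x2, alternative = "two.sided") {
    pooled <- c(x1, x2)
    n <- length(pooled); n1 <- length(x1)
    stat <- function(idx1) {
        d <- mean(pooled[idx1]) - mean(pooled[-idx1])
        switch(alternative, two.sided = abs(d), greater = d, less = -d)
    }
    obs <- stat(seq_len(n1))
    tol <- 1e-8 * (max(abs(pooled)) + 1)
    hits <- 0L; total <- 0L
    for (mask in 0:(2^n - 1)) {
        idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
        if (length(idx) != n1) next
        total <- total + 1L
        if (stat(idx) >= obs - tol) hits <- hits + 1L
    }
    hits / total
}

# random small experiment: dirichlet-style compositions with zeros
# injected (keeping >= 2 observed taxa per column, as in any community a
# pseudo count can validly be derived for), random gate sizes with
# pos + neg <= 1
randomBundle <- function(nTaxa = 5, nSamples = 3, zeroProb = 0.25) {
    rcomp <- function() {
        m <- matrix(rgamma(nTaxa * nSamples, 1), nTaxa,
                    dimnames = list(paste0("t", seq_len(nTaxa)),
                                    paste0("s", seq_len(nSamples))))
        drop <- matrix(runif(length(m)) < zeroProb, nTaxa, nSamples)
        for (j in seq_len(nSamples)) {
            keep <- sample(nTaxa, min(2, nTaxa))
            drop[keep, j] <- FALSE
        }
        m[drop] <- 0
        sweep(m, 2, colSums(m), "/")
    }
    pos <- runif(nSamples, 0.05, 0.5)
    neg <- runif(nSamples, 0.05, 1 - pos)
    list(igapos = rcomp(), iganeg = rcomp(), presort = rcomp(),
         posSizes = setNames(pos, paste0("s", seq_len(nSamples))),
         negSizes = setNames(neg, paste0("s", seq_len(nSamples))))
}
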