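## Between-group comparisons of score matrices. With group sizes as small
## as 3-4 samples, asymptotic tests are unreliable; the exact permutation
## test enumerates every distinct assignment of group labels and reports
## the proportion of assignments whose group-mean difference reaches the
## observed one.

#' Exact permutation test on group means
#'
#' For each taxon, the non-missing scores are split by group and the
#' difference in group means is computed. All `choose(n1 + n2, n1)`
#' distinct assignments of the group labels to the observed values are
#' enumerated, and the exact p-value is the proportion of assignments
#' whose statistic is at least the observed one (the observed assignment
#' is one of them, so p is never 0). The default two-sided statistic is
#' `|mean1 - mean2|`; one-sided alternatives use the signed difference.
#' Taxa with fewer than `minPerGroup` scored samples in either group are
#' flagged untested and excluded from multiple-testing adjustment.
#'
#' @param scores an [IgAScoreMatrix] or a taxa-by-sample numeric matrix
#'   with `NA` marking unscored cells.
#' @param groups named character vector mapping samples to exactly two
#'   group labels; samples absent from `groups` are ignored.
#' @param minPerGroup minimum scored samples required per group (default
#'   3).
#' @param alternative `"two.sided"` (default), `"greater"` (group 1 mean
#'   larger) or `"less"`. Group 1 is the first group label in sorted
#'   order unless `groups` is a factor, in which case its first level.
#' @return a data.frame, one row per taxon, with columns `taxon`,
#'   `n_group1`, `n_group2`, `mean_group1`, `mean_group2`, `p_value`,
#'   `p_adjusted` (Benjamini-Hochberg over tested taxa), `ssmd`
#'   (group 1 minus group 2; see [ssmd()]) and `tested`. Untested taxa
#'   carry `NA` p-values.
#' @examples
#' m <- rbind(t1 = c(10, 11, 12, 13, 1, 2, 3, 4))
#' colnames(m) <- paste0("s", 1:8)
#' g <- setNames(rep(c("a", "b"), each = 4), colnames(m))
#' exactPermutationTest(m, g)  # p = 2/70
#' @export
exactPermutationTest <- function(scores, groups, minPerGroup = 3,
                                 alternative = c("two.sided", "greater",
                                                 "less")) {
    alternative <- match.arg(alternative)
    if (is(scores, "IgAScoreMatrix")) scores <- methods::slot(scores, "scores")
    stopifnot(is.matrix(scores), minPerGroup >= 1)
    if (is.null(names(groups))) stop("'groups' must be named by sample")
    lv <- if (is.factor(groups)) levels(droplevels(groups))
          else sort(unique(as.character(groups)))
    if (length(lv) != 2L)
        stop(sprintf("exactly two groups required, got %d", length(lv)))
    groups <- as.character(groups)[match(colnames(scores),
                                         names(groups))]
    keepSample <- !is.na(groups)

    rows <- lapply(seq_len(nrow(scores)), function(i) {
        v <- scores[i, keepSample]
        g <- groups[keepSample]
        ok <- !is.na(v)
        v <- v[ok]; g <- g[ok]
        x1 <- v[g == lv[1L]]; x2 <- v[g == lv[2L]]
        n1 <- length(x1); n2 <- length(x2)
        base <- data.frame(taxon = rownames(scores)[i], n_group1 = n1,
                           n_group2 = n2,
                           mean_group1 = if (n1) mean(x1) else NA_real_,
                           mean_group2 = if (n2) mean(x2) else NA_real_,
                           p_value = NA_real_, ssmd = NA_real_,
                           tested = FALSE)
        if (n1 < minPerGroup || n2 < minPerGroup) return(base)
        base$p_value <- .exactMeanDiffP(x1, x2, alternative)
        base$ssmd <- suppressWarnings(ssmd(x1, x2))
        base$tested <- TRUE
        base
    })
    out <- do.call(rbind, rows)
    out$p_adjusted <- NA_real_
    out$p_adjusted[out$tested] <- stats::p.adjust(out$p_value[out$tested],
                                                  method = "BH")
    out[, c("taxon", "n_group1", "n_group2", "mean_group1", "mean_group2",
            "p_value", "p_adjusted", "ssmd", "tested")]
}

## exact p for the difference in group means by full enumeration of the
## choose(n1+n2, n1) label assignments; ties count as reaching the
## observed statistic (>= with a relative tolerance for float noise)
.exactMeanDiffP <- function(x1, x2, alternative) {
    n1 <- length(x1); n2 <- length(x2)
    pooled <- c(x1, x2)
    n <- n1 + n2
    total <- sum(pooled)
    stat <- function(sum1) {
        d <- sum1 / n1 - (total - sum1) / n2
        switch(alternative, two.sided = abs(d), greater = d, less = -d)
    }
    if (choose(n, n1) > 2e6)
        stop(sprintf(
            "full enumeration of %d assignments is infeasible; the exact test is meant for small groups",
            choose(n, n1)))
    obs <- stat(sum(x1))
    tol <- 1e-8 * (max(abs(pooled)) + 1)
    idx <- utils::combn(n, n1)
    sums1 <- colSums(matrix(pooled[idx], nrow = n1))
    mean(stat(sums1) >= obs - tol)
}

#' Strictly standardised mean difference
#'
#' `(mean(x1) - mean(x2)) / sqrt(var(x1) + var(x2))` with unbiased sample
#' variances: a scale-free effect size that makes group differences
#' comparable between scores measured on different scales. When both
#' variances are zero the value is 0 if the means agree and signed
#' infinity (with a warning) if they differ; a group with fewer than two
#' values has no variance estimate and yields `NA` with a warning.
#'
#' @param x1,x2 numeric vectors; `NA`s are dropped.
#' @return a single number (possibly `Inf`, `-Inf`, or `NA`).
#' @export
ssmd <- function(x1, x2) {
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    if (length(x1) == 0L || length(x2) == 0L)
        stop("both groups must be non-empty after removing NAs")
    if (length(x1) < 2L || length(x2) < 2L) {
        warning("a group has fewer than 2 values; variance undefined")
        return(NA_real_)
    }
    num <- mean(x1) - mean(x2)
    den <- sqrt(stats::var(x1) + stats::var(x2))
    if (den == 0) {
        if (num == 0) return(0)
        warning("zero variance in both groups with unequal means")
        return(sign(num) * Inf)
    }
    num / den
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean of the non-missing
#' values; with `absolute = TRUE` the absolute value is returned, which is
#' the meaningful quantity when comparing the dispersion of signed scores
#' across methods. A zero mean leaves the CV undefined (`NA`, with a
#' warning).
#'
#' @param x numeric vector; `NA`s are dropped.
#' @param absolute return `|CV|` (default `TRUE`).
#' @return a single number.
#' @export
coefficientOfVariation <- function(x, absolute = TRUE) {
    x <- x[!is.na(x)]
    if (length(x) < 2L)
        stop("at least two non-missing values required")
    m <- mean(x)
    if (m == 0) {
        warning("mean is zero; coefficient of variation undefined")
        return(NA_real_)
    }
    cv <- stats::sd(x) / m
    if (absolute) abs(cv) else cv
}
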