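## Construction, alignment, normalization and I/O for abundance tables.
## Tables are taxa-as-rows, samples-as-columns throughout; the header row of
## every file carries the sample identifiers and the first column the taxa.

.checkAbundanceMatrix <- function(m, what) {
    if (!is.matrix(m) || !is.numeric(m))
        stop(sprintf("'%s' must be a numeric matrix", what), call. = FALSE)
    if (is.null(rownames(m)) || is.null(colnames(m)))
        stop(sprintf("'%s' must have taxon rownames and sample colnames", what),
             call. = FALSE)
    if (anyDuplicated(rownames(m)))
        stop(sprintf("'%s' has duplicate taxon identifiers: %s", what,
                     paste(unique(rownames(m)[duplicated(rownames(m))]),
                           collapse = ", ")), call. = FALSE)
    if (anyDuplicated(colnames(m)))
        stop(sprintf("'%s' has duplicate sample identifiers: %s", what,
                     paste(unique(colnames(m)[duplicated(colnames(m))]),
                           collapse = ", ")), call. = FALSE)
    if (anyNA(m) || any(!is.finite(m)))
        stop(sprintf("'%s' contains missing or non-finite values", what),
             call. = FALSE)
    if (any(m < 0))
        stop(sprintf("'%s' contains negative abundances", what), call. = FALSE)
    invisible(m)
}

## Order-preserving union: taxa in order of first appearance across tables.
.unionTaxa <- function(tables) {
    out <- character()
    for (m in tables) out <- c(out, setdiff(rownames(m), out))
    out
}

.reindexTaxa <- function(m, taxa) {
    out <- matrix(0, nrow = length(taxa), ncol = ncol(m),
                  dimnames = list(taxa, colnames(m)))
    out[rownames(m), ] <- m
    out
}

#' Construct an IgA-Seq experiment from abundance matrices
#'
#' Bundles the abundance tables and per-sample flow-cytometry measurements
#' of one IgA-Seq experiment into an [IgASeqExperiment]. Inputs are aligned
#' before validation: all tables are reindexed to the union of taxa (taxa
#' absent from a table are filled with 0, the abundance of an unobserved
#' taxon) and the intersection of samples (a sample missing a sorted
#' fraction cannot be scored). Sample order follows the `igapos` table.
#'
#' @param igapos taxa-by-sample relative-abundance matrix of the IgA-bound
#'   sorted fraction. Required.
#' @param iganeg abundance matrix of the unbound fraction, or `NULL`.
#' @param presort abundance matrix of the unsorted community, or `NULL`.
#' @param posSizes,negSizes named numeric vectors giving, per sample, the
#'   proportion of sorted bacteria falling in the IgA+ (resp. IgA-) gate;
#'   proportions in `[0, 1]`, not percentages. Optional.
#' @param groups named character vector mapping samples to group labels.
#'   Optional.
#' @param normalized logical; declare that the tables already hold relative
#'   abundances summing to 1 per sample. Raw count tables must pass through
#'   [normalizeAbundances()] before scoring.
#' @return an [IgASeqExperiment].
#' @examples
#' pos <- matrix(c(0.7, 0.3, 0.2, 0.8), 2,
#'               dimnames = list(c("t1", "t2"), c("s1", "s2")))
#' neg <- matrix(c(0.4, 0.6, 0.5, 0.5), 2,
#'               dimnames = list(c("t1", "t2"), c("s1", "s2")))
#' exp <- IgASeqExperiment(igapos = pos, iganeg = neg,
#'                         posSizes = c(s1 = 0.1, s2 = 0.2),
#'                         negSizes = c(s1 = 0.3, s2 = 0.4),
#'                         normalized = TRUE)
#' igaScore(exp, "prob_ratio")
#' @export
IgASeqExperiment <- function(igapos, iganeg = NULL, presort = NULL,
                             posSizes = NULL, negSizes = NULL, groups = NULL,
                             normalized = FALSE) {
    .checkAbundanceMatrix(igapos, "igapos")
    tables <- list(igapos = igapos)
    if (!is.null(iganeg)) {
        .checkAbundanceMatrix(iganeg, "iganeg")
        tables$iganeg <- iganeg
    }
    if (!is.null(presort)) {
        .checkAbundanceMatrix(presort, "presort")
        tables$presort <- presort
    }
    if (any(vapply(tables, function(m) nrow(m) == 0L || ncol(m) == 0L,
                   logical(1))))
        stop("abundance tables must be non-empty")

    samples <- Reduce(intersect, lapply(tables, colnames))
    ## keep igapos ordering for the retained samples
    samples <- colnames(igapos)[colnames(igapos) %in% samples]
    if (length(samples) == 0L)
        stop("no sample is present in every supplied table")
    taxa <- .unionTaxa(tables)
    tables <- lapply(tables, function(m) .reindexTaxa(m, taxa)[, samples,
                                                               drop = FALSE])

    cd <- DataFrame(row.names = samples)
    for (nm in c("posSizes", "negSizes")) {
        v <- get(nm)
        if (!is.null(v)) {
            if (is.null(names(v)))
                stop(sprintf("'%s' must be a named vector", nm))
            miss <- setdiff(samples, names(v))
            if (length(miss))
                stop(sprintf("'%s' is missing sample(s): %s", nm,
                             paste(miss, collapse = ", ")))
            cd[[if (nm == "posSizes") "pos_size" else "neg_size"]] <-
                unname(v[samples])
        }
    }
    if (!is.null(groups)) {
        miss <- setdiff(samples, names(groups))
        if (length(miss))
            stop(sprintf("'groups' is missing sample(s): %s",
                         paste(miss, collapse = ", ")))
        cd$group <- unname(as.character(groups[samples]))
    }

    se <- SummarizedExperiment(assays = tables, colData = cd)
    out <- new("IgASeqExperiment", se)
    metadata(out)$normalized <- isTRUE(normalized)
    validObject(out)
    out
}

.assayOrNull <- function(x, nm) {
    if (nm %in% assayNames(x)) assay(x, nm) else NULL
}

.colDataOrNull <- function(x, nm) {
    cd <- colData(x)
    if (nm %in% names(cd)) stats::setNames(cd[[nm]], rownames(cd)) else NULL
}

#' Accessors for IgASeqExperiment components
#'
#' `igaPosAbundance()`, `igaNegAbundance()` and `presortAbundance()` return
#' the taxa-by-sample abundance matrix of the corresponding entity, or
#' `NULL` when it was not supplied. `posFractionSizes()` and
#' `negFractionSizes()` return the named per-sample gate proportions, or
#' `NULL`. `sampleGroups()` returns the named group labels, or `NULL`.
#' `isNormalized()` reports whether the tables are flagged as relative
#' abundances summing to 1 per sample.
#'
#' @param x an [IgASeqExperiment].
#' @return a matrix, a named vector, `NULL`, or a logical as described.
#' @name IgASeqExperiment-accessors
NULL

#' @rdname IgASeqExperiment-accessors
#' @export
setMethod("igaPosAbundance", "IgASeqExperiment", function(x)
    .assayOrNull(x, "igapos"))

#' @rdname IgASeqExperiment-accessors
#' @export
setMethod("igaNegAbundance", "IgASeqExperiment", function(x)
    .assayOrNull(x, "iganeg"))

#' @rdname IgASeqExperiment-accessors
#' @export
setMethod("presortAbundance", "IgASeqExperiment", function(x)
    .assayOrNull(x, "presort"))

#' @rdname IgASeqExperiment-accessors
#' @export
setMethod("posFractionSizes", "IgASeqExperiment", function(x)
    .colDataOrNull(x, "pos_size"))

#' @rdname IgASeqExperiment-accessors
#' @export
setMethod("negFractionSizes", "IgASeqExperiment", function(x)
    .colDataOrNull(x, "neg_size"))

#' @rdname IgASeqExperiment-accessors
#' @export
setMethod("sampleGroups", "IgASeqExperiment", function(x)
    .colDataOrNull(x, "group"))

#' @rdname IgASeqExperiment-accessors
#' @export
setMethod("isNormalized", "IgASeqExperiment", function(x)
    isTRUE(metadata(x)$normalized))

setMethod("show", "IgASeqExperiment", function(object) {
    cat(sprintf("IgASeqExperiment: %d taxa x %d samples\n",
                nrow(object), ncol(object)))
    cat("  tables:", paste(assayNames(object), collapse = ", "), "\n")
    extras <- intersect(c("pos_size", "neg_size", "group"),
                        names(colData(object)))
    if (length(extras)) cat("  per-sample data:",
                            paste(extras, collapse = ", "), "\n")
    cat("  normalized:", isNormalized(object), "\n")
})

## column-wise renormalization; all-zero columns either error or are kept
## (with a warning) so empty sorted fractions are visible, never hidden
.normalizeColumns <- function(m, what, allowEmpty = FALSE) {
    cs <- colSums(m)
    zero <- cs == 0
    if (any(zero)) {
        if (!allowEmpty)
            stop(sprintf("%s: sample(s) %s have zero total abundance", what,
                         paste(colnames(m)[zero], collapse = ", ")),
                 call. = FALSE)
        warning(sprintf("%s: sample(s) %s have zero total abundance; kept as all-zero",
                        what, paste(colnames(m)[zero], collapse = ", ")),
                call. = FALSE)
        cs[zero] <- 1
    }
    sweep(m, 2, cs, "/")
}

#' Convert tables to relative abundances
#'
#' Divides every sample column of every table by its column sum, so that
#' abundances within a sample sum to 1, and flags the result normalized.
#' Scoring assumes relative abundances, so raw count tables must pass
#' through this once; the operation is idempotent and preserves zeros.
#'
#' @param x an [IgASeqExperiment] (or a bare taxa-by-sample matrix).
#' @param ... unused.
#' @return the same class as `x`, column-normalized.
#' @rdname normalizeAbundances
#' @export
setMethod("normalizeAbundances", "IgASeqExperiment", function(x, ...) {
    for (nm in assayNames(x))
        assay(x, nm, withDimnames = FALSE) <-
            .normalizeColumns(assay(x, nm), sprintf("assay '%s'", nm))
    metadata(x)$normalized <- TRUE
    validObject(x)
    x
})

#' @rdname normalizeAbundances
#' @export
setMethod("normalizeAbundances", "matrix", function(x, ...) {
    .checkAbundanceMatrix(x, "table")
    .normalizeColumns(x, "table")
})

#' Read a taxa-by-sample abundance table
#'
#' Reads a delimited text file whose first column holds taxon identifiers
#' and whose header row holds sample identifiers, as written by
#' [writeAbundanceTable()]. Values are returned exactly as stored; no
#' normalization is applied.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return a numeric matrix with taxon rownames and sample colnames,
#'   preserving file order.
#' @export
readAbundanceTable <- function(path, sep = "\t") {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, colClasses = "character",
                            quote = "", comment.char = "")
    if (ncol(df) < 2L)
        stop("abundance table needs a taxon column plus at least one sample")
    taxa <- df[[1L]]
    if (anyDuplicated(taxa))
        stop(sprintf("duplicate taxon identifier(s): %s",
                     paste(unique(taxa[duplicated(taxa)]), collapse = ", ")))
    samples <- colnames(df)[-1L]
    if (anyDuplicated(samples))
        stop(sprintf("duplicate sample identifier(s): %s",
                     paste(unique(samples[duplicated(samples)]), collapse = ", ")))
    m <- matrix(NA_real_, length(taxa), length(samples),
                dimnames = list(taxa, samples))
    for (j in seq_along(samples)) {
        v <- suppressWarnings(as.numeric(df[[j + 1L]]))
        bad <- which(is.na(v))
        if (length(bad))
            stop(sprintf("non-numeric value '%s' at taxon '%s', sample '%s'",
                         df[[j + 1L]][bad[1L]], taxa[bad[1L]], samples[j]))
        m[, j] <- v
    }
    m
}

#' Write a taxa-by-sample table as tab-separated text
#'
#' Inverse of [readAbundanceTable()]: first header cell `taxon`, remaining
#' header cells the sample identifiers, one row per taxon. Values are
#' written with full double precision so that a read/write round trip is
#' exact. `NA` cells (not-scored entries of a score matrix) are written as
#' the literal token `NA`.
#'
#' @param m numeric matrix with dimnames, or an [IgAScoreMatrix].
#' @param path output file path.
#' @export
writeAbundanceTable <- function(m, path) {
    if (is(m, "IgAScoreMatrix")) m <- scores(m)
    df <- data.frame(taxon = rownames(m),
                     format(m, digits = 17, trim = TRUE, scientific = NA),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read per-sample gate fraction sizes
#'
#' Reads a tab-separated file with a `sample` column and one or both of
#' `igapos_size` and `iganeg_size`, giving the proportion of sorted
#' bacteria in each gate. Proportions must lie in `[0, 1]`; percentage
#' inputs are rejected rather than silently rescaled.
#'
#' @param path file path.
#' @return list with elements `pos` and `neg`, each a named numeric vector
#'   or `NULL` when the column is absent.
#' @export
readFractionSizes <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, quote = "")
    if (!"sample" %in% colnames(df))
        stop("fraction-size file needs a 'sample' column")
    if (anyDuplicated(df$sample))
        stop("duplicate sample identifier(s) in fraction-size file")
    pick <- function(col) {
        if (!col %in% colnames(df)) return(NULL)
        v <- df[[col]]
        if (!is.numeric(v)) stop(sprintf("column '%s' must be numeric", col))
        if (any(v < 0 | v > 1))
            stop(sprintf("column '%s' must hold proportions in [0, 1]", col))
        stats::setNames(v, df$sample)
    }
    list(pos = pick("igapos_size"), neg = pick("iganeg_size"))
}

#' Read sample-to-group labels
#'
#' Reads a two-column tab-separated file with columns `sample` and `group`.
#'
#' @param path file path.
#' @return named character vector mapping sample to group.
#' @export
readGroupLabels <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, quote = "",
                            colClasses = "character")
    if (!all(c("sample", "group") %in% colnames(df)))
        stop("group file needs 'sample' and 'group' columns")
    if (anyDuplicated(df$sample))
        stop("duplicate sample identifier(s) in group file")
    stats::setNames(df$group, df$sample)
}

#' Assemble an experiment from files on disk
#'
#' Convenience wrapper reading the tab-separated tables written by
#' [runSimulate()] (or prepared by hand) and assembling them with
#' [IgASeqExperiment()].
#'
#' @param igapos,iganeg,presort paths to abundance tables (`iganeg`,
#'   `presort` optional).
#' @param sizes path to a fraction-size file (optional).
#' @param groups path to a group-label file (optional).
#' @param normalized whether tables already hold relative abundances.
#' @return an [IgASeqExperiment].
#' @export
readIgASeqExperiment <- function(igapos, iganeg = NULL, presort = NULL,
                                 sizes = NULL, groups = NULL,
                                 normalized = TRUE) {
    sz <- if (!is.null(sizes)) readFractionSizes(sizes) else list(pos = NULL,
                                                                  neg = NULL)
    IgASeqExperiment(
        igapos = readAbundanceTable(igapos),
        iganeg = if (!is.null(iganeg)) readAbundanceTable(iganeg),
        presort = if (!is.null(presort)) readAbundanceTable(presort),
        posSizes = sz$pos, negSizes = sz$neg,
        groups = if (!is.null(groups)) readGroupLabels(groups),
        normalized = normalized)
}
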