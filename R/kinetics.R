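#' Construct a TimeCourseExperiment
#'
#' @param counts numeric matrix of normalized abundances (linear scale),
#'   genes in rows (unique rownames), samples in columns.
#' @param timepoint numeric vector of hours post stimulation, one per column.
#' @param replicate,genotype optional per-sample annotations.
#' @return a [TimeCourseExperiment].
#' @examples
#' m <- matrix(1:12, 2, 6, dimnames = list(c("g1", "g2"), NULL))
#' tce <- TimeCourseExperiment(m, timepoint = rep(c(0, 6, 9), 2),
#'                             replicate = rep(1:2, each = 3))
#' timepoints(tce)
#' @export
TimeCourseExperiment <- function(counts, timepoint, replicate = NULL,
                                 genotype = NULL) {
    counts <- as.matrix(counts)
    if (length(timepoint) != ncol(counts))
        stop("'timepoint' must have one entry per sample column")
    cd <- DataFrame(timepoint = as.numeric(timepoint))
    cd$replicate <- if (is.null(replicate)) rep(1L, ncol(counts)) else replicate
    cd$genotype <- if (is.null(genotype)) rep("WT", ncol(counts)) else genotype
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("s%02d_t%g_r%s", seq_len(ncol(counts)),
                                    cd$timepoint, cd$replicate)
    rownames(cd) <- colnames(counts)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(abundance = counts), colData = cd)
    new("TimeCourseExperiment", se)
}

#' Timepoints of a TimeCourseExperiment
#'
#' @param x a [TimeCourseExperiment].
#' @return sorted unique numeric timepoints (hours).
#' @name timepoints
#' @export
setMethod("timepoints", "TimeCourseExperiment", function(x)
    sort(unique(SummarizedExperiment::colData(x)$timepoint)))

setMethod("show", "TimeCourseExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cat("TimeCourseExperiment:", nrow(object), "gene(s) x", ncol(object),
        "sample(s)\n")
    cat("  timepoints (h):", paste(timepoints(object), collapse = ", "), "\n")
    cat("  genotypes:", paste(unique(cd$genotype), collapse = ", "), "\n")
    invisible(object)
})

#' Average replicates per timepoint
#'
#' Collapses replicate samples to their mean at each timepoint, the step
#' applied before peak normalization and persistence classification.
#'
#' @param x a [TimeCourseExperiment].
#' @param genotype if given, only samples of this genotype are used.
#' @return numeric matrix genes x timepoints; column names are the hours.
#' @name averageReplicates
#' @examples
#' m <- matrix(c(1, 2, 3, 5), 1, 4, dimnames = list("g1", NULL))
#' tce <- TimeCourseExperiment(m, timepoint = c(0, 0, 6, 6))
#' averageReplicates(tce)   # 1.5 at 0 h, 4 at 6 h
#' @export
setMethod("averageReplicates", "TimeCourseExperiment",
    function(x, genotype = NULL) {
        cd <- SummarizedExperiment::colData(x)
        keep <- if (is.null(genotype)) seq_len(ncol(x))
                else which(cd$genotype == genotype)
        if (!length(keep))
            stop("no samples for genotype ", genotype)
        a <- SummarizedExperiment::assay(x)[, keep, drop = FALSE]
        tp <- cd$timepoint[keep]
        tps <- sort(unique(tp))
        out <- vapply(tps, function(t)
            rowMeans(a[, tp == t, drop = FALSE]), numeric(nrow(a)))
        out <- matrix(out, nrow = nrow(a),
                      dimnames = list(rownames(x), as.character(tps)))
        out
    })

#' Peak-normalize a time course
#'
#' Divides each gene's values by its maximum over the course, so the peak of
#' expression is 1 and the 9 h value becomes the persistence statistic.
#' Idempotent and invariant to positive rescaling.
#'
#' @param x numeric vector (one course) or matrix (genes x timepoints).
#' @return same shape as `x`, row maxima equal to 1.
#' @examples
#' peakNormalize(c(1, 4, 2))
#' @export
peakNormalize <- function(x) {
    if (is.matrix(x)) {
        m <- apply(x, 1L, max)
        if (any(m <= 0))
            stop("all-zero (or negative) time course cannot be peak-normalized: ",
                 paste(utils::head(rownames(x)[m <= 0]), collapse = ", "))
        return(x / m)
    }
    stopifnot(is.numeric(x))
    m <- max(x)
    if (m <= 0)
        stop("all-zero (or negative) time course cannot be peak-normalized")
    x / m
}

#' Late-phase expression ratio
#'
#' Ratio of expression at a late timepoint to an earlier late-phase anchor
#' (default 9 h over 6 h post LPS), the window in which differential
#' destabilization acts.
#'
#' @param values numeric vector of abundances, or matrix genes x timepoints
#'   with timepoint column names.
#' @param timepoints numeric vector of hours matching `values` (taken from
#'   column names when `values` is a matrix).
#' @param tNum,tDen numerator and denominator timepoints (default 9 and 6).
#' @return numeric ratio(s).
#' @examples
#' lateRatio(c(5, 2, 1), timepoints = c(0, 6, 9))   # 0.5
#' @export
lateRatio <- function(values, timepoints = NULL, tNum = 9, tDen = 6) {
    if (is.matrix(values)) {
        timepoints <- as.numeric(colnames(values))
        iN <- match(tNum, timepoints); iD <- match(tDen, timepoints)
        if (is.na(iN) || is.na(iD))
            stop("timepoint ", if (is.na(iN)) tNum else tDen, " h not present")
        den <- values[, iD]
        if (any(den == 0))
            stop("zero expression at the ", tDen, " h denominator")
        return(values[, iN] / den)
    }
    stopifnot(is.numeric(values), length(values) == length(timepoints))
    iN <- match(tNum, timepoints); iD <- match(tDen, timepoints)
    if (is.na(iN) || is.na(iD))
        stop("timepoint ", if (is.na(iN)) tNum else tDen, " h not present")
    if (values[iD] == 0)
        stop("zero expression at the ", tDen, " h denominator")
    values[iN] / values[iD]
}

#' Sustained vs downregulated persistence call
#'
#' Classifies genes by their peak-normalized late (9 h) expression: values
#' above 0.5 are `SUSTAINED`, below 0.5 `DOWNREGULATED`. The boundary value
#' 0.5 is assigned to `SUSTAINED` so the two classes partition the list.
#'
#' @param x numeric vector of peak-normalized 9 h values, each in `[0, 1]`.
#' @return factor with levels `SUSTAINED`, `DOWNREGULATED`.
#' @examples
#' classifyPersistence(c(0.8, 0.3, 0.5))
#' @export
classifyPersistence <- function(x) {
    stopifnot(is.numeric(x))
    if (any(x < 0 | x > 1))
        stop("peak-normalized values must lie in [0, 1]")
    factor(ifelse(x >= 0.5, "SUSTAINED", "DOWNREGULATED"),
           levels = c("SUSTAINED", "DOWNREGULATED"))
}

#' Percent mRNA remaining after transcription block
#'
#' Actinomycin-D-style decay normalization: each value is divided by the
#' matching reference (housekeeping) value and rescaled so the value at the
#' first timepoint is 100%.
#'
#' @param series numeric vector of target-gene abundances over time.
#' @param reference numeric vector of reference-gene abundances, same
#'   timepoints, all `> 0`.
#' @param timepoints optional numeric vector naming the timepoints.
#' @return numeric vector in percent units; first element is 100.
#' @examples
#' percentRemaining(c(10, 5), c(1, 1))   # 100 50
#' @export
percentRemaining <- function(series, reference, timepoints = NULL) {
    stopifnot(is.numeric(series), is.numeric(reference))
    if (length(series) != length(reference))
        stop("'series' and 'reference' must cover the same timepoints")
    if (!is.null(timepoints) && length(timepoints) != length(series))
        stop("'timepoints' length mismatch")
    if (any(reference <= 0))
        stop("reference values must be positive")
    norm <- series / reference
    if (norm[1L] <= 0)
        stop("series value at the first timepoint must be positive")
    out <- 100 * norm / norm[1L]
    if (!is.null(timepoints)) names(out) <- timepoints
    out
}

#' Gene-set z-score signature per sample
#'
#' Each gene is z-scored across samples; a sample's raw signature is the mean
#' z-score over the gene set. To remove the association expected of a random
#' gene set, the global signature (mean z-score over *all* genes) is
#' subtracted a priori. Zero-variance genes are dropped with a warning.
#'
#' @param x numeric matrix genes x samples, or a [TimeCourseExperiment].
#' @param geneSet character vector of gene ids; must intersect `rownames(x)`.
#' @return named numeric vector, one centered signature score per sample.
#' @examples
#' m <- matrix(c(0, 2, 0, 2), 2, 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' zscoreSignature(m, "g1")   # 0 0: set matches the global signature
#' @export
zscoreSignature <- function(x, geneSet) {
    if (is(x, "TimeCourseExperiment"))
        x <- SummarizedExperiment::assay(x)
    stopifnot(is.matrix(x), !is.null(rownames(x)))
    geneSet <- unique(geneSet)
    hit <- intersect(geneSet, rownames(x))
    if (!length(hit))
        stop("gene set does not intersect the expression matrix")
    sds <- apply(x, 1L, stats::sd)
    if (any(sds == 0)) {
        warning(sum(sds == 0), " zero-variance gene(s) dropped from z-scoring")
        x <- x[sds > 0, , drop = FALSE]
        hit <- intersect(hit, rownames(x))
        if (!length(hit))
            stop("gene set has no genes with nonzero variance")
    }
    z <- t(scale(t(x)))   # gene-wise center/scale across samples
    global <- colMeans(z)
    colMeans(z[hit, , drop = FALSE]) - global
}

#' Two-group Mann-Whitney comparison
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test, the comparison used for
#' late-ratio and persistence differences between motif classes. The exact
#' distribution is used when both groups have at most 8 observations and no
#' ties span the groups; otherwise the normal approximation with continuity
#' and tie correction is used.
#'
#' @param a,b numeric vectors, both non-empty.
#' @return list with `statistic` (the U statistic for `a` vs `b`), `p.value`
#'   (two-sided) and `method`.
#' @examples
#' compareGroups(c(1, 2, 3), c(4, 5, 6))$p.value   # 0.1 (exact, 2/20 splits)
#' @export
compareGroups <- function(a, b) {
    stopifnot(is.numeric(a), is.numeric(b))
    if (!length(a) || !length(b))
        stop("both groups must be non-empty")
    useExact <- length(a) <= 8 && length(b) <= 8
    res <- suppressWarnings(
        stats::wilcox.test(a, b, alternative = "two.sided", exact = useExact,
                           correct = TRUE))
    list(statistic = unname(res$statistic), p.value = res$p.value,
         method = res$method)
}
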