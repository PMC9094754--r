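#' Construct a TargetSet
#'
#' @param name label for the set.
#' @param targetGenes character vector of gene ids in the set.
#' @param universe character vector of gene ids the set was called from.
#' @return a [TargetSet].
#' @examples
#' ts <- TargetSet("demo", c("g1", "g2"), c("g1", "g2", "g3"))
#' targetGenes(ts)
#' @export
TargetSet <- function(name, targetGenes, universe) {
    new("TargetSet", name = as.character(name),
        targetGenes = unique(as.character(targetGenes)),
        universe = unique(as.character(universe)))
}

#' Accessors for TargetSet
#'
#' @param x a [TargetSet].
#' @return character vector of gene ids.
#' @name TargetSet-accessors
#' @aliases targetGenes universe
NULL

#' @rdname TargetSet-accessors
#' @export
setMethod("targetGenes", "TargetSet", function(x) x@targetGenes)

#' @rdname TargetSet-accessors
#' @export
setMethod("universe", "TargetSet", function(x) x@universe)

setMethod("show", "TargetSet", function(object) {
    cat(sprintf("TargetSet '%s': %d target(s) in a universe of %d gene(s)\n",
                object@name, length(object@targetGenes),
                length(object@universe)))
    invisible(object)
})

# Validate an enrichment table's required columns and p-value ranges.
.checkEnrichment <- function(tbl) {
    tbl <- as.data.frame(tbl)
    need <- c("gene_id", "input_reads", "log2_rpkm_fc", "pv", "pv_by")
    miss <- setdiff(need, colnames(tbl))
    if (length(miss))
        stop("enrichment table is missing column(s): ",
             paste(miss, collapse = ", "))
    if (!"max_score" %in% colnames(tbl))
        tbl$max_score <- 0         # UTRs with no overlapping peak score 0
    tbl$max_score[is.na(tbl$max_score)] <- 0
    for (p in c("pv", "pv_by"))
        if (any(is.na(tbl[[p]]) | tbl[[p]] <= 0 | tbl[[p]] > 1))
            stop("'", p, "' must lie in (0, 1]")
    tbl
}

#' Define the expressed transcriptome from input coverage
#'
#' The measured universe for target calling: genes whose input library shows
#' strictly more than `minReads` reads.
#'
#' @param tbl enrichment table (data.frame/DataFrame) with at least `gene_id`
#'   and `input_reads`.
#' @param minReads read threshold; strictly-greater comparison (default 10).
#' @return character vector of gene ids.
#' @examples
#' tbl <- data.frame(gene_id = c("a", "b"), input_reads = c(11, 10),
#'                   log2_rpkm_fc = 0, pv = 0.5, pv_by = 0.5)
#' defineTranscriptome(tbl)   # "a" only
#' @export
defineTranscriptome <- function(tbl, minReads = 10L) {
    tbl <- as.data.frame(tbl)
    stopifnot(all(c("gene_id", "input_reads") %in% colnames(tbl)))
    unique(tbl$gene_id[tbl$input_reads > minReads])
}

#' Call RIP-seq targets from per-UTR enrichment statistics
#'
#' A gene is called a binding target when any of the three criteria holds
#' (all comparisons strict):
#' \enumerate{
#'   \item BY-adjusted p `< pvByMax` and log2 IP/input RPKM fold change
#'     `> fcMinBY`;
#'   \item raw p `< pvMax` and fold change `> fcMinRaw`;
#'   \item maximal overlapping peak score `> maxScoreMin` and fold change
#'     `> fcMinPeak`.
#' }
#' UTRs with no overlapping peak carry `max_score = 0`. When several rows map
#' to one gene, the per-gene maxima of fold change and peak score and minima
#' of p-values are used. The universe is the expressed transcriptome
#' ([defineTranscriptome()]).
#'
#' @param tbl enrichment table with columns `gene_id`, `input_reads`,
#'   `log2_rpkm_fc`, `pv`, `pv_by` and optionally `max_score`.
#' @param pvByMax,fcMinBY,pvMax,fcMinRaw,maxScoreMin,fcMinPeak thresholds of
#'   the three criteria (defaults 0.02, 0.5, 0.02, 1.2, 500, 0.5).
#' @param minReads transcriptome read threshold (default 10).
#' @param name label for the returned set.
#' @return a [TargetSet].
#' @examples
#' tbl <- data.frame(gene_id = c("a", "b"), input_reads = 100,
#'                   log2_rpkm_fc = c(0.6, 1.0), pv = c(0.5, 0.5),
#'                   pv_by = c(0.01, 0.5), max_score = 0)
#' targetGenes(callTargets(tbl))   # "a" via criterion 1
#' @export
callTargets <- function(tbl, pvByMax = 0.02, fcMinBY = 0.5, pvMax = 0.02,
                        fcMinRaw = 1.2, maxScoreMin = 500, fcMinPeak = 0.5,
                        minReads = 10L, name = "targets") {
    tbl <- .checkEnrichment(tbl)
    if (!nrow(tbl))
        stop("empty enrichment table")
    # collapse multiple UTR regions per gene: strongest evidence wins
    if (anyDuplicated(tbl$gene_id)) {
        agg <- do.call(rbind, lapply(split(tbl, tbl$gene_id), function(d)
            data.frame(gene_id = d$gene_id[1L],
                       input_reads = max(d$input_reads),
                       log2_rpkm_fc = max(d$log2_rpkm_fc),
                       pv = min(d$pv), pv_by = min(d$pv_by),
                       max_score = max(d$max_score))))
    } else {
        agg <- tbl
    }
    hit <- (agg$pv_by < pvByMax & agg$log2_rpkm_fc > fcMinBY) |
           (agg$pv < pvMax & agg$log2_rpkm_fc > fcMinRaw) |
           (agg$max_score > maxScoreMin & agg$log2_rpkm_fc > fcMinPeak)
    uni <- defineTranscriptome(tbl, minReads = minReads)
    TargetSet(name, targetGenes = intersect(agg$gene_id[hit], uni),
              universe = uni)
}

#' Overlap between two target sets
#'
#' Intersection size and the percentage of set `b` that is also in set `a`,
#' the statistic used to report what fraction of one protein's bound mRNAs a
#' second protein also binds.
#'
#' @param a,b [TargetSet] objects (or character vectors of gene ids).
#' @return list with `nIntersection`, `nB`, `percentOfB` (full precision).
#' @examples
#' overlapStats(TargetSet("x", letters[1:6], letters),
#'              TargetSet("y", letters[4:9], letters))
#' @export
overlapStats <- function(a, b) {
    ma <- if (is(a, "TargetSet")) targetGenes(a) else unique(as.character(a))
    mb <- if (is(b, "TargetSet")) targetGenes(b) else unique(as.character(b))
    if (!length(mb))
        stop("set 'b' is empty: percentage undefined")
    ni <- length(intersect(ma, mb))
    list(nIntersection = ni, nB = length(mb), percentOfB = 100 * ni / length(mb))
}

#' Motif-class enrichment among targets (Fisher's exact test)
#'
#' Cross-tabulates target membership against a binary gene class (e.g.
#' CPE-containing vs not) over the target set's universe and tests the
#' association with a two-sided Fisher's exact test (conditional
#' maximum-likelihood odds ratio).
#'
#' @param targets a [TargetSet].
#' @param classLabels named logical vector over (at least) the universe, or a
#'   character vector of class-member gene ids.
#' @return list with `table` (2x2: target status x class status),
#'   `oddsRatio`, and two-sided `p.value`.
#' @examples
#' ts <- TargetSet("t", c("g1", "g2"), paste0("g", 1:8))
#' classEnrichment(ts, c("g1", "g2", "g3"))
#' @export
classEnrichment <- function(targets, classLabels) {
    stopifnot(is(targets, "TargetSet"))
    uni <- universe(targets)
    if (is.character(classLabels)) {
        lab <- uni %in% classLabels
    } else {
        if (is.null(names(classLabels)))
            stop("'classLabels' must be named by gene id (or be a character vector)")
        miss <- setdiff(uni, names(classLabels))
        if (length(miss))
            stop(length(miss), " universe gene(s) lack a class label")
        lab <- as.logical(classLabels[uni])
    }
    if (!any(lab) || all(lab))
        stop("class must be non-empty and non-exhaustive within the universe")
    isTarget <- uni %in% targetGenes(targets)
    tab <- table(target = factor(isTarget, c(TRUE, FALSE)),
                 class = factor(lab, c(TRUE, FALSE)))
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    list(table = tab, oddsRatio = unname(ft$estimate), p.value = ft$p.value)
}
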