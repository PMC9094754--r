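#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' UTRSet: a set of 3'-UTR sequences with gene/transcript annotation
#'
#' A thin extension of [Biostrings::DNAStringSet] holding one 3'-UTR sequence
#' per transcript, with `gene_id` and `transcript_id` kept in `mcols()`.
#' Sequences are canonicalized on construction (uppercase, RNA `U` mapped to
#' `T`) and restricted to the alphabet `A,C,G,T,N`; `N` never participates in
#' any motif match downstream.
#'
#' @slot .Data inherited DNAStringSet contents.
#' @seealso [UTRSet()], [readUTRFasta()], [scanUTRs()], [selectLongestUTR()]
#' @exportClass UTRSet
setClass("UTRSet", contains = "DNAStringSet")

setValidity("UTRSet", function(object) {
    msg <- NULL
    mc <- mcols(object)
    if (is.null(mc) || !all(c("gene_id", "transcript_id") %in% colnames(mc)))
        msg <- c(msg, "mcols must contain 'gene_id' and 'transcript_id'")
    else {
        if (anyDuplicated(mc$transcript_id))
            msg <- c(msg, "duplicated transcript_id")
        if (any(is.na(mc$gene_id)) || any(is.na(mc$transcript_id)))
            msg <- c(msg, "gene_id/transcript_id must not be NA")
    }
    if (length(object)) {
        freq <- Biostrings::alphabetFrequency(object, baseOnly = FALSE)
        allowed <- c("A", "C", "G", "T", "N")
        bad <- colSums(freq[, setdiff(colnames(freq), allowed), drop = FALSE])
        if (any(bad > 0))
            msg <- c(msg, paste0("sequence alphabet outside {A,C,G,T,N}: ",
                                 paste(names(bad)[bad > 0], collapse = ",")))
    }
    if (is.null(msg)) TRUE else msg
})

#' TimeCourseExperiment: expression over an LPS stimulation time course
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose `colData` carries a
#' numeric `timepoint` (hours post stimulation) for every sample, plus optional
#' `replicate` and `genotype` annotations. The single assay holds normalized
#' abundances on a linear scale (genes x samples).
#'
#' @seealso [TimeCourseExperiment()], [averageReplicates()], [peakNormalize()]
#' @exportClass TimeCourseExperiment
setClass("TimeCourseExperiment", contains = "SummarizedExperiment")

setValidity("TimeCourseExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    if (!"timepoint" %in% colnames(cd))
        return("colData must contain a numeric 'timepoint' column")
    tp <- cd$timepoint
    if (!is.numeric(tp) || anyNA(tp))
        return("'timepoint' must be numeric with no NA")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        return("assay rows must have unique gene ids as rownames")
    TRUE
})

#' TargetSet: a named gene set within a measured universe
#'
#' Holds the member genes of a target list (e.g. RIP-seq-called bound mRNAs)
#' together with the universe they were called from (e.g. the expressed
#' transcriptome), so downstream overlap and enrichment statistics always know
#' their denominator.
#'
#' @slot name single character label.
#' @slot targetGenes character vector of gene ids, a subset of `universe`.
#' @slot universe character vector of gene ids.
#' @seealso [TargetSet()], [callTargets()], [overlapStats()], [classEnrichment()]
#' @exportClass TargetSet
setClass("TargetSet",
    representation(name = "character", targetGenes = "character",
                   universe = "character"))

setValidity("TargetSet", function(object) {
    msg <- NULL
    if (length(object@name) != 1L)
        msg <- c(msg, "'name' must be a single string")
    if (anyDuplicated(object@targetGenes))
        msg <- c(msg, "duplicated gene ids in targetGenes")
    if (anyDuplicated(object@universe))
        msg <- c(msg, "duplicated gene ids in universe")
    if (!all(object@targetGenes %in% object@universe))
        msg <- c(msg, "targetGenes must be a subset of universe")
    if (is.null(msg)) TRUE else msg
})
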