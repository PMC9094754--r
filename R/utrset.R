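#' Construct a UTRSet
#'
#' Builds a [UTRSet] from raw sequences, canonicalizing them with
#' [normalizeSequence()] (uppercase, `U -> T`). Gene ids default to the
#' transcript ids (one isoform per gene).
#'
#' @param sequences character vector, `DNAStringSet` or `RNAStringSet` of
#'   3'-UTR sequences.
#' @param txIds character vector of unique transcript ids; defaults to
#'   `names(sequences)`.
#' @param geneIds character vector of gene ids, recycled checkably; defaults
#'   to `txIds`.
#' @return a [UTRSet].
#' @examples
#' u <- UTRSet(c(tx1 = "auuuauuua", tx2 = "TTTTAAT"), geneIds = c("g1", "g2"))
#' width(u)
#' @export
UTRSet <- function(sequences, txIds = names(sequences), geneIds = txIds) {
    if (is(sequences, "XStringSet"))
        sequences <- as.character(sequences)
    if (!is.character(sequences))
        stop("'sequences' must be a character vector or XStringSet")
    if (is.null(txIds))
        stop("transcript ids are required (names or 'txIds')")
    seqs <- normalizeSequence(unname(sequences))
    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- txIds
    mcols(dss) <- DataFrame(gene_id = as.character(geneIds),
                            transcript_id = as.character(txIds))
    new("UTRSet", dss)
}

#' Accessors for UTRSet annotation
#'
#' @param x a [UTRSet].
#' @return character vector of gene or transcript ids, parallel to `x`.
#' @name UTRSet-accessors
#' @aliases geneIds txIds
#' @examples
#' u <- UTRSet(c(tx1 = "ATTTA"), geneIds = "g1")
#' geneIds(u); txIds(u)
NULL

#' @rdname UTRSet-accessors
#' @export
setMethod("geneIds", "UTRSet", function(x) mcols(x)$gene_id)

#' @rdname UTRSet-accessors
#' @export
setMethod("txIds", "UTRSet", function(x) mcols(x)$transcript_id)

setMethod("show", "UTRSet", function(object) {
    cat("UTRSet with", length(object), "3'-UTR sequence(s) from",
        length(unique(geneIds(object))), "gene(s)\n")
    if (length(object)) {
        w <- Biostrings::width(object)
        cat("  length range:", min(w), "-", max(w), "nt\n")
        n <- min(length(object), 5L)
        for (i in seq_len(n)) {
            s <- as.character(object[[i]])
            if (nchar(s) > 40) s <- paste0(substr(s, 1, 37), "...")
            cat(sprintf("  %s (%s): %s\n", txIds(object)[i],
                        geneIds(object)[i], s))
        }
        if (length(object) > n) cat("  ...\n")
    }
    invisible(object)
})

#' Read 3'-UTR sequences from a FASTA file
#'
#' Headers are parsed as `>transcript_id [gene=GENE] ...`: the first
#' whitespace-delimited token is the transcript id and an optional `gene=` tag
#' supplies the gene id (otherwise gene id = transcript id). Sequences are
#' canonicalized to the DNA alphabet; duplicate transcript ids are an error.
#'
#' @param path path to a (multi-)FASTA file, DNA or RNA alphabet, any case.
#' @return a [UTRSet].
#' @export
readUTRFasta <- function(path) {
    if (!file.exists(path))
        stop("FASTA file not found: ", path)
    ss <- Biostrings::readBStringSet(path)
    if (length(ss) == 0L)
        stop("empty FASTA file: ", path)
    headers <- names(ss)
    tx <- sub("\\s.*$", "", headers)
    gene <- ifelse(grepl("gene=", headers),
                   sub(".*gene=([^\\s]+).*", "\\1", sub("\\s+$", "", headers)),
                   tx)
    gene <- sub("\\s.*$", "", gene)
    if (anyDuplicated(tx))
        stop("duplicate transcript id in FASTA: ",
             paste(unique(tx[duplicated(tx)]), collapse = ", "))
    UTRSet(as.character(ss), txIds = tx, geneIds = gene)
}

#' Write a UTRSet to FASTA
#'
#' Headers are written as `>transcript_id gene=gene_id`.
#'
#' @param x a [UTRSet].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeUTRFasta <- function(x, path) {
    stopifnot(is(x, "UTRSet"))
    out <- Biostrings::DNAStringSet(as.character(x))
    names(out) <- paste0(txIds(x), " gene=", geneIds(x))
    Biostrings::writeXStringSet(out, filepath = path)
    invisible(path)
}

#' Keep the longest 3'-UTR isoform per gene
#'
#' For each gene the transcript with the maximal UTR length is retained, the
#' reference-isoform rule used before motif counting and scoring. Ties are
#' broken deterministically by the lexicographically smallest transcript id.
#'
#' @param x a [UTRSet].
#' @return a [UTRSet] with one record per gene, sorted by gene id.
#' @name selectLongestUTR
#' @examples
#' u <- UTRSet(c(tx2 = "ATTTA", tx1 = "ATTTAG", tx3 = "TTTTAT"),
#'             geneIds = c("g1", "g1", "g2"))
#' txIds(selectLongestUTR(u))  # tx1 (longer) and tx3
#' @export
setMethod("selectLongestUTR", "UTRSet", function(x) {
    if (length(x) == 0L)
        stop("empty UTRSet")
    df <- data.frame(idx = seq_along(x), gene = geneIds(x), tx = txIds(x),
                     len = Biostrings::width(x), stringsAsFactors = FALSE)
    df <- df[order(df$gene, -df$len, df$tx), ]
    keep <- df$idx[!duplicated(df$gene)]
    x[sort(keep)][order(geneIds(x)[sort(keep)])]
})
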