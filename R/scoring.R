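#' The ARE:CPE score
#'
#' The log2 ratio between the number of AREs and the number of CPEs in a
#' gene's (longest) 3'-UTR. Positive scores mean ARE dominance (destabilizing
#' element excess), negative scores CPE dominance. Both counts must be at
#' least 1: genes carrying only one element class are excluded upstream
#' rather than smoothed with pseudocounts (see [buildScoreTable()]).
#'
#' @param nAre,nCpe integer vectors of ARE and CPE counts, both `>= 1`.
#' @return numeric vector, `log2(nAre / nCpe)`.
#' @examples
#' areCpeScore(5, 3)   # the 5-ARE / 3-CPE reporter, ~0.737
#' areCpeScore(4, 4)   # 0: balanced
#' @export
areCpeScore <- function(nAre, nCpe) {
    stopifnot(is.numeric(nAre), is.numeric(nCpe))
    if (any(nAre < 1) || any(nCpe < 1))
        stop("ARE:CPE score requires nAre >= 1 and nCpe >= 1; ",
             "genes lacking either element must be excluded first")
    log2(nAre / nCpe)
}

#' Dominance class from the ARE:CPE score
#'
#' Scores above zero are ARE-dominant, below zero CPE-dominant; an exact zero
#' (equal counts) is labelled `BALANCED` and belongs to neither group in
#' downstream comparisons.
#'
#' @param score numeric vector of finite ARE:CPE scores.
#' @return factor with levels `ARE_DOMINANT`, `CPE_DOMINANT`, `BALANCED`.
#' @examples
#' classifyDominance(c(0.737, -0.585, 0))
#' @export
classifyDominance <- function(score) {
    stopifnot(is.numeric(score), all(is.finite(score)))
    factor(ifelse(score > 0, "ARE_DOMINANT",
                  ifelse(score < 0, "CPE_DOMINANT", "BALANCED")),
           levels = c("ARE_DOMINANT", "CPE_DOMINANT", "BALANCED"))
}

#' ARE-level class from the raw ARE count
#'
#' Splits genes into `ARE_HIGH` (more than 4 AREs) and `ARE_LOW` (4 or fewer),
#' the single-element classification used as the contrast to dominance-based
#' classification.
#'
#' @param nAre integer vector of ARE counts, `>= 0`.
#' @return factor with levels `ARE_HIGH`, `ARE_LOW`.
#' @examples
#' classifyAreLevel(c(5, 4, 0))
#' @export
classifyAreLevel <- function(nAre) {
    stopifnot(is.numeric(nAre), all(nAre >= 0))
    factor(ifelse(nAre > 4, "ARE_HIGH", "ARE_LOW"),
           levels = c("ARE_HIGH", "ARE_LOW"))
}

#' Build the per-gene score table
#'
#' Takes a motif-count table (as from [scanUTRs()]) and returns one scored
#' record per gene that carries at least one ARE *and* at least one CPE;
#' genes with only one element class are dropped, with the counts of each
#' drop reason attached as the `"dropped"` attribute and reported via
#' `message()`.
#'
#' @param counts a `DataFrame`/data.frame with columns `gene_id`, `n_are`,
#'   `n_cpe` (one row per gene; duplicated gene ids are an error).
#' @param verbose report the drop summary (default `TRUE`).
#' @return a `DataFrame` with columns `gene_id`, `n_are`, `n_cpe`, `score`,
#'   `dominance`, `are_level`, sorted by gene id, with attribute `dropped`.
#' @examples
#' tbl <- S4Vectors::DataFrame(gene_id = c("a", "b", "c"),
#'                             n_are = c(2L, 0L, 2L), n_cpe = c(3L, 3L, 0L))
#' buildScoreTable(tbl, verbose = FALSE)   # only gene "a" survives
#' @export
buildScoreTable <- function(counts, verbose = TRUE) {
    counts <- as.data.frame(counts)
    need <- c("gene_id", "n_are", "n_cpe")
    if (!all(need %in% colnames(counts)))
        stop("'counts' must have columns ", paste(need, collapse = ", "))
    if (anyDuplicated(counts$gene_id))
        stop("duplicated gene_id in 'counts': ",
             paste(unique(counts$gene_id[duplicated(counts$gene_id)]),
                   collapse = ", "))
    noAre <- counts$n_are < 1
    noCpe <- counts$n_cpe < 1
    dropped <- c(no_are = sum(noAre & !noCpe), no_cpe = sum(noCpe & !noAre),
                 neither = sum(noAre & noCpe))
    .msg(verbose, sprintf(
        "buildScoreTable: %d gene(s) kept; dropped %d (no ARE), %d (no CPE), %d (neither)",
        sum(!noAre & !noCpe), dropped["no_are"], dropped["no_cpe"],
        dropped["neither"]))
    keep <- counts[!noAre & !noCpe, , drop = FALSE]
    score <- if (nrow(keep)) areCpeScore(keep$n_are, keep$n_cpe) else numeric(0)
    out <- DataFrame(gene_id = keep$gene_id,
                     n_are = as.integer(keep$n_are),
                     n_cpe = as.integer(keep$n_cpe),
                     score = score,
                     dominance = classifyDominance(score),
                     are_level = classifyAreLevel(keep$n_are))
    out <- out[order(out$gene_id), , drop = FALSE]
    attr(out, "dropped") <- dropped
    out
}
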