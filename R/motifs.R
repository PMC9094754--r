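#' Motif vocabularies
#'
#' `areMotif()` returns the AU-rich element pentamer (DNA alphabet).
#' `cpeMotifs()` returns the seven cytoplasmic polyadenylation element motifs
#' scanned by [countCPE()]: the canonical UUUUA(A)U family, its A/G- and
#' C-substituted variants, and the UUUUGU variant. `pasMotifs()` returns the
#' canonical polyadenylation-signal hexamers.
#'
#' @return character vector of motifs in the DNA alphabet.
#' @export
areMotif <- function() "ATTTA"

#' @rdname areMotif
#' @export
cpeMotifs <- function() c("TTTTAT", "TTTTAAT", "TTTTAAAT", "TTTTACT",
                          "TTTTCAT", "TTTTAAGT", "TTTTGT")

#' @rdname areMotif
#' @export
pasMotifs <- function() c("AATAAA", "ATTAAA")

#' Canonicalize a nucleotide sequence
#'
#' Uppercases and maps RNA `U` to DNA `T`; the result is restricted to the
#' alphabet `A,C,G,T,N`. Idempotent. Any other character is an error that
#' names the first offending position.
#'
#' @param x character vector of sequences (DNA or RNA, any case).
#' @return character vector of canonical DNA sequences.
#' @examples
#' normalizeSequence("auuua")          # "ATTTA"
#' normalizeSequence("AUUUAUUUA")      # "ATTTATTTA"
#' @export
normalizeSequence <- function(x) {
    if (!is.character(x))
        stop("'x' must be a character vector")
    if (any(!nzchar(x) | is.na(x)))
        stop("empty or NA sequence")
    out <- chartr("u", "T", x)
    out <- chartr("U", "T", toupper(out))
    bad <- regexpr("[^ACGTN]", out)
    if (any(bad > 0)) {
        i <- which(bad > 0)[1L]
        stop(sprintf("invalid character '%s' at position %d of sequence %d",
                     substr(out[i], bad[i], bad[i]), bad[i], i))
    }
    out
}

# Coerce character/XString/XStringSet/UTRSet input to a DNAStringSet without
# re-validating already-canonical UTRSet contents.
.asDNASet <- function(x) {
    if (is(x, "UTRSet")) return(Biostrings::DNAStringSet(as.character(x)))
    if (is(x, "DNAStringSet")) return(x)
    if (is(x, "XString")) return(Biostrings::DNAStringSet(as.character(x)))
    # empty strings are legal scan inputs (zero matches), but not legal
    # normalizeSequence inputs
    ok <- nzchar(x) & !is.na(x)
    x[ok] <- normalizeSequence(x[ok])
    Biostrings::DNAStringSet(x)
}

# All occurrences of a motif vocabulary in one DNAStringSet, overlapping starts
# included. Returns a DataFrame: seq (index), motif, start, end (1-based,
# closed, Biostrings convention; width == nchar(motif)).
.findMotifs <- function(seqs, motifs) {
    hits <- lapply(motifs, function(m) {
        mi <- Biostrings::vmatchPattern(m, seqs)
        n <- S4Vectors::elementNROWS(mi)
        DataFrame(seq = rep(seq_along(seqs), n),
                  motif = rep(m, sum(n)),
                  start = unlist(lapply(mi, IRanges::start), use.names = FALSE),
                  end = unlist(lapply(mi, IRanges::end), use.names = FALSE))
    })
    out <- do.call(rbind, hits)
    out[order(out$seq, out$start, out$motif), , drop = FALSE]
}

#' Count AU-rich elements (overlapping AUUUA starts)
#'
#' Counts every start position at which the ARE pentamer `ATTTA` (`AUUUA` on
#' the mRNA) matches, so overlapping repeats are all counted: a maximal run
#' `A(TTTA)^k` contributes exactly `k`. `N` never matches.
#'
#' @param x sequences: character vector, `DNAString(Set)`, or [UTRSet].
#' @return integer vector of ARE counts, one per sequence.
#' @examples
#' countARE("ATTTATTTA")  # 2 overlapping AREs
#' @export
countARE <- function(x) {
    seqs <- .asDNASet(x)
    as.integer(Biostrings::vcountPattern(areMotif(), seqs))
}

#' Count cytoplasmic polyadenylation elements
#'
#' Counts all occurrences of the seven CPE motifs (see [cpeMotifs()]) across
#' all start positions; distance-to-PAS rules are deliberately not applied
#' (see [classifyCPEPositional()] for the positional rule). The seven motifs
#' are pairwise exclusive at any shared start, so the plain sum is an
#' occurrence count without double-counting.
#'
#' @inheritParams countARE
#' @return integer vector of CPE counts, one per sequence.
#' @examples
#' countCPE("TTTTATTTTGT")  # TTTTAT at 1, TTTTGT at 6
#' @export
countCPE <- function(x) {
    seqs <- .asDNASet(x)
    counts <- vapply(cpeMotifs(), function(m)
        Biostrings::vcountPattern(m, seqs), integer(length(seqs)))
    if (length(seqs) == 1L) return(as.integer(sum(counts)))
    as.integer(rowSums(counts))
}

#' Locate CPE motif matches in a single sequence
#'
#' @param x a single sequence (character, `DNAString`, or length-1 set).
#' @return a `DataFrame` with columns `motif`, `start`, `end` (1-based,
#'   closed coordinates), sorted by start.
#' @examples
#' findCPEMatches("TTTTATTTTGT")
#' @export
findCPEMatches <- function(x) {
    seqs <- .asDNASet(x)
    if (length(seqs) != 1L)
        stop("'x' must be a single sequence")
    hits <- .findMotifs(seqs, cpeMotifs())
    hits[, c("motif", "start", "end"), drop = FALSE]
}

#' @rdname findCPEMatches
#' @export
findAREMatches <- function(x) {
    seqs <- .asDNASet(x)
    if (length(seqs) != 1L)
        stop("'x' must be a single sequence")
    hits <- .findMotifs(seqs, areMotif())
    hits[, c("motif", "start", "end"), drop = FALSE]
}

#' Locate polyadenylation-signal hexamers
#'
#' @inheritParams findCPEMatches
#' @param pas character vector of PAS hexamers to scan for.
#' @return a `DataFrame` with columns `motif`, `start`, `end`, sorted by start.
#' @examples
#' findPAS("AATAAATTAAA")
#' @export
findPAS <- function(x, pas = pasMotifs()) {
    if (length(pas) == 0L) stop("'pas' must be non-empty")
    seqs <- .asDNASet(x)
    if (length(seqs) != 1L)
        stop("'x' must be a single sequence")
    hits <- .findMotifs(seqs, pas)
    hits[, c("motif", "start", "end"), drop = FALSE]
}

#' Positional CPE call: a CPE within reach of a polyadenylation signal
#'
#' Declares a 3'-UTR CPE-containing in the positional sense when at least one
#' CPE motif starts within `maxDistance` nucleotides upstream of (or at) some
#' PAS start. If `requirePAS` and no PAS is found the call is `FALSE`. The
#' distance window is configurable because published optimal CPE-PAS
#' distances vary between predictors.
#'
#' @inheritParams findCPEMatches
#' @param pas PAS hexamers (default `AATAAA`, `ATTAAA`).
#' @param maxDistance window in nt upstream of a PAS start within which a CPE
#'   start counts (default 100).
#' @param requirePAS if `TRUE` (default) a sequence without any PAS is never
#'   positional-CPE positive.
#' @return a list with `positional` (logical) and `reason` (character).
#' @examples
#' classifyCPEPositional(paste0("TTTTAT", strrep("C", 30), "AATAAA"))$positional
#' @export
classifyCPEPositional <- function(x, pas = pasMotifs(), maxDistance = 100L,
                                  requirePAS = TRUE) {
    stopifnot(maxDistance > 0)
    seqs <- .asDNASet(x)
    if (length(seqs) != 1L)
        stop("'x' must be a single sequence")
    cpe <- findCPEMatches(seqs)
    if (nrow(cpe) == 0L)
        return(list(positional = FALSE, reason = "no CPE motif"))
    pasHits <- findPAS(seqs, pas)
    if (nrow(pasHits) == 0L) {
        if (requirePAS)
            return(list(positional = FALSE, reason = "no PAS"))
        return(list(positional = TRUE,
                    reason = "CPE present; PAS not required"))
    }
    for (p in pasHits$start) {
        d <- p - cpe$start
        ok <- which(d >= 0 & d <= maxDistance)
        if (length(ok))
            return(list(positional = TRUE,
                        reason = sprintf("%s at %d is %d nt upstream of PAS at %d",
                                         cpe$motif[ok[1L]], cpe$start[ok[1L]],
                                         d[ok[1L]], p)))
    }
    list(positional = FALSE,
         reason = sprintf("no CPE within %d nt upstream of a PAS", maxDistance))
}

#' ARE-containing rule
#'
#' An mRNA is called ARE-containing when its 3'-UTR carries two or more
#' AUUUA pentamers.
#'
#' @param nAre integer vector of ARE counts.
#' @return logical vector.
#' @examples
#' isAREContaining(c(0, 1, 2))  # FALSE FALSE TRUE
#' @export
isAREContaining <- function(nAre) {
    stopifnot(is.numeric(nAre), all(nAre >= 0))
    nAre >= 2
}

#' Inactivate motif matches by point mutation
#'
#' Reproduces in silico the reporter-construct strategy of killing individual
#' ARE/CPE motifs by point substitution: each targeted match is mutated (same
#' sequence length) until it no longer matches any ARE or CPE motif and no new
#' ARE/CPE match has been created anywhere in the sequence. Substitutions are
#' drawn deterministically from `seed`; positions inside the match are
#' replaced by `G` or `C` (never part of a poly-U/A core) one at a time until
#' the constraint holds.
#'
#' @param x a single canonical sequence.
#' @param targets a `DataFrame`/data.frame of matches with `start` and `end`
#'   columns (1-based, closed), e.g. from [findCPEMatches()] or
#'   [findAREMatches()]; every target must currently match.
#' @param seed integer seed making the substitutions reproducible.
#' @param maxTries retry budget per motif before giving up.
#' @return the mutated sequence as a character string of identical length.
#' @examples
#' inactivateMotifs("TTTTAAT", findCPEMatches("TTTTAAT"), seed = 1)
#' @export
inactivateMotifs <- function(x, targets, seed = 1L, maxTries = 100L) {
    seqs <- .asDNASet(x)
    if (length(seqs) != 1L)
        stop("'x' must be a single sequence")
    s <- as.character(seqs)
    targets <- as.data.frame(targets)
    if (nrow(targets) == 0L)
        return(s)
    if (any(targets$start < 1 | targets$end > nchar(s) |
            targets$end < targets$start))
        stop("target coordinates outside the sequence")
    before <- .findMotifs(seqs, c(areMotif(), cpeMotifs()))
    if (!all(targets$start %in% before$start))
        stop("a target does not match any ARE/CPE motif in 'x'")
    chars <- strsplit(s, "")[[1L]]
    .withSeed(seed, {
        for (i in seq_len(nrow(targets))) {
            pos <- seq(targets$start[i], targets$end[i])
            done <- FALSE
            for (try in seq_len(maxTries)) {
                trial <- chars
                nMut <- min(length(pos), 2L + (try - 1L) %/% 10L)
                at <- sample(pos, nMut)
                trial[at] <- sample(c("G", "C"), nMut, replace = TRUE)
                cand <- paste(trial, collapse = "")
                hits <- .findMotifs(Biostrings::DNAStringSet(cand),
                                    c(areMotif(), cpeMotifs()))
                # targeted starts must be dead; every surviving match must be
                # one that already existed (no new motif anywhere)
                okDead <- !any(hits$start %in% targets$start[seq_len(i)])
                okNoNew <- all(paste(hits$motif, hits$start) %in%
                               paste(before$motif, before$start))
                if (okDead && okNoNew) {
                    chars <- trial
                    done <- TRUE
                    break
                }
            }
            if (!done)
                stop("could not inactivate motif at position ",
                     targets$start[i], " within the retry budget")
        }
    })
    paste(chars, collapse = "")
}

#' Scan a UTRSet for ARE and CPE content
#'
#' Runs the ARE and CPE counters (and optionally the positional CPE rule) over
#' the longest-isoform UTR of each gene, the standard first step before
#' scoring.
#'
#' @param x a [UTRSet].
#' @param longestPerGene collapse to one longest UTR per gene first
#'   (default `TRUE`).
#' @param positional also evaluate the positional CPE rule
#'   (default `FALSE`).
#' @param pas,pasWindow,requirePAS passed to [classifyCPEPositional()].
#' @return a `DataFrame` with columns `gene_id`, `transcript_id`,
#'   `utr_length`, `n_are`, `n_cpe`, `cpe_positional`, sorted by gene id.
#' @examples
#' u <- UTRSet(c(tx1 = "ATTTATTTAGTTTTAT"), geneIds = "g1")
#' scanUTRs(u)
#' @export
scanUTRs <- function(x, longestPerGene = TRUE, positional = FALSE,
                     pas = pasMotifs(), pasWindow = 100L, requirePAS = TRUE) {
    stopifnot(is(x, "UTRSet"))
    if (longestPerGene)
        x <- selectLongestUTR(x)
    pos <- rep(NA, length(x))
    if (positional)
        pos <- vapply(seq_along(x), function(i)
            classifyCPEPositional(x[i], pas = pas, maxDistance = pasWindow,
                                  requirePAS = requirePAS)$positional,
            logical(1L))
    out <- DataFrame(gene_id = geneIds(x),
                     transcript_id = txIds(x),
                     utr_length = Biostrings::width(x),
                     n_are = countARE(x),
                     n_cpe = countCPE(x),
                     cpe_positional = as.logical(pos))
    out[order(out$gene_id), , drop = FALSE]
}
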