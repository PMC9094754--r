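# Independent oracles used to validate the package's counting and testing
# machinery. These deliberately use nothing from the code paths they check:
# plain substring scans, full permutation enumeration, and closed-form
# hypergeometric combinatorics.

# All-offset brute-force motif count (overlapping starts included).
bruteCountMotif <- function(seq, motif) {
  n <- nchar(seq); m <- nchar(motif)
  if (n < m) return(0L)
  starts <- seq_len(n - m + 1L)
  sum(substring(seq, starts, starts + m - 1L) == motif)
}

bruteCountARE <- function(seq) bruteCountMotif(seq, "ATTTA")

bruteCountCPE <- function(seq) {
  motifs <- c("TTTTAT", "TTTTAAT", "TTTTAAAT", "TTTTACT", "TTTTCAT",
              "TTTTAAGT", "TTTTGT")
  sum(vapply(motifs, bruteCountMotif, integer(1L), seq = seq))
}

# All motif starts over a vocabulary (for the start-exclusivity property).
bruteMotifStarts <- function(seq, motifs) {
  out <- lapply(motifs, function(m) {
    n <- nchar(seq); k <- nchar(m)
    if (n < k) return(integer(0))
    starts <- seq_len(n - k + 1L)
    starts[substring(seq, starts, starts + k - 1L) == m]
  })
  names(out) <- motifs
  out
}

# Random AT-rich test sequence; the skew makes ARE/CPE hits common.
randomSeq <- function(len, pN = 0.02) {
  paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
               prob = c(0.35, 0.12, 0.11, 0.40, pN)), collapse = "")
}

# Two-sided Mann-Whitney p by full enumeration of all choose(na+nb, na)
# group assignments of the pooled values (no ties assumed).
permutationMannWhitneyP <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  uStat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  uObs <- uStat(a, b)
  idx <- utils::combn(length(pooled), na)
  us <- apply(idx, 2L, function(i) uStat(pooled[i], pooled[-i]))
  pLow <- mean(us <= uObs)
  pHigh <- mean(us >= uObs)
  min(1, 2 * min(pLow, pHigh))
}

# Two-sided Fisher p for a 2x2 table by exhaustive enumeration over all
# tables with the observed margins, using closed-form combinatorics.
enumFisherP <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  ks <- max(0L, c1 - r2):min(r1, c1)
  prob <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  pObs <- choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  sum(prob[prob <= pObs * (1 + 1e-7)])
}
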