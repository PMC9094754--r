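test_that("sequence normalization canonicalizes case and RNA alphabet", {
  expect_equal(normalizeSequence("auuua"), "ATTTA")
  expect_equal(normalizeSequence("AUUUAUUUA"), "ATTTATTTA")
  expect_equal(normalizeSequence(c("acgun", "ACGTN")), c("ACGTN", "ACGTN"))
  # idempotent
  x <- normalizeSequence("uuAUgc")
  expect_equal(normalizeSequence(x), x)
  expect_error(normalizeSequence("AXTTA"), "position 2")
  expect_error(normalizeSequence(""), "empty")
})

test_that("ARE counting includes overlapping starts", {
  expect_equal(countARE("ATTTA"), 1L)
  expect_equal(countARE("ATTTATTTA"), 2L)
  expect_equal(countARE("GCGCGC"), 0L)
  expect_equal(countARE(""), 0L)
  # hand enumeration: six overlapping ATTTA starts
  expect_equal(countARE("ATTTATTTATTTATTTATTTATTTA"), 6L)
  # A(TTTA)^k runs count exactly k
  for (k in 1:8)
    expect_equal(countARE(paste0("A", strrep("TTTA", k))), k)
  # N never matches
  expect_equal(countARE("ANTTA"), 0L)
})

test_that("CPE matching finds the seven motifs at all starts", {
  m <- findCPEMatches("TTTTAAT")
  expect_equal(nrow(m), 1L)
  expect_equal(m$motif, "TTTTAAT")
  expect_equal(m$start, 1L)
  # the reporter-style inactivated motif no longer matches
  expect_equal(nrow(findCPEMatches("TTGGGAT")), 0L)
  # exhaustive hand scan: TTTTAT at 1, TTTTGT at 6 (1-based)
  m2 <- findCPEMatches("TTTTATTTTGT")
  expect_equal(m2$motif, c("TTTTAT", "TTTTGT"))
  expect_equal(m2$start, c(1L, 6L))
  expect_equal(m2$end - m2$start + 1L, nchar(m2$motif))
  expect_equal(countCPE("TTTTAT"), 1L)
  expect_equal(countCPE("TTTTATTTTAT"), 2L)
  expect_equal(countCPE("AAAAAA"), 0L)
})

test_that("motif counters equal the brute-force all-offset oracle", {
  set.seed(42)
  for (i in 1:300) {
    s <- randomSeq(sample(20:300, 1))
    expect_equal(countARE(s), bruteCountARE(s), info = s)
    expect_equal(countCPE(s), bruteCountCPE(s), info = s)
  }
})

test_that("no two distinct CPE motifs match at the same start", {
  set.seed(7)
  for (i in 1:200) {
    s <- randomSeq(sample(50:400, 1), pN = 0)
    starts <- unlist(bruteMotifStarts(s, cpeMotifs()))
    expect_false(anyDuplicated(starts) > 0, info = s)
  }
})

test_that("PAS scanning and the positional CPE rule respect the window", {
  p <- findPAS("AATAAA")
  expect_equal(p$start, 1L)
  expect_equal(nrow(findPAS("GGGGGG")), 0L)
  # hand scan of AATAAATTAAA: AATAAA at 1; ATTAAA at 6 (1-based)
  p2 <- findPAS("AATAAATTAAA")
  expect_equal(p2$motif, c("AATAAA", "ATTAAA"))
  expect_equal(p2$start, c(1L, 6L))

  spacer30 <- strrep("C", 30)
  hit <- classifyCPEPositional(paste0("TTTTAT", spacer30, "AATAAA"))
  expect_true(hit$positional)
  # CPE but no PAS, PAS required
  miss <- classifyCPEPositional(paste0("TTTTAT", spacer30))
  expect_false(miss$positional)
  expect_match(miss$reason, "no PAS")
  # CPE too far upstream of the PAS
  far <- classifyCPEPositional(paste0("TTTTGT", strrep("C", 400), "AATAAA"))
  expect_false(far$positional)
  expect_true(classifyCPEPositional(paste0("TTTTAT", spacer30),
                                    requirePAS = FALSE)$positional)
})

test_that("ARE-containing rule is two or more pentamers", {
  expect_equal(isAREContaining(c(0, 1, 2, 5)), c(FALSE, FALSE, TRUE, TRUE))
})

test_that("motif inactivation kills targets without creating new motifs", {
  for (motif in c("TTTTAAT", "TTTTACT")) {
    mut <- inactivateMotifs(motif, findCPEMatches(motif), seed = 1)
    expect_equal(nchar(mut), nchar(motif))
    expect_equal(countCPE(mut), 0L)
    expect_equal(countARE(mut), 0L)
  }
  # zero targets: identity
  expect_equal(inactivateMotifs("ATTTA", findCPEMatches("ATTTA")), "ATTTA")
  # embedded case: only the targeted CPE dies, total matches strictly drop,
  # and nothing new appears anywhere
  s <- generateUTR(3, 2, 300, seed = 5)
  cpe <- findCPEMatches(s)
  mut <- inactivateMotifs(s, cpe[1, ], seed = 2)
  expect_equal(nchar(mut), nchar(s))
  expect_lt(countARE(mut) + countCPE(mut), countARE(s) + countCPE(s))
  expect_false(cpe$start[1] %in% findCPEMatches(mut)$start)
  expect_equal(countARE(mut), 3L)   # AREs untouched
  # deterministic given seed
  expect_equal(inactivateMotifs(s, cpe[1, ], seed = 2), mut)
})

test_that("longest-UTR selection keeps one isoform per gene with tie-break", {
  u <- UTRSet(c(tx1 = strrep("C", 100), tx2 = strrep("C", 200),
                tx3 = strrep("G", 150)),
              geneIds = c("g1", "g1", "g2"))
  sel <- selectLongestUTR(u)
  expect_equal(txIds(sel), c("tx2", "tx3"))
  # tie broken by lexicographically smallest transcript id
  tie <- UTRSet(c(tx2 = strrep("A", 150), tx1 = strrep("G", 150)),
                geneIds = c("g1", "g1"))
  expect_equal(txIds(selectLongestUTR(tie)), "tx1")
  single <- UTRSet(c(tx9 = "ACGT"), geneIds = "g9")
  expect_equal(txIds(selectLongestUTR(single)), "tx9")
})

test_that("scanUTRs produces per-gene counts on the longest isoform", {
  u <- UTRSet(c(tx1 = "ATTTATTTA", tx2 = paste0("ATTTA", strrep("C", 20)),
                tx3 = "TTTTATTTTGT"),
              geneIds = c("g1", "g1", "g2"))
  tab <- scanUTRs(u)
  expect_equal(tab$gene_id, c("g1", "g2"))
  expect_equal(tab$transcript_id, c("tx2", "tx3"))  # tx2 is longer
  expect_equal(tab$n_are, c(1L, 0L))
  expect_equal(tab$n_cpe, c(0L, 2L))
  pos <- scanUTRs(UTRSet(c(t1 = paste0("TTTTAT", strrep("C", 10), "AATAAA")),
                         geneIds = "g"), positional = TRUE)
  expect_true(pos$cpe_positional)
})

test_that("UTRSet validates alphabet and id uniqueness", {
  expect_error(UTRSet(c(tx1 = "ACGT", tx1 = "ACGT")), "duplicate|unique")
  expect_error(UTRSet(c(tx1 = "AXGT")), "invalid character")
  u <- UTRSet(c(tx1 = "acgu"), geneIds = "g1")
  expect_equal(as.character(u[[1]]), "ACGT")
})
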