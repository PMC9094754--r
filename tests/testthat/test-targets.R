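enrRow <- function(gene, reads = 100, fc = 0, pv = 0.5, pvBy = 0.5, ms = 0) {
  data.frame(gene_id = gene, input_reads = reads, log2_rpkm_fc = fc,
             pv = pv, pv_by = pvBy, max_score = ms)
}

test_that("transcriptome definition uses strictly more than the read cutoff", {
  tbl <- rbind(enrRow("a", reads = 11), enrRow("b", reads = 10),
               enrRow("c", reads = 0))
  expect_equal(defineTranscriptome(tbl), "a")
  expect_equal(defineTranscriptome(tbl[0, ]), character(0))
})

test_that("target calling applies the three criteria with strict inequalities", {
  # criterion 1: pvBY < 0.02 and FC > 0.5
  t1 <- callTargets(enrRow("a", fc = 0.6, pvBy = 0.01))
  expect_equal(targetGenes(t1), "a")
  # fails all three clauses: pvBY too big for (1), FC too small for (2)
  t2 <- callTargets(enrRow("a", fc = 1.0, pv = 0.01, pvBy = 0.5))
  expect_equal(targetGenes(t2), character(0))
  # criterion 2: pv < 0.02 and FC > 1.2
  t2b <- callTargets(enrRow("a", fc = 1.3, pv = 0.01, pvBy = 0.5))
  expect_equal(targetGenes(t2b), "a")
  # criterion 3: MaxScore > 500 and FC > 0.5
  t3 <- callTargets(enrRow("a", fc = 0.6, ms = 600))
  expect_equal(targetGenes(t3), "a")
  # boundaries are exclusive
  expect_equal(targetGenes(callTargets(enrRow("a", fc = 0.5, pvBy = 0.01))),
               character(0))
  expect_equal(targetGenes(callTargets(enrRow("a", fc = 0.6, ms = 500))),
               character(0))
  expect_error(callTargets(enrRow("a", pv = 0)), "\\(0, 1\\]")
  expect_error(callTargets(enrRow("a", pv = 1.5)), "\\(0, 1\\]")
})

test_that("missing max_score defaults to 0 and regions collapse per gene", {
  tbl <- rbind(enrRow("a", fc = 0.6, pvBy = 0.5),
               enrRow("a", fc = 0.4, pvBy = 0.01))
  tbl$region_id <- c("a_utr1", "a_utr2")
  # per-gene maxima/minima: fc 0.6 with pvBY 0.01 -> target
  expect_equal(targetGenes(callTargets(tbl)), "a")
  noMs <- enrRow("b", fc = 0.6, pvBy = 0.01)
  noMs$max_score <- NULL
  expect_equal(targetGenes(callTargets(noMs)), "b")
})

test_that("target calling is monotone in its thresholds", {
  set.seed(21)
  g <- generateEnrichmentTable(300, seed = 21)
  base <- targetGenes(callTargets(g$table))
  relaxed <- targetGenes(callTargets(g$table, pvByMax = 0.1, pvMax = 0.1,
                                 fcMinBY = 0.2, fcMinRaw = 0.8,
                                 maxScoreMin = 100, fcMinPeak = 0.2))
  expect_true(all(base %in% relaxed))
})

test_that("overlap statistics report the intersection as a share of b", {
  uni <- sprintf("g%03d", 1:300)
  a <- TargetSet("a", uni[1:10], uni)
  expect_equal(overlapStats(a, a),
               list(nIntersection = 10L, nB = 10L, percentOfB = 100))
  b <- TargetSet("b", uni[11:20], uni)
  expect_equal(overlapStats(a, b)$percentOfB, 0)
  # symmetric intersection count
  c1 <- TargetSet("c", uni[5:14], uni)
  expect_equal(overlapStats(a, c1)$nIntersection,
               overlapStats(c1, a)$nIntersection)
  expect_error(overlapStats(a, TargetSet("e", character(0), uni)), "empty")
})

test_that("class enrichment reproduces Fisher's exact test structure", {
  uni <- sprintf("g%03d", 1:40)
  # balanced 2x2 with no association: OR 1, p 1
  ts <- TargetSet("t", uni[1:20], uni)
  res <- classEnrichment(ts, c(uni[1:10], uni[21:30]))
  expect_equal(unname(res$table[1, ]), c(10L, 10L))
  expect_equal(unname(res$table[2, ]), c(10L, 10L))
  expect_equal(res$p.value, 1)
  expect_equal(res$oddsRatio, 1, tolerance = 1e-6)
  # perfect association [[5,0],[0,5]] against the enumeration oracle
  uni10 <- letters[1:10]
  ts2 <- TargetSet("t2", uni10[1:5], uni10)
  res2 <- classEnrichment(ts2, uni10[1:5])
  expect_equal(res2$p.value, enumFisherP(5, 0, 0, 5))
  expect_error(classEnrichment(ts2, character(0)), "non-empty")
  expect_error(classEnrichment(ts2, uni10), "non-exhaustive")
})

test_that("class enrichment equals the hypergeometric oracle across margins", {
  set.seed(31)
  for (i in 1:60) {
    a <- sample(1:6, 1); b <- sample(1:6, 1)
    c_ <- sample(1:6, 1); d <- sample(1:6, 1)
    n <- a + b + c_ + d
    uni <- sprintf("u%02d", seq_len(n))
    targets <- uni[seq_len(a + b)]
    classGenes <- c(uni[seq_len(a)], uni[a + b + seq_len(c_)])
    res <- classEnrichment(TargetSet("t", targets, uni), classGenes)
    expect_equal(res$p.value, enumFisherP(a, b, c_, d), tolerance = 1e-12,
                 info = paste(a, b, c_, d))
  }
})

test_that("TargetSet enforces targetGenes within the universe", {
  expect_error(TargetSet("bad", c("x"), c("y")), "subset")
  ts <- TargetSet("ok", "y", c("x", "y"))
  expect_equal(universe(ts), c("x", "y"))
})
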