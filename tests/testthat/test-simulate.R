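test_that("generated UTRs carry exactly the planted motif counts", {
  u0 <- generateUTR(0, 0, 200, seed = 4)
  expect_equal(nchar(u0), 200L)
  expect_equal(countARE(u0), 0L)
  expect_equal(countCPE(u0), 0L)

  u <- generateUTR(5, 3, 500, seed = 1)
  expect_equal(countARE(u), 5L)
  expect_equal(countCPE(u), 3L)

  # deterministic given seed
  expect_equal(generateUTR(5, 3, 500, seed = 1), u)
  expect_false(generateUTR(5, 3, 500, seed = 2) == u)

  withPas <- generateUTR(2, 2, 300, seed = 8, withPAS = TRUE)
  expect_equal(nrow(findPAS(withPas)), 1L)

  expect_error(generateUTR(60, 0, 100, seed = 1), "cannot fit")
})

test_that("round-trip: re-scanning generated UTRs reproduces planted counts", {
  set.seed(17)
  grid <- data.frame(nA = sample(0:10, 40, replace = TRUE),
                     nC = sample(0:6, 40, replace = TRUE),
                     len = sample(200:1200, 40, replace = TRUE))
  for (i in seq_len(nrow(grid))) {
    s <- generateUTR(grid$nA[i], grid$nC[i], grid$len[i], seed = 1000 + i,
                     withPAS = i %% 2 == 0)
    expect_identical(countARE(s), grid$nA[i])
    expect_identical(countCPE(s), grid$nC[i])
    expect_identical(nchar(s), grid$len[i])
  }
})

test_that("time-course generator honors the closed-form decay law", {
  noiseless <- kineticParams(noiseSigma = 0)
  # zero decay: flat after the peak, 9 h / peak ratio is 1
  flat <- kineticParams(k0 = 0, alphaAre = 0, alphaCpe = 0, noiseSigma = 0)
  tc <- generateTimeCourse(0, 0, flat, seed = 2)
  expect_equal(unname(tc[1, "9"] / max(tc[1, ])), 1)

  # half-life 3 h with peak forced at 6 h: 9 h / peak = 0.5 exactly
  half <- kineticParams(k0 = log(2) / 3, alphaAre = 0, alphaCpe = 0,
                        noiseSigma = 0, peakTimes = 6)
  tc2 <- generateTimeCourse(0, 0, half, seed = 3)
  expect_equal(unname(tc2[1, "9"] / max(tc2[1, ])), 0.5)

  # same seed, same course; decay rate clipped at zero
  expect_equal(generateTimeCourse(3, 2, noiseless, seed = 7),
               generateTimeCourse(3, 2, noiseless, seed = 7))
  tc3 <- generateTimeCourse(0, 8, noiseless, seed = 7)
  expect_equal(unname(attr(tc3, "decayRate")), 0)
})

test_that("enrichment generator produces a truth-consistent table", {
  g <- generateEnrichmentTable(500, seed = 7)
  expect_equal(nrow(g$table), 500L)
  expect_true(all(g$table$pv > 0 & g$table$pv <= 1))
  expect_true(all(g$table$pv_by >= g$table$pv))
  expect_true(all(g$table$max_score == 0))
  # determinism and the zero-target edge
  g2 <- generateEnrichmentTable(500, seed = 7)
  expect_identical(g$table, g2$table)
  none <- generateEnrichmentTable(100, enrichmentParams(fracTargets = 0),
                                  seed = 1)
  expect_equal(sum(none$truth$is_target), 0L)
})

test_that("target calling recovers the planted truth at default effect sizes", {
  g <- generateEnrichmentTable(1000, seed = 7)
  called <- targetGenes(callTargets(g$table))
  uni <- defineTranscriptome(g$table)
  truthIn <- g$truth$gene_id[g$truth$is_target & g$truth$gene_id %in% uni]
  nullIn <- setdiff(uni, g$truth$gene_id[g$truth$is_target])
  sens <- length(intersect(called, truthIn)) / length(truthIn)
  fpr <- length(intersect(called, nullIn)) / length(nullIn)
  expect_gte(sens, 0.9)
  expect_lte(fpr, 0.05)
})

test_that("a study bundle is deterministic and internally cross-referenced", {
  spec <- syntheticSpec(nGenes = 15, seed = 5)
  st <- generateStudy(spec)
  st2 <- generateStudy(spec)
  expect_identical(as.character(st$utrs), as.character(st2$utrs))
  expect_identical(st$truth, st2$truth)
  expect_equal(SummarizedExperiment::assay(st$expression),
               SummarizedExperiment::assay(st2$expression))
  # oracle round-trip against the scanners
  expect_equal(countARE(st$utrs), st$truth$n_are)
  expect_equal(countCPE(st$utrs), st$truth$n_cpe)
  expect_equal(unname(Biostrings::width(st$utrs)), st$truth$utr_length)
  # all three tables speak the same gene namespace
  expect_equal(geneIds(st$utrs), st$truth$gene_id)
  expect_equal(st$enrichment$gene_id, st$truth$gene_id)
  expect_equal(rownames(st$expression), st$truth$gene_id)
})
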