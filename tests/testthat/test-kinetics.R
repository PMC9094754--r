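test_that("peak normalization divides by the course maximum", {
  expect_equal(peakNormalize(c(1, 4, 2)), c(0.25, 1, 0.5))
  expect_equal(peakNormalize(c(3, 3, 3)), c(1, 1, 1))
  expect_error(peakNormalize(c(0, 0, 0)), "all-zero")
  m <- rbind(g1 = c(1, 4, 2), g2 = c(2, 2, 1))
  pk <- peakNormalize(m)
  expect_equal(unname(apply(pk, 1, max)), c(1, 1))
  expect_equal(pk["g1", ], c(0.25, 1, 0.5))
})

test_that("peak normalization is idempotent and scale-invariant", {
  set.seed(3)
  for (i in 1:25) {
    v <- runif(5, 0.01, 10)
    expect_equal(peakNormalize(peakNormalize(v)), peakNormalize(v))
    expect_equal(peakNormalize(v * runif(1, 0.1, 100)), peakNormalize(v))
  }
})

test_that("late ratio divides 9 h by 6 h expression", {
  expect_equal(lateRatio(c(2, 1), timepoints = c(6, 9)), 0.5)
  expect_equal(lateRatio(c(1, 1), timepoints = c(6, 9)), 1)
  expect_error(lateRatio(c(0, 1), timepoints = c(6, 9)), "zero expression")
  expect_error(lateRatio(c(1, 1), timepoints = c(0, 6)), "not present")
  m <- matrix(c(4, 2, 8, 8), 2, 2, dimnames = list(c("a", "b"), c("6", "9")))
  expect_equal(unname(lateRatio(m)), c(2, 4))
})

test_that("persistence classification splits at 0.5 with the boundary sustained", {
  expect_equal(as.character(classifyPersistence(c(0.8, 0.3, 0.5))),
               c("SUSTAINED", "DOWNREGULATED", "SUSTAINED"))
  expect_error(classifyPersistence(1.2), "\\[0, 1\\]")
  expect_error(classifyPersistence(-0.1), "\\[0, 1\\]")
})

test_that("persistence call agrees with direct late thresholding for decaying courses", {
  tt <- c(0, 1, 3, 6, 9)
  set.seed(9)
  for (i in 1:50) {
    k <- runif(1, 0, 0.5)
    peak <- sample(c(1, 3), 1)
    v <- ifelse(tt <= peak, 10 * (tt / peak), 10 * exp(-k * (tt - peak)))
    v[1] <- 0.01
    pk9 <- peakNormalize(v)[5]
    expect_equal(classifyPersistence(pk9) == "SUSTAINED",
                 exp(-k * (9 - peak)) >= 0.5)
  }
})

test_that("percent remaining rescales to 100% at time zero", {
  expect_equal(percentRemaining(c(10, 5), c(1, 1)), c(100, 50))
  expect_equal(percentRemaining(c(3, 6, 9), c(3, 6, 9)), c(100, 100, 100))
  expect_error(percentRemaining(c(1, 1), c(1, 0)), "positive")
  expect_error(percentRemaining(c(1, 1, 1), c(1, 1)), "same timepoints")
})

test_that("z-score signatures are globally centered", {
  m <- matrix(c(0, 2, 0, 2), 2, 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  # hand computation: both genes have identical z-scores, so any subset
  # signature equals the global signature and centering cancels it
  expect_equal(unname(zscoreSignature(m, "g1")), c(0, 0))
  # the all-genes set is identically zero by construction
  set.seed(5)
  big <- matrix(rnorm(200), 20, 10,
                dimnames = list(sprintf("g%02d", 1:20), NULL))
  expect_equal(unname(zscoreSignature(big, rownames(big))), rep(0, 10))
  expect_error(zscoreSignature(big, c("nope1", "nope2")), "intersect")
  flat <- rbind(big, gflat = rep(1, 10))
  expect_warning(zscoreSignature(flat, "g01"), "zero-variance")
})

test_that("replicate averaging collapses samples per timepoint", {
  m <- matrix(c(1, 2, 3, 5,
                10, 10, 20, 40), 2, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2"), NULL))
  tce <- TimeCourseExperiment(m, timepoint = c(0, 0, 6, 6),
                              replicate = c(1, 2, 1, 2))
  avg <- averageReplicates(tce)
  expect_equal(colnames(avg), c("0", "6"))
  expect_equal(avg["g1", ], c(`0` = 1.5, `6` = 4))
  expect_equal(avg["g2", ], c(`0` = 10, `6` = 30))
  expect_equal(timepoints(tce), c(0, 6))
})

test_that("Mann-Whitney comparison matches the full permutation oracle", {
  expect_equal(compareGroups(c(1, 2, 3), c(4, 5, 6))$p.value, 0.1)
  expect_equal(compareGroups(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_error(compareGroups(numeric(0), 1), "non-empty")
  set.seed(13)
  for (i in 1:40) {
    na <- sample(2:7, 1); nb <- sample(2:7, 1)
    vals <- sample(1:100, na + nb)   # distinct values: no ties
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    expect_equal(compareGroups(a, b)$p.value, permutationMannWhitneyP(a, b),
                 info = paste(na, nb))
  }
})
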