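test_that("ratios are computed from raw intensities with NA for absent peaks", {
  cands <- CandidateSet(envelopePeaks(c(1000, 212, NA, NA)))
  fv <- extractFeatures(cands)
  expect_equal(fv$r1, 0.212)
  expect_true(is.na(fv$r2) && is.na(fv$r3))
  expect_true(fv$m1_present)
  expect_false(fv$m2_present || fv$m3_present)
  expect_equal(fv$log_i0, 3)
})

test_that("r1 is the reciprocal of the reported M0/M1 orientation", {
  fv <- extractFeatures(CandidateSet(envelopePeaks(c(470, 100))))
  expect_equal(fv$r1, 100 / 470)         # M0/M1 = 4.7 in table orientation
  expect_equal(1 / fv$r1, 4.7, tolerance = 1e-12)
})

test_that("noiseless simulated envelopes give r1 = a1/a0 exactly", {
  comp <- ElementalComposition(C = 11, H = 12, N = 2, O = 2)
  d <- naturalDistribution(comp)
  cfg <- simConfig(noiseSigma = 0, detectionLimit = 0, nUnlabeledSamples = 2)
  pk <- sampleEnvelopes(d, cfg, "unlabeled")
  fv <- extractFeatures(CandidateSet(pk))
  a <- abundances(d)
  expect_equal(fv$r1, rep(a[2] / a[1], 2), tolerance = 1e-12)
})

test_that("ratio features are invariant to intensity rescaling", {
  pk <- envelopePeaks(c(1200, 260, 40, 15))
  f1 <- extractFeatures(CandidateSet(pk))
  pk$intensity <- pk$intensity * 37.5
  f2 <- extractFeatures(CandidateSet(pk))
  for (col in c("r1", "r2", "r3", "r1_excess"))
    expect_equal(f1[[col]], f2[[col]])
  expect_equal(f2$log_i0 - f1$log_i0, log10(37.5))
})

test_that("zero M0 intensity is rejected", {
  pk <- envelopePeaks(c(1000, 100))
  pk$intensity[1] <- 0
  expect_error(extractFeatures(pk), "M0")
})

test_that("the natural-abundance r1 baseline follows the mass heuristic", {
  expect_equal(expectedNaturalR1(367.09), 16 * 0.0108)
  expect_equal(expectedNaturalR1(367.09 * 2) / expectedNaturalR1(367.09), 2,
               tolerance = 0.05)
  expect_error(expectedNaturalR1(0), "mz")
})

test_that("discretization maps edges to the upper bin and NA to missing", {
  feats <- data.frame(r1 = c(0.05, 0.1, 0.4, NA), r2 = c(NA, 0.2, 0.5, 1),
                      r3 = NA_real_)
  disc <- new("Discretizer", edges = list(r1 = c(0.1, 0.3),
                                          r2 = c(0.5), r3 = numeric()),
              nBins = 3L)
  out <- discretize(feats, disc)
  expect_equal(as.character(out$r1_bin), c("b1", "b2", "b3", "missing"))
  expect_equal(as.character(out$r2_bin), c("missing", "b1", "b2", "b2"))
  expect_true(all(out$r3_bin == "missing"))
  expect_error(discretize(feats, new("Discretizer", edges = list(),
                                     nBins = 5L)), "fitted")
})

test_that("quantile fitting on uniform data yields near-equal bin counts", {
  set.seed(12)
  feats <- data.frame(r1 = runif(4000), r2 = runif(4000), r3 = runif(4000))
  disc <- fitDiscretizer(feats, nBins = 4)
  out <- discretize(feats, disc)
  frac <- table(out$r1_bin) / 4000
  expect_equal(as.numeric(frac[c("b1", "b2", "b3", "b4")]),
               rep(0.25, 4), tolerance = 0.05)
  expect_true(all(diff(binEdges(disc)$r1) > 0))
})

test_that("imputer leaves M1-complete envelopes untouched", {
  bench <- smallBenchmark()
  feats <- extractFeatures(bench$candidates)
  disc <- fitDiscretizer(feats)
  imp <- fitM1Imputer(feats, disc, seed = 3)
  complete <- feats[feats$m1_present, , drop = FALSE]
  out <- imputeM1(complete, imp)
  expect_equal(out$r1, complete$r1)
  expect_equal(out$r1_excess, complete$r1_excess)
})

test_that("imputation is perfect when r1 bin is determined by r2 bin", {
  set.seed(8)
  vals <- sample(c(0.1, 0.5, 1, 2, 4), 400, replace = TRUE)
  feats <- data.frame(
    candidate_id = sprintf("c%03d", seq_len(400)),
    sample_id = "s1", condition = "labeled",
    mz = runif(400, 100, 500), rt = 10,
    r1 = vals, r2 = vals, r3 = runif(400),
    log_i0 = runif(400, 3, 6), r1_excess = 0,
    m1_present = TRUE, m2_present = TRUE, m3_present = TRUE)
  disc <- fitDiscretizer(feats, nBins = 5)
  imp <- fitM1Imputer(feats, disc, seed = 4)
  masked <- feats[1:80, ]
  truthBin <- discretize(masked, disc)$r1_bin
  masked$m1_present <- FALSE
  masked$r1 <- NA_real_
  out <- imputeM1(masked, imp)
  expect_equal(as.character(out$r1_bin), as.character(truthBin))
})

test_that("imputed bins beat the majority-class baseline on simulated data", {
  b <- makeBenchmark(nLabeledCands = 20, nUnlabeledCands = 40, seed = 55)
  feats <- extractFeatures(b$candidates)
  feats <- feats[feats$m1_present & is.finite(feats$r1), ]
  disc <- fitDiscretizer(feats)
  set.seed(9)
  maskIdx <- sample(nrow(feats), round(0.2 * nrow(feats)))
  train <- feats[-maskIdx, ]
  imp <- fitM1Imputer(train, disc, seed = 10)
  test <- feats[maskIdx, ]
  truthBin <- as.character(discretize(test, disc)$r1_bin)
  test$m1_present <- FALSE
  test$r1 <- NA_real_
  predBin <- as.character(imputeM1(test, imp)$r1_bin)
  acc <- mean(predBin == truthBin)
  majority <- max(table(as.character(discretize(train, disc)$r1_bin))) /
    nrow(train)
  expect_gt(acc, majority)
})

test_that("too few complete envelopes is an error", {
  feats <- extractFeatures(CandidateSet(envelopePeaks(c(1000, 100, 20))))
  disc <- new("Discretizer", edges = list(r1 = 0.1, r2 = 0.2, r3 = 0.3),
              nBins = 2L)
  expect_error(fitM1Imputer(feats, disc), "at least 50")
})
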