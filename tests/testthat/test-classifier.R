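# synthetic raw feature table with a controllable class difference
syntheticFeatures <- function(n, r1Mean, seed, prefix) {
  withr::with_seed(seed, data.frame(
    candidate_id = sprintf("%s%04d", prefix, seq_len(n)),
    sample_id = "s1", condition = "labeled",
    mz = runif(n, 100, 500), rt = 10,
    r1 = pmax(0.01, rnorm(n, r1Mean, 0.02)),
    r2 = runif(n, 0.1, 0.6), r3 = runif(n, 0.1, 0.6),
    log_i0 = runif(n, 3, 6), r1_excess = 0,
    m1_present = TRUE, m2_present = TRUE, m3_present = TRUE,
    stringsAsFactors = FALSE))
}

separableTrainingSet <- function(seed = 1, prefix = "s") {
  pos <- syntheticFeatures(120, 1.0, seed, paste0(prefix, "p"))
  neg <- syntheticFeatures(120, 0.1, seed + 1, paste0(prefix, "n"))
  feats <- rbind(pos, neg)
  feats$r1_excess <- feats$r1 - expectedNaturalR1(feats$mz)
  TrainingSet(feats, rep(c(1L, 0L), each = 120), feats$candidate_id)
}

test_that("perfectly separable features train to AUC 1", {
  ts <- separableTrainingSet()
  model <- trainClassifier(ts, modelConfig())
  probs <- predictProba(model, ts@features)
  expect_true(all(probs[ts@labels == 1L] > 0.5))
  expect_true(all(probs[ts@labels == 0L] < 0.5))
})

test_that("training is deterministic under a fixed seed", {
  bench <- smallBenchmark()
  ts <- buildTrainingSet(bench$candidates, bench$truth)
  cfg <- modelConfig(seed = 77)
  m1 <- trainClassifier(ts, cfg)
  m2 <- trainClassifier(ts, cfg)
  expect_identical(predictProba(m1, ts@features),
                   predictProba(m2, ts@features))
})

test_that("single-class training input is an error", {
  ts <- separableTrainingSet()
  tsOne <- TrainingSet(ts@features[ts@labels == 1L, ],
                       ts@labels[ts@labels == 1L],
                       ts@groups[ts@labels == 1L])
  expect_error(trainClassifier(tsOne), "single class")
})

test_that("prediction handles empty input, bad schema and row order", {
  model <- trainedModel()
  feats <- extractFeatures(smallBenchmark()$candidates)
  expect_identical(predictProba(model, feats[0, ]), numeric(0))
  expect_error(predictProba(model, feats[, setdiff(names(feats), "r2")]),
               "r2")
  p <- predictProba(model, feats)
  expect_true(all(p >= 0 & p <= 1))
  set.seed(2)
  perm <- sample(nrow(feats))
  expect_equal(predictProba(model, feats[perm, ]), p[perm])
})

test_that("an envelope resembling labeled training data scores above 0.5", {
  model <- trainedModel()
  bench <- smallBenchmark()
  feats <- extractFeatures(bench$candidates)
  lab <- bench$truth$candidate_id[bench$truth$is_labeled]
  sel <- feats$candidate_id %in% lab & feats$condition == "labeled"
  p <- predictProba(model, feats)
  expect_gt(mean(p[sel] > 0.5), 0.8)
})

test_that("label permutation drives grouped-CV AUC to chance", {
  bench <- makeBenchmark(nLabeledCands = 25, nUnlabeledCands = 55, seed = 61,
                         idPrefix = "perm")
  ts <- buildTrainingSet(bench$candidates, bench$truth)
  auc <- withr::with_seed(123, {
    tsNull <- TrainingSet(ts@features, sample(ts@labels), ts@groups)
    crossValidate(tsNull, modelConfig(seed = 5))
  })
  expect_gt(auc, 0.35)
  expect_lt(auc, 0.65)
})

test_that("transfer evaluation enforces provenance and reports both AUCs", {
  tsA <- separableTrainingSet(seed = 11, prefix = "A")
  tsB <- separableTrainingSet(seed = 31, prefix = "B")
  res <- transferEvaluate(tsA, tsB, modelConfig())
  expect_gt(res$roc_auc, 0.99)
  expect_gt(res$pr_auc, 0.99)

  ## identical sets: allowed self-test with a warning
  expect_warning(transferEvaluate(tsA, tsA, modelConfig()), "overfit")

  ## partial overlap: leakage error
  half <- unique(tsB@groups)[1:60]
  keep <- tsB@groups %in% half | tsA@groups %in% tsA@groups
  tsMix <- TrainingSet(rbind(tsA@features, tsB@features[tsB@groups %in% half, ]),
                       c(tsA@labels, tsB@labels[tsB@groups %in% half]),
                       c(tsA@groups, tsB@groups[tsB@groups %in% half]))
  expect_error(transferEvaluate(tsA, tsMix, modelConfig()), "leakage")

  ## degenerate single-class test set
  tsOne <- TrainingSet(tsB@features[tsB@labels == 1L, ],
                       tsB@labels[tsB@labels == 1L],
                       tsB@groups[tsB@labels == 1L])
  expect_error(transferEvaluate(tsA, tsOne, modelConfig()), "single class")
})

test_that("transfer AUC degrades as test-regime labeling fades", {
  trainBench <- makeBenchmark(nLabeledCands = 30, nUnlabeledCands = 60,
                              seed = 71, compositions = metaboliteLibrary("A"),
                              idPrefix = "tr")
  tsTrain <- buildTrainingSet(trainBench$candidates, trainBench$truth)
  aucs <- vapply(c(0.5, 0.05), function(f) {
    tb <- makeBenchmark(cfgHuman = simConfig(rho = 0.15, mixFraction = f),
                        nLabeledCands = 30, nUnlabeledCands = 60,
                        seed = 72, regime = "human",
                        compositions = metaboliteLibrary("B"),
                        idPrefix = sprintf("te%02.0f", 100 * f))
    transferEvaluate(tsTrain, buildTrainingSet(tb$candidates, tb$truth),
                     modelConfig())$roc_auc
  }, numeric(1))
  expect_gt(aucs[1], aucs[2])
})
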