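test_that("ratio summaries use the printed Mn/Mn+1 orientation", {
  pk <- rbind(envelopePeaks(c(470, 100), sample = "s1", condition = "unlabeled"),
              envelopePeaks(c(470, 100), sample = "s2", condition = "labeled"))
  rs <- ratioSummary(CandidateSet(pk))
  row <- rs[rs$condition == "unlabeled" & rs$ratio == "M0/M1", ]
  expect_equal(row$mean, 4.7)
  expect_equal(row$n, 1L)
  expect_true(is.na(row$sd))
})

test_that("means and SDs aggregate across envelopes; absences stay undefined", {
  pk <- rbind(
    envelopePeaks(c(400, 100), sample = "s1", condition = "unlabeled"),
    envelopePeaks(c(600, 100), sample = "s2", condition = "unlabeled"),
    envelopePeaks(c(500, 400, 200), sample = "s3", condition = "labeled"))
  rs <- ratioSummary(CandidateSet(pk))
  u01 <- rs[rs$condition == "unlabeled" & rs$ratio == "M0/M1", ]
  expect_equal(u01$mean, 5)
  expect_equal(u01$sd, sqrt(2))
  ## M1/M2 never defined in unlabeled envelopes: undefined, not zero
  u12 <- rs[rs$condition == "unlabeled" & rs$ratio == "M1/M2", ]
  expect_equal(u12$n, 0L)
  expect_true(is.na(u12$mean))
  l12 <- rs[rs$condition == "labeled" & rs$ratio == "M1/M2", ]
  expect_equal(l12$mean, 2)
})

test_that("ratio summaries are intensity-scale invariant", {
  bench <- smallBenchmark()
  one <- bench$candidates[candidateIds(bench$candidates)[1]]
  rs1 <- ratioSummary(one)
  pk <- peaks(one)
  pk$intensity <- pk$intensity * 1e3
  rs2 <- ratioSummary(CandidateSet(pk, candidateInfo(one)))
  expect_equal(rs1$mean, rs2$mean)
  expect_equal(rs1$sd, rs2$sd)
})

test_that("labeling depresses M0/M1 in the labeled condition of true labels", {
  bench <- smallBenchmark()
  rs <- ratioSummary(bench$candidates)
  lab <- bench$truth$candidate_id[bench$truth$is_labeled]
  m0m1 <- rs[rs$ratio == "M0/M1" & rs$candidate_id %in% lab, ]
  u <- m0m1$mean[m0m1$condition == "unlabeled"]
  l <- m0m1$mean[m0m1$condition == "labeled"]
  expect_true(all(u > l, na.rm = TRUE))
})

test_that("truly labeled candidates have at least as many defined heavier ratios", {
  bench <- smallBenchmark()
  rs <- ratioSummary(bench$candidates)
  lab <- bench$truth$candidate_id[bench$truth$is_labeled]
  heavier <- rs[rs$ratio != "M0/M1" & rs$candidate_id %in% lab, ]
  for (id in lab) {
    nl <- sum(heavier$n[heavier$candidate_id == id &
                          heavier$condition == "labeled"] > 0)
    nu <- sum(heavier$n[heavier$candidate_id == id &
                          heavier$condition == "unlabeled"] > 0)
    expect_gte(nl, nu)
  }
})

test_that("the published exemplar ratio pair is label-confirmed", {
  summary <- data.frame(
    candidate_id = "urine_426",
    condition = rep(c("unlabeled", "labeled"), each = 2),
    ratio = rep(c("M0/M1", "M1/M2"), 2),
    mean = c(4.71, 3.7, 1.27, 1.68),
    sd = c(0.61, 1.7, 0.16, 0.1),
    n = c(8L, 8L, 8L, 8L), stringsAsFactors = FALSE)
  call <- callLabel(summary)
  expect_equal(call$decision, "label-confirmed")
  expect_equal(call$fold_m0m1, 4.71 / 1.27)

  ## the M0/M1 pair alone is already decisive (shift of ~7.7 pooled SDs)
  call2 <- callLabel(summary[summary$ratio == "M0/M1", ])
  expect_equal(call2$decision, "label-confirmed")
})

test_that("identical conditions are not confirmed; low n is insufficient", {
  same <- data.frame(candidate_id = "c", condition = c("unlabeled", "labeled"),
                     ratio = "M0/M1", mean = c(4.5, 4.5), sd = c(0.5, 0.5),
                     n = c(8L, 8L), stringsAsFactors = FALSE)
  expect_equal(callLabel(same)$decision, "not-confirmed")

  lowN <- same
  lowN$n <- c(8L, 1L)
  expect_equal(callLabel(lowN)$decision, "insufficient-data")
})

test_that("label calls recover simulator ground truth accurately", {
  hb <- makeBenchmark(nLabeledCands = 20, nUnlabeledCands = 40, seed = 91,
                      regime = "human", idPrefix = "v")
  calls <- callLabels(hb$candidates)
  isLab <- hb$truth$is_labeled[match(calls$candidate_id,
                                     hb$truth$candidate_id)]
  conf <- calls$decision == "label-confirmed"
  expect_gte(mean(conf[isLab]), 0.9)     # sensitivity
  expect_gte(mean(!conf[!isLab]), 0.9)   # specificity
})
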