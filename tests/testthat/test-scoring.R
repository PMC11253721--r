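test_that("p_L and p_U are unweighted per-condition means", {
  agg <- aggregateProbs(c("labeled", "labeled", "unlabeled", "unlabeled"),
                        c(0.9, 0.7, 0.1, 0.1))
  expect_equal(unname(agg), c(0.8, 0.1))

  allEq <- aggregateProbs(c("labeled", "unlabeled", "labeled"),
                          rep(0.42, 3))
  expect_equal(unname(allEq), c(0.42, 0.42))

  cond <- c("labeled", "labeled", "unlabeled", "unlabeled", "unlabeled")
  pr <- c(0.9, 0.5, 0.2, 0.1, 0.3)
  perm <- c(4, 2, 5, 1, 3)
  expect_equal(aggregateProbs(cond, pr), aggregateProbs(cond[perm], pr[perm]))

  expect_error(aggregateProbs(c("labeled", "labeled"), c(0.5, 0.5)),
               "both conditions")
})

test_that("the candidate score follows p_L/(p_U + c)", {
  expect_equal(candidateScore(0.8, 0.1), 0.8 / 0.11)
  expect_equal(candidateScore(0, 0.9), 0)
  expect_equal(candidateScore(0.5, 0.5), 0.5 / 0.51)
  expect_lt(candidateScore(0.5, 0.5), 1)   # no contrast is down-weighted
  expect_error(candidateScore(0.8, 0.1, c = 0), "c must be")
  expect_error(candidateScore(1.2, 0.1), "0, 1")
})

test_that("the score is monotone in p_L, anti-monotone in p_U, capped at 1/c", {
  pGrid <- seq(0, 1, by = 0.05)
  sUp <- candidateScore(pGrid, 0.3)
  expect_true(all(diff(sUp) > 0))
  sDown <- candidateScore(0.7, pGrid)
  expect_true(all(diff(sDown) < 0))
  expect_equal(candidateScore(1, 0), 100)
  expect_true(all(candidateScore(pGrid, pGrid) <= 100))
})

test_that("ranking is descending with stable id tie-breaks", {
  sc <- data.frame(candidate_id = c("z", "a", "m"), score = c(2, 9, 9))
  r <- rankCandidates(sc)
  expect_equal(r$candidate_id, c("a", "m", "z"))
  expect_equal(r$rank, 1:3)
  expect_equal(rankCandidates(sc[c(3, 1, 2), ]), r)
  one <- rankCandidates(data.frame(candidate_id = "x", score = 5))
  expect_equal(one$rank, 1L)
})

test_that("precision-at-k comparison covers the three strategies", {
  sc <- data.frame(candidate_id = sprintf("c%02d", 1:10),
                   score = 10:1)
  truthAll <- data.frame(candidate_id = sc$candidate_id, is_labeled = TRUE)
  cmp <- compareRankings(sc, truthAll, k = 5,
                         upstreamPvalues = setNames(runif(10), sc$candidate_id))
  expect_equal(cmp$precision_at_k, rep(1, 3))

  truth <- truthAll
  truth$is_labeled <- c(rep(TRUE, 3), rep(FALSE, 7))
  expect_error(compareRankings(sc, truth, k = 0), "k must be")
  expect_error(compareRankings(sc, truth, k = 11), "k must be")
})

test_that("model ranking beats random on a human-like benchmark", {
  model <- trainedModel()
  hb <- makeBenchmark(nLabeledCands = 25, nUnlabeledCands = 75, seed = 88,
                      regime = "human", compositions = metaboliteLibrary("B"),
                      idPrefix = "hb")
  sc <- scoreCandidates(model, hb$candidates)
  info <- candidateInfo(hb$candidates)
  cmp <- compareRankings(sc, hb$truth, k = 20,
                         upstreamPvalues = setNames(info$upstream_pvalue,
                                                    info$candidate_id),
                         seed = 4)
  prec <- setNames(cmp$precision_at_k, cmp$strategy)
  expect_gte(prec["model-score"], prec["random"])
})

test_that("truly labeled candidates rank above unlabeled ones end to end", {
  model <- trainedModel()
  bench <- smallBenchmark()
  sc <- scoreCandidates(model, bench$candidates)
  isLab <- bench$truth$is_labeled[match(sc$candidate_id,
                                        bench$truth$candidate_id)]
  wt <- wilcox.test(sc$rank[isLab], sc$rank[!isLab],
                    alternative = "less", exact = FALSE)
  expect_lt(wt$p.value, 0.01)
})
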