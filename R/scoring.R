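#' Aggregate per-envelope probabilities into p_L and p_U
#'
#' Unweighted arithmetic means of the predicted probability of label over
#' the envelopes from labeled-condition samples (p_L) and over those from
#' unlabeled-condition samples (p_U). Both conditions must be represented.
#'
#' @param condition Character vector (`"labeled"`/`"unlabeled"`), one per
#'   envelope.
#' @param probs Numeric probabilities, one per envelope.
#' @return Named numeric vector `c(p_L = , p_U = )`.
#' @examples
#' aggregateProbs(c("labeled", "labeled", "unlabeled", "unlabeled"),
#'                c(0.9, 0.7, 0.1, 0.1))
#' @export
aggregateProbs <- function(condition, probs) {
  stopifnot(length(condition) == length(probs))
  nL <- sum(condition == "labeled")
  nU <- sum(condition == "unlabeled")
  if (nL == 0L || nU == 0L)
    stop("both conditions must have at least one envelope")
  c(p_L = mean(probs[condition == "labeled"]),
    p_U = mean(probs[condition == "unlabeled"]))
}

#' Candidate labeling score p_L / (p_U + c)
#'
#' p_U acts as a reference point normalizing p_L: a candidate scores high
#' only when its labeled-condition envelopes look labeled while its
#' unlabeled-condition envelopes do not, ruling out detections that score
#' uniformly high in both conditions. The constant `c` (default 0.01)
#' ensures numerical stability, bounding the score by 1/c = 100.
#'
#' @param pL,pU Probabilities in [0, 1] (vectorized).
#' @param c Stability constant, > 0.
#' @return `pL / (pU + c)`.
#' @examples
#' candidateScore(0.8, 0.1)    # ~ 7.273
#' candidateScore(0.5, 0.5)    # < 1: no contrast between conditions
#' @export
candidateScore <- function(pL, pU, c = 0.01) {
  if (c <= 0) stop("c must be > 0")
  if (any(pL < 0 | pL > 1 | pU < 0 | pU > 1, na.rm = TRUE))
    stop("pL and pU must be in [0, 1]")
  pL / (pU + c)
}

#' Rank a score table
#'
#' Orders descending by score with ties broken by candidate id, and assigns
#' ranks 1..N; ranking is invariant to the input row order.
#'
#' @param scores data.frame with at least `candidate_id` and `score`.
#' @return The reordered data.frame with a `rank` column.
#' @export
rankCandidates <- function(scores) {
  ord <- order(-scores$score, scores$candidate_id)
  scores <- scores[ord, , drop = FALSE]
  scores$rank <- seq_len(nrow(scores))
  rownames(scores) <- NULL
  scores
}

#' Score candidates with a fitted classifier
#'
#' Applies the classifier to every envelope, aggregates probabilities per
#' candidate into p_L and p_U, computes the score p_L/(p_U + c) and ranks.
#'
#' @param model A [LabelClassifier-class].
#' @param cands A [CandidateSet-class] whose candidates all have envelopes
#'   in both conditions (run [applyFilters()] first).
#' @param c Stability constant.
#' @return Ranked data.frame: `candidate_id`, `p_L`, `p_U`, `score`,
#'   `rank`, `n_labeled_envelopes`, `n_unlabeled_envelopes`.
#' @export
scoreCandidates <- function(model, cands, c = 0.01) {
  stopifnot(is(cands, "CandidateSet"))
  feats <- extractFeatures(cands)
  probs <- predictProba(model, feats)
  ids <- unique(feats$candidate_id)
  agg <- t(vapply(ids, function(id) {
    sel <- feats$candidate_id == id
    a <- aggregateProbs(feats$condition[sel], probs[sel])
    c(a, n_L = sum(sel & feats$condition == "labeled"),
      n_U = sum(sel & feats$condition == "unlabeled"))
  }, numeric(4)))
  out <- data.frame(
    candidate_id = ids,
    p_L = agg[, "p_L"], p_U = agg[, "p_U"],
    score = candidateScore(agg[, "p_L"], agg[, "p_U"], c),
    n_labeled_envelopes = as.integer(agg[, "n_L"]),
    n_unlabeled_envelopes = as.integer(agg[, "n_U"]),
    stringsAsFactors = FALSE)
  rankCandidates(out)
}

#' Compare candidate ranking strategies by precision at k
#'
#' Blinded-test analog comparing three ways of choosing candidates to
#' inspect: (1) the classifier-informed score ranking, (2) ascending
#' upstream p-values (candidates without a p-value sort last), and
#' (3) random selection, averaged over `reseeds` random orders.
#'
#' @param scores Ranked score data.frame from [scoreCandidates()].
#' @param truth data.frame with `candidate_id` and logical `is_labeled`.
#' @param k Depth of the inspection list (1 <= k <= number of candidates).
#' @param upstreamPvalues Named numeric vector (names = candidate ids) or
#'   `NULL` to skip the p-value strategy.
#' @param reseeds Number of random orderings averaged.
#' @param seed Seed for the random strategy.
#' @return data.frame: `strategy`, `precision_at_k`, `sd` (random strategy
#'   only).
#' @export
compareRankings <- function(scores, truth, k, upstreamPvalues = NULL,
                            reseeds = 20, seed = 1) {
  n <- nrow(scores)
  if (k < 1 || k > n) stop(sprintf("k must be in 1..%d", n))
  isLab <- truth$is_labeled[match(scores$candidate_id, truth$candidate_id)]
  if (anyNA(isLab)) stop("truth does not cover all scored candidates")
  names(isLab) <- scores$candidate_id

  precAt <- function(ids) mean(isLab[ids[seq_len(k)]])
  modelPrec <- precAt(rankCandidates(scores)$candidate_id)

  out <- data.frame(strategy = "model-score", precision_at_k = modelPrec,
                    sd = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(upstreamPvalues)) {
    pv <- upstreamPvalues[scores$candidate_id]
    ord <- order(pv, scores$candidate_id, na.last = TRUE)
    out <- rbind(out, data.frame(
      strategy = "upstream-pvalue",
      precision_at_k = precAt(scores$candidate_id[ord]),
      sd = NA_real_, stringsAsFactors = FALSE))
  }
  rnd <- withSeed(seed, vapply(seq_len(reseeds), function(i)
    precAt(sample(scores$candidate_id)), numeric(1)))
  rbind(out, data.frame(strategy = "random",
                        precision_at_k = mean(rnd),
                        sd = stats::sd(rnd), stringsAsFactors = FALSE))
}
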