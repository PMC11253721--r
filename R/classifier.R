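.PREDICTORS <- c("r1", "r1_excess", "log_i0", "mz", "r2_bin", "r3_bin",
                 "m1_present", "m2_present", "m3_present")
.RAW_FEATURES <- c("r1", "r2", "r3", "log_i0", "mz", "r1_excess",
                   "m1_present", "m2_present", "m3_present")

#' Build an envelope-level training set from candidates and ground truth
#'
#' Envelope labels are 1 for envelopes drawn from the labeled condition of a
#' truly labeled candidate and 0 otherwise (unlabeled-condition envelopes of
#' labeled candidates carry the natural pattern, so they are negatives).
#' Groups are candidate ids, used for grouped cross-validation so that
#' envelopes of one candidate never straddle folds.
#'
#' @param cands A [CandidateSet-class].
#' @param truth data.frame with `candidate_id` and logical `is_labeled`.
#' @return A [TrainingSet-class].
#' @export
buildTrainingSet <- function(cands, truth) {
  feats <- extractFeatures(cands)
  isLab <- truth$is_labeled[match(feats$candidate_id, truth$candidate_id)]
  if (anyNA(isLab)) stop("truth does not cover all candidates")
  labels <- as.integer(isLab & feats$condition == "labeled")
  TrainingSet(feats, labels, feats$candidate_id)
}

## preprocessing shared by train and predict: discretize + impute missing M1
.prepareFeatures <- function(features, discretizer, imputer) {
  if (!is.null(imputer)) {
    out <- imputeM1(features, imputer)
  } else {
    out <- discretize(features, discretizer)
    miss <- !out$m1_present | !is.finite(out$r1)
    if (any(miss)) {
      med <- stats::median(out$r1[is.finite(out$r1)])
      out$r1[miss] <- med
      out$r1_bin[miss] <- .binAssign(med, discretizer@edges[["r1"]],
                                     discretizer@nBins)
      out$r1_excess[miss] <- out$r1[miss] - expectedNaturalR1(out$mz[miss])
    }
  }
  out
}

.fitForest <- function(df, labels, cfg) {
  df$.label <- factor(labels, levels = c(0L, 1L))
  ranger::ranger(.label ~ ., data = df, num.trees = cfg@nTrees,
                 max.depth = cfg@maxDepth, min.node.size = cfg@minInstances,
                 probability = TRUE, seed = cfg@seed, num.threads = 1,
                 respect.unordered.factors = "order")
}

#' Train the random-forest envelope classifier
#'
#' Fits the published classifier configuration (100 trees, maximum depth 5,
#' minimum 10 instances per leaf) on discretized, M1-imputed envelope
#' features. The discretizer and imputer fitted on the training data are
#' stored inside the returned model so prediction applies identical edges.
#' Optionally reports grouped cross-validated ROC AUC (folds grouped by
#' candidate id, stratified by candidate-level class). Deterministic under
#' the config seed.
#'
#' @param ts A [TrainingSet-class] with both classes present.
#' @param cfg A [ModelConfig-class].
#' @param cv Logical; also run grouped cross-validation (slower).
#' @return A [LabelClassifier-class].
#' @export
trainClassifier <- function(ts, cfg = modelConfig(), cv = FALSE) {
  stopifnot(is(ts, "TrainingSet"))
  validObject(cfg)
  if (length(unique(ts@labels)) < 2L)
    stop("training set contains a single class")
  disc <- fitDiscretizer(ts@features)
  imputer <- tryCatch(
    fitM1Imputer(ts@features, disc, nTrees = cfg@nTrees, seed = cfg@seed),
    error = function(e) NULL)
  prep <- .prepareFeatures(ts@features, disc, imputer)
  X <- prep[, .PREDICTORS]
  forest <- .fitForest(X, ts@labels, cfg)
  cvMetrics <- numeric(0)
  if (cv) cvMetrics <- c(cv_roc_auc = crossValidate(ts, cfg))
  new("LabelClassifier", forest = forest, discretizer = disc,
      imputer = imputer, featureNames = .PREDICTORS, config = cfg,
      cvMetrics = cvMetrics)
}

#' Predict per-envelope probability of being labeled
#'
#' @param model A [LabelClassifier-class].
#' @param features Raw feature data.frame from [extractFeatures()] (or a
#'   [CandidateSet-class], which is featurized first). A missing feature
#'   column is an error naming the column.
#' @return Numeric vector of probabilities in [0, 1], one per envelope, in
#'   row order.
#' @export
predictProba <- function(model, features) {
  stopifnot(is(model, "LabelClassifier"))
  if (is(features, "CandidateSet")) features <- extractFeatures(features)
  missing <- setdiff(.RAW_FEATURES, names(features))
  if (length(missing))
    stop(sprintf("feature schema mismatch; missing: %s",
                 paste(missing, collapse = ", ")))
  if (!nrow(features)) return(numeric(0))
  prep <- .prepareFeatures(features, model@discretizer, model@imputer)
  pr <- stats::predict(model@forest, data = prep[, model@featureNames],
                       num.threads = 1)$predictions
  as.numeric(pr[, "1"])
}

## ROC AUC via pROC (independent of the forest implementation)
.rocAUC <- function(labels, scores) {
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c("0", "1"), direction = "<",
                                 quiet = TRUE)))
}

## area under the precision-recall curve (average precision, step integral)
.prAUC <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  nPos <- sum(y == 1L)
  if (nPos == 0L) return(NA_real_)
  tp <- cumsum(y == 1L)
  prec <- tp / seq_along(y)
  sum(prec[y == 1L]) / nPos
}

## deterministic grouped folds, stratified by candidate-level class
.groupedFolds <- function(groups, labels, k) {
  g <- unique(groups)
  gLab <- vapply(g, function(x) max(labels[groups == x]), integer(1))
  g <- g[order(gLab, g)]
  fold <- rep_len(seq_len(k), length(g))
  names(fold) <- g
  fold[groups]
}

#' Grouped cross-validated ROC AUC
#'
#' Folds are grouped by candidate id (all envelopes of a candidate stay in
#' one fold) and approximately stratified by candidate-level class. The
#' discretizer and imputer are refitted inside each training fold so no
#' information leaks from held-out envelopes.
#'
#' @param ts A [TrainingSet-class].
#' @param cfg A [ModelConfig-class] (`cvFolds` controls the fold count).
#' @return The pooled out-of-fold ROC AUC (single number).
#' @export
crossValidate <- function(ts, cfg = modelConfig()) {
  stopifnot(is(ts, "TrainingSet"))
  folds <- .groupedFolds(ts@groups, ts@labels, cfg@cvFolds)
  oof <- rep(NA_real_, length(ts@labels))
  for (f in seq_len(cfg@cvFolds)) {
    tr <- folds != f
    if (length(unique(ts@labels[tr])) < 2L) next
    disc <- fitDiscretizer(ts@features[tr, , drop = FALSE])
    imp <- tryCatch(
      fitM1Imputer(ts@features[tr, , drop = FALSE], disc,
                   nTrees = cfg@nTrees, seed = cfg@seed),
      error = function(e) NULL)
    Xtr <- .prepareFeatures(ts@features[tr, , drop = FALSE], disc, imp)
    forest <- .fitForest(Xtr[, .PREDICTORS], ts@labels[tr], cfg)
    Xte <- .prepareFeatures(ts@features[!tr, , drop = FALSE], disc, imp)
    pr <- stats::predict(forest, data = Xte[, .PREDICTORS],
                         num.threads = 1)$predictions
    oof[!tr] <- as.numeric(pr[, "1"])
  }
  ok <- !is.na(oof)
  .rocAUC(factor(ts@labels[ok], levels = c(0L, 1L)), oof[ok])
}

#' Transfer evaluation: train on one regime, test on another
#'
#' Reproduces the train-on-one-plant, test-on-the-other protocol used to
#' establish classifier transferability. The two sets must have disjoint
#' candidate ids (partial overlap is a leakage error); passing the identical
#' set is allowed as a self-test upper bound and triggers a warning.
#'
#' @param tsTrain,tsTest [TrainingSet-class] objects with disjoint
#'   provenance.
#' @param cfg A [ModelConfig-class].
#' @return Named list with `roc_auc` and `pr_auc`, computed on the held-out
#'   test set only.
#' @export
transferEvaluate <- function(tsTrain, tsTest, cfg = modelConfig()) {
  trainIds <- unique(tsTrain@groups)
  testIds <- unique(tsTest@groups)
  if (setequal(trainIds, testIds)) {
    warning("test set equals training set; metrics are an overfit upper bound")
  } else if (length(intersect(trainIds, testIds))) {
    stop("leakage: candidate ids overlap between train and test sets")
  }
  if (length(unique(tsTest@labels)) < 2L)
    stop("test set contains a single class")
  model <- trainClassifier(tsTrain, cfg, cv = FALSE)
  probs <- predictProba(model, tsTest@features)
  y <- factor(tsTest@labels, levels = c(0L, 1L))
  list(roc_auc = .rocAUC(y, probs), pr_auc = .prAUC(tsTest@labels, probs))
}
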