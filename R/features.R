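#' Expected natural-abundance M1/M0 ratio at a given m/z
#'
#' A formula-free baseline for the natural 13C contribution to M1: the
#' carbon count is estimated from the mass as `round(mz * 0.043)` (small
#' metabolites average roughly 0.043 carbons per Da) and each carbon
#' contributes the 13C/12C abundance ratio (~0.0108) to M1/M0. Used to
#' express the observed M1/M0 ratio as an excess over the natural-abundance
#' expectation.
#'
#' @param mz Measured m/z (Da), > 0.
#' @return Expected I(M1)/I(M0) ratio under natural abundance.
#' @examples
#' expectedNaturalR1(367.09)   # ~ 16 carbons -> ~ 0.173
#' @export
expectedNaturalR1 <- function(mz) {
  if (any(mz <= 0)) stop("mz must be > 0")
  round(mz * 0.043) * 0.0108
}

#' Extract per-envelope isotopologue features
#'
#' Step 2's input engineering. Each envelope (one candidate in one sample)
#' is described by consecutive intensity ratios r1 = I(M1)/I(M0),
#' r2 = I(M2)/I(M1), r3 = I(M3)/I(M2), the log10 M0 intensity, the M0 m/z,
#' the excess of r1 over the natural-abundance expectation, and
#' presence flags for M1..M3. Ratios are computed from raw intensities
#' without natural-isotope-abundance correction; absent peaks yield `NA`
#' markers (never zeros), to be handled downstream by discretization with a
#' "missing" category and by M1 imputation. Note the ratio orientation:
#' features store Mn+1/Mn while validation tables print the reciprocal
#' Mn/Mn+1.
#'
#' @param x A [CandidateSet-class] (or its long-format peak data.frame).
#' @return data.frame with one row per envelope: `candidate_id`,
#'   `sample_id`, `condition`, `mz`, `rt`, `r1`, `r2`, `r3`, `log_i0`,
#'   `r1_excess`, `m1_present`, `m2_present`, `m3_present`.
#' @export
extractFeatures <- function(x) {
  pk <- if (is(x, "CandidateSet")) peaks(x) else as.data.frame(x)
  if (!nrow(pk))
    return(data.frame(candidate_id = character(), sample_id = character(),
                      condition = character(), mz = numeric(), rt = numeric(),
                      r1 = numeric(), r2 = numeric(), r3 = numeric(),
                      log_i0 = numeric(), r1_excess = numeric(),
                      m1_present = logical(), m2_present = logical(),
                      m3_present = logical(), stringsAsFactors = FALSE))
  key <- paste(pk$candidate_id, pk$sample_id, sep = "\r")
  env <- !duplicated(key)
  envKeys <- key[env]
  nEnv <- length(envKeys)
  row <- match(key, envKeys)
  K <- max(4L, max(pk$iso_index)) + 1L
  I <- matrix(NA_real_, nEnv, K)
  I[cbind(row, pk$iso_index + 1L)] <- pk$intensity
  mz0 <- rep(NA_real_, nEnv)
  m0row <- pk$iso_index == 0L
  mz0[row[m0row]] <- pk$mz[m0row]
  if (anyNA(mz0))
    stop("envelope(s) without an M0 peak; run QC (readCandidates) first")
  if (any(I[, 1L] == 0, na.rm = TRUE))
    stop("zero M0 intensity violates the envelope invariant")
  rtEnv <- as.numeric(tapply(pk$rt, factor(key, levels = envKeys),
                             stats::median))
  r1 <- I[, 2L] / I[, 1L]
  r2 <- I[, 3L] / I[, 2L]
  r3 <- I[, 4L] / I[, 3L]
  data.frame(
    candidate_id = pk$candidate_id[env],
    sample_id = pk$sample_id[env],
    condition = pk$condition[env],
    mz = mz0, rt = rtEnv,
    r1 = r1, r2 = r2, r3 = r3,
    log_i0 = log10(I[, 1L]),
    r1_excess = r1 - expectedNaturalR1(mz0),
    m1_present = !is.na(I[, 2L]),
    m2_present = !is.na(I[, 3L]),
    m3_present = !is.na(I[, 4L]),
    stringsAsFactors = FALSE)
}

.RATIO_FEATURES <- c("r1", "r2", "r3")
.BIN_LEVELS <- function(nBins) c(paste0("b", seq_len(nBins)), "missing")

#' Fit a quantile discretizer for the ratio features
#'
#' Bin edges are the interior quantiles of the observed (non-missing)
#' training values of each ratio feature, giving approximately equal-count
#' bins; duplicate quantiles are collapsed so edges stay strictly
#' increasing. The fitted edges travel with the classifier so train- and
#' predict-time discretization are identical.
#'
#' @param features data.frame from [extractFeatures()].
#' @param nBins Number of bins (default 5) before the extra `"missing"`
#'   category.
#' @return A fitted [Discretizer-class].
#' @export
fitDiscretizer <- function(features, nBins = 5) {
  edges <- lapply(.RATIO_FEATURES, function(f) {
    v <- features[[f]]
    v <- v[is.finite(v)]
    if (!length(v)) return(numeric())
    e <- unique(as.numeric(stats::quantile(v, probs = seq_len(nBins - 1) / nBins,
                                           names = FALSE, type = 7)))
    e[diff(c(-Inf, e)) > 0]
  })
  names(edges) <- .RATIO_FEATURES
  new("Discretizer", edges = edges, nBins = as.integer(nBins))
}

## assign values to bins; a value equal to an edge goes to the right-closed
## upper bin; NA -> "missing"
.binAssign <- function(x, edges, nBins) {
  lev <- .BIN_LEVELS(nBins)
  idx <- findInterval(x, edges) + 1L
  out <- lev[idx]
  out[is.na(x)] <- "missing"
  factor(out, levels = lev)
}

#' Discretize ratio features with an explicit "missing" category
#'
#' Adds `r1_bin`, `r2_bin`, `r3_bin` factor columns. Every finite ratio maps
#' to exactly one bin; `NA` ratios map to `"missing"`.
#'
#' @param features data.frame from [extractFeatures()].
#' @param discretizer A fitted [Discretizer-class].
#' @return `features` with the three bin columns appended.
#' @export
discretize <- function(features, discretizer) {
  stopifnot(is(discretizer, "Discretizer"))
  if (!isFitted(discretizer)) stop("discretizer has not been fitted")
  for (f in .RATIO_FEATURES)
    features[[paste0(f, "_bin")]] <-
      .binAssign(features[[f]], discretizer@edges[[f]], discretizer@nBins)
  features
}

#' Fit the M1-feature imputer
#'
#' The M1 peak is the most informative and most reliably observed
#' isotopologue peak, but it is occasionally censored. Features tied to a
#' missing M1 are imputed with a random-forest *classifier* (not a
#' regressor) trained on complete envelopes: it predicts the discretized r1
#' bin from m/z, M0 intensity, the M2/M3 bins and the presence flags. The
#' numeric r1 assigned at imputation time is the training median of the
#' predicted bin.
#'
#' @param features data.frame from [extractFeatures()] (raw, undiscretized).
#' @param discretizer A fitted [Discretizer-class].
#' @param nTrees,seed Forest size and seed.
#' @param minComplete Minimum number of M1-complete envelopes required.
#' @return An object of class `m1Imputer`.
#' @export
fitM1Imputer <- function(features, discretizer, nTrees = 100, seed = 1,
                         minComplete = 50) {
  disc <- discretize(features, discretizer)
  complete <- disc[disc$m1_present & is.finite(disc$r1), , drop = FALSE]
  if (nrow(complete) < minComplete)
    stop(sprintf("need at least %d complete envelopes, got %d",
                 minComplete, nrow(complete)))
  df <- data.frame(y = droplevels(complete$r1_bin),
                   mz = complete$mz, log_i0 = complete$log_i0,
                   r2_bin = complete$r2_bin, r3_bin = complete$r3_bin,
                   m2_present = complete$m2_present,
                   m3_present = complete$m3_present)
  forest <- ranger::ranger(y ~ ., data = df, num.trees = nTrees,
                           min.node.size = 5, seed = seed, num.threads = 1,
                           respect.unordered.factors = "order")
  binMed <- tapply(complete$r1, complete$r1_bin, stats::median)
  structure(list(forest = forest, discretizer = discretizer,
                 binMedians = binMed),
            class = "m1Imputer")
}

#' Impute features of envelopes with a missing M1 peak
#'
#' Envelopes whose M1 peak was observed are returned unchanged (no-op
#' contract); envelopes missing M1 get their r1 bin predicted by the fitted
#' imputer, a numeric r1 equal to that bin's training median, and a
#' recomputed r1 excess. The returned table is discretized with the
#' imputer's own edges.
#'
#' @param features data.frame from [extractFeatures()].
#' @param imputer A fitted `m1Imputer` from [fitM1Imputer()].
#' @return Discretized feature data.frame in which every row has a defined
#'   `r1` and `r1_bin`.
#' @export
imputeM1 <- function(features, imputer) {
  stopifnot(inherits(imputer, "m1Imputer"))
  disc <- discretize(features, imputer$discretizer)
  todo <- which(!disc$m1_present)
  if (!length(todo)) return(disc)
  df <- data.frame(mz = disc$mz[todo], log_i0 = disc$log_i0[todo],
                   r2_bin = disc$r2_bin[todo], r3_bin = disc$r3_bin[todo],
                   m2_present = disc$m2_present[todo],
                   m3_present = disc$m3_present[todo])
  pred <- stats::predict(imputer$forest, data = df,
                         num.threads = 1)$predictions
  pred <- as.character(pred)
  disc$r1_bin[todo] <- factor(pred,
                              levels = levels(disc$r1_bin))
  med <- imputer$binMedians[pred]
  fallback <- stats::median(imputer$binMedians, na.rm = TRUE)
  med[is.na(med)] <- fallback
  disc$r1[todo] <- as.numeric(med)
  disc$r1_excess[todo] <- disc$r1[todo] - expectedNaturalR1(disc$mz[todo])
  disc
}
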