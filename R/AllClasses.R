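#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## ElementalComposition
## ---------------------------------------------------------------------------

#' Elemental composition of a metabolite
#'
#' Atom counts for the five elements that dominate small-molecule isotope
#' patterns (C, H, N, O, S), plus the number of hydrogen positions eligible
#' for deuterium incorporation during biosynthesis. In a D2O labeling
#' experiment only carbon-bound hydrogens retain deuterium; O-H and N-H
#' positions exchange back in aqueous solution, so `exchangeableH` is
#' typically well below the total hydrogen count.
#'
#' @slot counts Named integer vector with elements `C`, `H`, `N`, `O`, `S`.
#' @slot exchangeableH Integer, number of H positions that can carry
#'   deuterium; must not exceed `counts["H"]`.
#'
#' @examples
#' glucose <- ElementalComposition(C = 6, H = 12, O = 6, exchangeableH = 7)
#' atomCounts(glucose)
#' @aliases ElementalComposition
#' @exportClass ElementalComposition
setClass("ElementalComposition",
  representation(counts = "integer", exchangeableH = "integer"))

setValidity("ElementalComposition", function(object) {
  cnt <- object@counts
  if (!identical(names(cnt), c("C", "H", "N", "O", "S")))
    return("counts must be named C, H, N, O, S")
  if (any(is.na(cnt)) || any(cnt < 0L))
    return("atom counts must be non-negative")
  if (sum(cnt) == 0L)
    return("empty formula")
  ex <- object@exchangeableH
  if (length(ex) != 1L || is.na(ex) || ex < 0L)
    return("exchangeableH must be a single non-negative integer")
  if (ex > cnt[["H"]])
    return("exchangeableH cannot exceed the hydrogen count")
  TRUE
})

#' @param C,H,N,O,S Non-negative integer atom counts.
#' @param exchangeableH Number of deuterium-eligible hydrogen positions.
#'   Defaults to roughly the carbon-bound share of hydrogens
#'   (`floor(0.6 * H)`, at least 1 when H > 0).
#' @rdname ElementalComposition-class
#' @export
ElementalComposition <- function(C = 0, H = 0, N = 0, O = 0, S = 0,
                                 exchangeableH = NULL) {
  cnt <- as.integer(c(C = C, H = H, N = N, O = O, S = S))
  names(cnt) <- c("C", "H", "N", "O", "S")
  if (is.null(exchangeableH))
    exchangeableH <- if (cnt[["H"]] > 0L) max(1L, floor(0.6 * cnt[["H"]])) else 0L
  new("ElementalComposition", counts = cnt,
      exchangeableH = as.integer(exchangeableH))
}

#' @rdname ElementalComposition-class
#' @param object An `ElementalComposition`.
#' @export
setMethod("atomCounts", "ElementalComposition", function(object) object@counts)

#' @rdname ElementalComposition-class
#' @export
setMethod("exchangeableH", "ElementalComposition",
          function(object) object@exchangeableH)

setMethod("show", "ElementalComposition", function(object) {
  cnt <- object@counts
  f <- paste0(names(cnt)[cnt > 0L], ifelse(cnt[cnt > 0L] > 1L, cnt[cnt > 0L], ""),
              collapse = "")
  cat("ElementalComposition:", f,
      sprintf("(%d deuterium-eligible H)\n", object@exchangeableH))
})

## ---------------------------------------------------------------------------
## IsotopologueDistribution
## ---------------------------------------------------------------------------

#' Mass isotopologue distribution
#'
#' Ordered fractional abundances of the unit-mass isotopologues M0, M1, ...
#' of one compound. Peaks are binned by integer mass shift: at TOF
#' resolution a 13C substitution (+1.00336 Da) and a 2H-for-1H substitution
#' (+1.00628 Da) fall in the same Mn bin and are not resolved.
#'
#' @slot abundance Numeric vector of fractional abundances summing to 1.
#' @aliases IsotopologueDistribution
#' @exportClass IsotopologueDistribution
setClass("IsotopologueDistribution", representation(abundance = "numeric"))

setValidity("IsotopologueDistribution", function(object) {
  a <- object@abundance
  if (length(a) < 1L || any(is.na(a)))
    return("abundance must be a non-empty numeric vector")
  if (any(a < 0))
    return("abundances must be non-negative")
  if (abs(sum(a) - 1) > 1e-9)
    return("abundances must sum to 1 (within 1e-9)")
  TRUE
})

#' @param abundance Non-negative numeric vector; normalized to sum 1 unless
#'   `normalize = FALSE`.
#' @param normalize Logical; divide by the sum before validation.
#' @rdname IsotopologueDistribution-class
#' @export
IsotopologueDistribution <- function(abundance, normalize = TRUE) {
  if (normalize) {
    s <- sum(abundance)
    if (!is.finite(s) || s <= 0)
      stop("abundances must have a positive finite sum")
    abundance <- abundance / s
  }
  new("IsotopologueDistribution", abundance = as.numeric(abundance))
}

#' @rdname IsotopologueDistribution-class
#' @param object An `IsotopologueDistribution`.
#' @export
setMethod("abundances", "IsotopologueDistribution",
          function(object) object@abundance)

setMethod("show", "IsotopologueDistribution", function(object) {
  a <- object@abundance
  names(a) <- paste0("M", seq_along(a) - 1L)
  cat("IsotopologueDistribution over", length(a), "isotopologues\n")
  print(round(a, 5))
})

setMethod("length", "IsotopologueDistribution",
          function(x) length(x@abundance))

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Parameters of the synthetic isotopologue-envelope generator. `rho` is the
#' effective deuterium enrichment: the probability that a deuterium-eligible
#' hydrogen position carries 2H. `mixFraction` models pool dilution in a
#' consumer: the fraction of the circulating metabolite pool derived from the
#' labeled food, so the observed distribution is a convex mixture of the
#' labeled and natural patterns. Plant extracts correspond to
#' `mixFraction = 1` (undiluted, high enrichment); human biofluids to a small
#' `mixFraction`.
#'
#' @slot isotopeTable Named list; per element, numeric abundance vector over
#'   integer mass shifts 0, 1, 2, ... summing to 1.
#' @slot rho Enrichment probability in [0, 1].
#' @slot mixFraction Labeled-pool fraction in [0, 1].
#' @slot noiseSigma SD of multiplicative log-normal intensity noise.
#' @slot detectionLimit Intensity below which a peak is censored (dropped).
#' @slot nLabeledSamples,nUnlabeledSamples Samples per condition.
#' @slot baseIntensity Expected M0 intensity scale (counts).
#' @slot seed Integer seed making envelope sampling reproducible.
#' @aliases SimConfig
#' @exportClass SimConfig
setClass("SimConfig",
  representation(isotopeTable = "list", rho = "numeric",
                 mixFraction = "numeric", noiseSigma = "numeric",
                 detectionLimit = "numeric", nLabeledSamples = "integer",
                 nUnlabeledSamples = "integer", baseIntensity = "numeric",
                 seed = "integer"))

setValidity("SimConfig", function(object) {
  if (object@rho < 0 || object@rho > 1) return("rho must be in [0, 1]")
  if (object@mixFraction < 0 || object@mixFraction > 1)
    return("mixFraction must be in [0, 1]")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (object@detectionLimit < 0) return("detectionLimit must be >= 0")
  if (object@baseIntensity <= 0) return("baseIntensity must be > 0")
  if (object@nLabeledSamples < 0L || object@nUnlabeledSamples < 0L)
    return("sample counts must be >= 0")
  for (el in names(object@isotopeTable)) {
    ab <- object@isotopeTable[[el]]
    if (any(ab < 0)) return(sprintf("negative abundance for element %s", el))
    if (abs(sum(ab) - 1) > 1e-9)
      return(sprintf("isotope abundances for %s must sum to 1", el))
  }
  TRUE
})

#' @param rho,mixFraction,noiseSigma,detectionLimit,baseIntensity,seed See slots.
#' @param nLabeledSamples,nUnlabeledSamples Samples per condition.
#' @param isotopeTable Per-element isotope abundance table; defaults to
#'   [defaultIsotopeTable()].
#' @rdname SimConfig-class
#' @export
simConfig <- function(rho = 0.15, mixFraction = 1, noiseSigma = 0.2,
                      detectionLimit = 200, nLabeledSamples = 8,
                      nUnlabeledSamples = 8, baseIntensity = 1e5,
                      seed = 1, isotopeTable = defaultIsotopeTable()) {
  new("SimConfig", isotopeTable = isotopeTable, rho = rho,
      mixFraction = mixFraction, noiseSigma = noiseSigma,
      detectionLimit = detectionLimit,
      nLabeledSamples = as.integer(nLabeledSamples),
      nUnlabeledSamples = as.integer(nUnlabeledSamples),
      baseIntensity = baseIntensity, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: rho =", object@rho, ", mixFraction =", object@mixFraction,
      "\n  noiseSigma =", object@noiseSigma,
      ", detectionLimit =", object@detectionLimit,
      ", baseIntensity =", object@baseIntensity,
      "\n  samples:", object@nLabeledSamples, "labeled /",
      object@nUnlabeledSamples, "unlabeled, seed =", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## CandidateSet
## ---------------------------------------------------------------------------

#' Set of candidate metabolites with their isotopologue envelopes
#'
#' The central data container: a long-format peak table (one row per
#' candidate x sample x isotopologue-index) plus per-candidate metadata.
#' An *envelope* is the set of observed isotopologue peaks (M0..M4) of one
#' candidate in one sample -- the unit of observation for the classifier.
#'
#' @slot peaks data.frame with columns `candidate_id`, `sample_id`,
#'   `condition` (`"labeled"`/`"unlabeled"`), `iso_index` (0-based integer),
#'   `mz` (Da), `rt` (minutes), `intensity` (positive counts).
#' @slot candidates data.frame with one row per candidate: `candidate_id`,
#'   `base_mz`, `rt`, `ion_mode`, `upstream_pvalue` (NA when the upstream
#'   candidate-detection tool reported none).
#' @aliases CandidateSet
#' @exportClass CandidateSet
setClass("CandidateSet",
  representation(peaks = "data.frame", candidates = "data.frame"))

.PEAK_COLS <- c("candidate_id", "sample_id", "condition", "iso_index",
                "mz", "rt", "intensity")

setValidity("CandidateSet", function(object) {
  pk <- object@peaks
  missing <- setdiff(.PEAK_COLS, names(pk))
  if (length(missing))
    return(paste("peaks is missing column(s):", paste(missing, collapse = ", ")))
  if (nrow(pk)) {
    if (!all(pk$condition %in% c("labeled", "unlabeled")))
      return("condition must be 'labeled' or 'unlabeled'")
    if (any(!is.finite(pk$intensity)) || any(pk$intensity <= 0))
      return("intensities must be positive and finite")
    if (any(pk$iso_index < 0L))
      return("iso_index must be >= 0")
  }
  cd <- object@candidates
  if (!all(c("candidate_id") %in% names(cd)))
    return("candidates must contain candidate_id")
  if (nrow(pk) && !all(pk$candidate_id %in% cd$candidate_id))
    return("every peak must belong to a listed candidate")
  TRUE
})

#' @param peaks,candidates See slots.
#' @rdname CandidateSet-class
#' @export
CandidateSet <- function(peaks, candidates = NULL) {
  peaks <- as.data.frame(peaks)
  if (is.null(candidates)) {
    ids <- unique(peaks$candidate_id)
    m0 <- peaks[peaks$iso_index == 0L, , drop = FALSE]
    candidates <- data.frame(
      candidate_id = ids,
      base_mz = vapply(ids, function(i)
        stats::median(m0$mz[m0$candidate_id == i]), numeric(1)),
      rt = vapply(ids, function(i)
        stats::median(peaks$rt[peaks$candidate_id == i]), numeric(1)),
      ion_mode = "positive",
      upstream_pvalue = NA_real_,
      stringsAsFactors = FALSE)
  }
  rownames(peaks) <- NULL
  rownames(candidates) <- NULL
  new("CandidateSet", peaks = peaks, candidates = as.data.frame(candidates))
}

#' @rdname CandidateSet-class
#' @param object A `CandidateSet`.
#' @export
setMethod("peaks", "CandidateSet", function(object) object@peaks)

#' @rdname CandidateSet-class
#' @export
setMethod("candidateInfo", "CandidateSet", function(object) object@candidates)

#' @rdname CandidateSet-class
#' @export
setMethod("candidateIds", "CandidateSet",
          function(object) object@candidates$candidate_id)

#' @rdname CandidateSet-class
#' @export
setMethod("nCandidates", "CandidateSet",
          function(object) nrow(object@candidates))

#' @rdname CandidateSet-class
#' @export
setMethod("nEnvelopes", "CandidateSet", function(object) {
  if (!nrow(object@peaks)) return(0L)
  nrow(unique(object@peaks[, c("candidate_id", "sample_id")]))
})

setMethod("show", "CandidateSet", function(object) {
  cat("CandidateSet with", nCandidates(object), "candidates,",
      nEnvelopes(object), "envelopes,", nrow(object@peaks), "peaks\n")
  if (nrow(object@peaks)) {
    tab <- table(unique(object@peaks[, c("sample_id", "condition")])$condition)
    cat("  samples:", paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  }
})

#' Subset a CandidateSet by candidate id
#'
#' @param x A `CandidateSet`.
#' @param i Character vector of candidate ids (or logical/integer index into
#'   `candidateIds(x)`).
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "CandidateSet", function(x, i, j, ..., drop = FALSE) {
  ids <- candidateIds(x)
  keep <- if (is.character(i)) i else ids[i]
  new("CandidateSet",
      peaks = x@peaks[x@peaks$candidate_id %in% keep, , drop = FALSE],
      candidates = x@candidates[x@candidates$candidate_id %in% keep, ,
                                drop = FALSE])
})

## ---------------------------------------------------------------------------
## FilterConfig
## ---------------------------------------------------------------------------

#' Quality-filter configuration
#'
#' Thresholds for the rule engine that removes noisy candidates erroneously
#' detected upstream. Rules run in a fixed, documented order (presence,
#' intensity, retention time, m/z spacing, M1 availability) and each rule can
#' be disabled individually.
#'
#' @slot minM0Intensity Minimum median M0 intensity (counts).
#' @slot minSamplesPerCondition Minimum envelopes required in *each*
#'   condition.
#' @slot rtWindow Length-2 numeric, admissible retention-time range (min).
#' @slot maxRtSpread Maximum RT spread across a candidate's envelopes (min).
#' @slot mzSpacingTol Tolerance (Da) on the ~1.00336 Da unit-mass spacing.
#' @slot requireM1Fraction Fraction of envelopes that must contain M1.
#' @slot enabled Character vector of active rule names.
#' @aliases FilterConfig
#' @exportClass FilterConfig
setClass("FilterConfig",
  representation(minM0Intensity = "numeric",
                 minSamplesPerCondition = "integer",
                 rtWindow = "numeric", maxRtSpread = "numeric",
                 mzSpacingTol = "numeric", requireM1Fraction = "numeric",
                 enabled = "character"))

.FILTER_RULES <- c("insufficient-replicates", "low-intensity",
                   "rt-out-of-range", "rt-unstable", "incoherent-spacing",
                   "missing-m1")

setValidity("FilterConfig", function(object) {
  if (object@minM0Intensity < 0) return("minM0Intensity must be >= 0")
  if (object@minSamplesPerCondition < 0L)
    return("minSamplesPerCondition must be >= 0")
  if (length(object@rtWindow) != 2L || object@rtWindow[1] >= object@rtWindow[2])
    return("rtWindow must be (min, max) with min < max")
  if (object@maxRtSpread < 0) return("maxRtSpread must be >= 0")
  if (object@mzSpacingTol < 0) return("mzSpacingTol must be >= 0")
  if (object@requireM1Fraction < 0 || object@requireM1Fraction > 1)
    return("requireM1Fraction must be in [0, 1]")
  if (!all(object@enabled %in% .FILTER_RULES))
    return(paste("unknown rule(s):",
                 paste(setdiff(object@enabled, .FILTER_RULES), collapse = ", ")))
  TRUE
})

#' @param minM0Intensity,minSamplesPerCondition,rtWindow,maxRtSpread See slots.
#' @param mzSpacingTol,requireM1Fraction,enabled See slots.
#' @rdname FilterConfig-class
#' @export
filterConfig <- function(minM0Intensity = 1000,
                         minSamplesPerCondition = 3,
                         rtWindow = c(0.5, 30),
                         maxRtSpread = 0.5,
                         mzSpacingTol = 0.01,
                         requireM1Fraction = 0.5,
                         enabled = .FILTER_RULES) {
  new("FilterConfig", minM0Intensity = minM0Intensity,
      minSamplesPerCondition = as.integer(minSamplesPerCondition),
      rtWindow = as.numeric(rtWindow), maxRtSpread = maxRtSpread,
      mzSpacingTol = mzSpacingTol, requireM1Fraction = requireM1Fraction,
      enabled = enabled)
}

#' Fully permissive filter configuration (identity limit of the rule engine)
#' @export
permissiveFilterConfig <- function() {
  filterConfig(minM0Intensity = 0, minSamplesPerCondition = 0,
               rtWindow = c(-Inf, Inf), maxRtSpread = Inf,
               mzSpacingTol = Inf, requireM1Fraction = 0)
}

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig:\n",
      " minM0Intensity =", object@minM0Intensity,
      ", minSamplesPerCondition =", object@minSamplesPerCondition, "\n",
      " rtWindow = [", object@rtWindow[1], ",", object@rtWindow[2], "]",
      ", maxRtSpread =", object@maxRtSpread, "\n",
      " mzSpacingTol =", object@mzSpacingTol,
      ", requireM1Fraction =", object@requireM1Fraction, "\n",
      " enabled:", paste(object@enabled, collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## Discretizer
## ---------------------------------------------------------------------------

#' Quantile discretizer for isotopologue-ratio features
#'
#' Bin edges fitted on training data by quantiles; the same edges are applied
#' at train and predict time (they are carried inside the fitted classifier).
#' Values equal to an edge fall in the right-closed upper bin; missing ratios
#' map to an explicit `"missing"` category.
#'
#' @slot edges Named list of strictly increasing numeric edge vectors, one
#'   per feature (`r1`, `r2`, `r3`).
#' @slot nBins Requested number of bins.
#' @aliases Discretizer
#' @exportClass Discretizer
setClass("Discretizer",
  representation(edges = "list", nBins = "integer"))

setValidity("Discretizer", function(object) {
  for (nm in names(object@edges)) {
    e <- object@edges[[nm]]
    if (length(e) && any(diff(e) <= 0))
      return(sprintf("edges for %s must be strictly increasing", nm))
  }
  if (object@nBins < 2L) return("nBins must be >= 2")
  TRUE
})

#' @rdname Discretizer-class
#' @param object A `Discretizer`.
#' @export
setMethod("isFitted", "Discretizer",
          function(object) length(object@edges) > 0L)

#' @rdname Discretizer-class
#' @export
setMethod("binEdges", "Discretizer", function(object) object@edges)

setMethod("show", "Discretizer", function(object) {
  if (!isFitted(object)) {
    cat("Discretizer (unfitted),", object@nBins, "bins\n")
  } else {
    cat("Discretizer with", object@nBins, "quantile bins + 'missing':\n")
    for (nm in names(object@edges))
      cat(" ", nm, ": edges", paste(signif(object@edges[[nm]], 4),
                                    collapse = ", "), "\n")
  }
})

## ---------------------------------------------------------------------------
## ModelConfig / TrainingSet / LabelClassifier
## ---------------------------------------------------------------------------

#' Random-forest model configuration
#'
#' Defaults follow the published classifier settings: 100 trees, maximum
#' depth 5, minimum of 10 instances per leaf. Cross-validation is grouped by
#' candidate so the envelopes of one candidate never straddle folds.
#'
#' @slot nTrees,maxDepth,minInstances,cvFolds,seed Integers.
#' @aliases ModelConfig
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(nTrees = "integer", maxDepth = "integer",
                 minInstances = "integer", cvFolds = "integer",
                 seed = "integer"))

setValidity("ModelConfig", function(object) {
  if (object@nTrees < 1L) return("nTrees must be >= 1")
  if (object@maxDepth < 1L) return("maxDepth must be >= 1")
  if (object@minInstances < 2L) return("minInstances must be >= 2")
  if (object@cvFolds < 2L) return("cvFolds must be >= 2")
  TRUE
})

#' @param nTrees,maxDepth,minInstances,cvFolds,seed See slots.
#' @rdname ModelConfig-class
#' @export
modelConfig <- function(nTrees = 100, maxDepth = 5, minInstances = 10,
                        cvFolds = 5, seed = 1) {
  new("ModelConfig", nTrees = as.integer(nTrees),
      maxDepth = as.integer(maxDepth),
      minInstances = as.integer(minInstances),
      cvFolds = as.integer(cvFolds), seed = as.integer(seed))
}

setMethod("show", "ModelConfig", function(object) {
  cat("ModelConfig: ", object@nTrees, " trees, max depth ", object@maxDepth,
      ", min ", object@minInstances, " instances/leaf, ",
      object@cvFolds, "-fold grouped CV, seed ", object@seed, "\n", sep = "")
})

#' Envelope-level training set
#'
#' @slot features data.frame of raw (pre-discretization) per-envelope
#'   feature vectors as produced by [extractFeatures()].
#' @slot labels Integer 0/1 vector: 1 for envelopes drawn from the labeled
#'   condition of a truly labeled candidate.
#' @slot groups Character vector of candidate ids for grouped
#'   cross-validation.
#' @aliases TrainingSet
#' @exportClass TrainingSet
setClass("TrainingSet",
  representation(features = "data.frame", labels = "integer",
                 groups = "character"))

setValidity("TrainingSet", function(object) {
  n <- nrow(object@features)
  if (length(object@labels) != n || length(object@groups) != n)
    return("features, labels and groups must have equal length")
  if (n && !all(object@labels %in% c(0L, 1L)))
    return("labels must be 0/1")
  TRUE
})

#' @param features,labels,groups See slots.
#' @rdname TrainingSet-class
#' @export
TrainingSet <- function(features, labels, groups) {
  new("TrainingSet", features = as.data.frame(features),
      labels = as.integer(labels), groups = as.character(groups))
}

setMethod("show", "TrainingSet", function(object) {
  cat("TrainingSet:", nrow(object@features), "envelopes from",
      length(unique(object@groups)), "candidates;",
      sum(object@labels == 1L), "labeled /",
      sum(object@labels == 0L), "unlabeled\n")
})

#' Fitted envelope classifier
#'
#' Bundles the random forest with the exact preprocessing artifacts used at
#' training time (discretizer edges and M1 imputer), so prediction always
#' applies identical transformations.
#'
#' @slot forest The fitted `ranger` probability forest.
#' @slot discretizer The fitted [Discretizer-class].
#' @slot imputer The fitted M1 imputer (list) or `NULL`.
#' @slot featureNames Predictor columns, in training order.
#' @slot config The [ModelConfig-class] used.
#' @slot cvMetrics Named numeric vector (e.g. grouped CV ROC AUC), possibly
#'   empty.
#' @aliases LabelClassifier
#' @exportClass LabelClassifier
setClass("LabelClassifier",
  representation(forest = "ANY", discretizer = "Discretizer",
                 imputer = "ANY", featureNames = "character",
                 config = "ModelConfig", cvMetrics = "numeric"))

setMethod("show", "LabelClassifier", function(object) {
  cat("LabelClassifier (random forest,", object@config@nTrees, "trees, depth",
      object@config@maxDepth, ")\n  predictors:",
      paste(object@featureNames, collapse = ", "), "\n")
  if (length(object@cvMetrics))
    cat("  CV:", paste(names(object@cvMetrics),
                       signif(object@cvMetrics, 4),
                       sep = " = ", collapse = ", "), "\n")
})
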