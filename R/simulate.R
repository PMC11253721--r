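## draw envelopes using the CURRENT RNG stream (callers manage seeding)
.drawEnvelopes <- function(dist, cfg, condition, candidateId, baseMz, rt,
                           sampleIds) {
  a <- abundances(dist)
  k <- length(a)
  n <- length(sampleIds)
  if (n == 0L) return(NULL)
  ## intensity matrix: samples x isotopologues, multiplicative log-normal noise
  noise <- matrix(exp(stats::rnorm(n * k, 0, cfg@noiseSigma)), n, k)
  inten <- cfg@baseIntensity * matrix(a, n, k, byrow = TRUE) * noise
  rtEnv <- rt + stats::rnorm(n, 0, 0.02)
  keep <- inten >= cfg@detectionLimit & inten > 0
  idx <- which(keep, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  data.frame(
    candidate_id = candidateId,
    sample_id = sampleIds[idx[, 1L]],
    condition = condition,
    iso_index = idx[, 2L] - 1L,
    mz = baseMz + (idx[, 2L] - 1L) * 1.00336,
    rt = rtEnv[idx[, 1L]],
    intensity = inten[cbind(idx[, 1L], idx[, 2L])],
    stringsAsFactors = FALSE)
}

#' Sample noisy isotopologue envelopes from a distribution
#'
#' Realizes the observed-peak structure of LC-MS isotopologue envelopes: the
#' expected intensity of peak Mn is `baseIntensity * a_n`, perturbed by
#' multiplicative log-normal noise, and peaks falling below the detection
#' limit are censored (dropped). Censoring is the mechanism that produces
#' envelopes with missing M1/M2/M3 peaks. Reproducible under the config seed.
#'
#' @param dist An [IsotopologueDistribution-class].
#' @param cfg A [SimConfig-class]; its `seed` controls the draw.
#' @param condition `"labeled"` or `"unlabeled"`; selects the per-condition
#'   sample count from `cfg`.
#' @param candidateId,baseMz,rt Identity of the simulated candidate.
#' @return Long-format peak `data.frame` (one row per retained peak), columns
#'   as in [CandidateSet-class].
#' @examples
#' d <- naturalDistribution(ElementalComposition(C = 10, H = 12, N = 1, O = 3))
#' head(sampleEnvelopes(d, simConfig(noiseSigma = 0), "unlabeled"))
#' @export
sampleEnvelopes <- function(dist, cfg, condition = c("labeled", "unlabeled"),
                            candidateId = "cand1", baseMz = 300, rt = 10) {
  condition <- match.arg(condition)
  validObject(cfg)
  n <- if (condition == "labeled") cfg@nLabeledSamples else cfg@nUnlabeledSamples
  ids <- sprintf("%s_s%02d", substr(condition, 1, 3), seq_len(n))
  out <- withSeed(cfg@seed,
                  .drawEnvelopes(dist, cfg, condition, candidateId, baseMz,
                                 rt, ids))
  if (is.null(out)) {
    out <- data.frame(candidate_id = character(), sample_id = character(),
                      condition = character(), iso_index = integer(),
                      mz = numeric(), rt = numeric(), intensity = numeric(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Generate a ground-truth benchmark of candidate metabolites
#'
#' Emits candidates in two labeling regimes -- plant-like (undiluted pool,
#' `mixFraction = 1`) and human-like (pool mixing with small `mixFraction`)
#' -- plus optional junk candidates that violate envelope coherence
#' (incoherent m/z spacing, single-sample presence), mimicking noisy
#' upstream detections. Truly labeled candidates carry the enriched pattern
#' in their labeled-condition samples only; unlabeled candidates show the
#' natural pattern in both conditions. Default candidate counts follow the
#' published training set (272 labeled, 928 unlabeled).
#'
#' @param cfgPlant,cfgHuman [SimConfig-class] objects for the two regimes.
#' @param nLabeledCands,nUnlabeledCands,nJunk Candidate counts.
#' @param seed Integer; the benchmark is byte-identical under a fixed seed.
#' @param compositions Named list of [ElementalComposition-class] to draw
#'   from (see [metaboliteLibrary()]).
#' @param regime `"both"` alternates labeled candidates between the two
#'   regimes; `"plant"`/`"human"` uses a single regime (used e.g. to build
#'   disjoint train/test regimes for transfer evaluation).
#' @param idPrefix Candidate-id prefix; give two benchmarks different
#'   prefixes to keep their candidate ids disjoint.
#' @return List with `candidates` (a [CandidateSet-class]) and `truth`
#'   (data.frame: `candidate_id`, `is_labeled`, `regime`, `composition`).
#' @examples
#' bench <- makeBenchmark(nLabeledCands = 4, nUnlabeledCands = 6, seed = 7)
#' bench$candidates
#' @export
makeBenchmark <- function(cfgPlant = simConfig(rho = 0.15, mixFraction = 1),
                          cfgHuman = simConfig(rho = 0.15, mixFraction = 0.2),
                          nLabeledCands = 272, nUnlabeledCands = 928,
                          nJunk = 0, seed = 1,
                          compositions = metaboliteLibrary("all"),
                          regime = c("both", "plant", "human"),
                          idPrefix = "cand") {
  regime <- match.arg(regime)
  stopifnot(nLabeledCands >= 0, nUnlabeledCands >= 0, nJunk >= 0)
  validObject(cfgPlant); validObject(cfgHuman)
  withSeed(seed, {
    nTot <- nLabeledCands + nUnlabeledCands
    isLab <- rep(c(TRUE, FALSE), c(nLabeledCands, nUnlabeledCands))
    reg <- switch(regime,
      both = rep_len(c("plant", "human"), nTot),
      plant = rep("plant", nTot),
      human = rep("human", nTot))
    compIdx <- if (nTot) sample.int(length(compositions), nTot, replace = TRUE)
               else integer()
    ids <- sprintf("%s%04d", idPrefix, seq_len(nTot))
    mode <- if (nTot) sample(c("positive", "negative"), nTot, replace = TRUE)
            else character()
    rts <- stats::runif(nTot, 2, 28)
    pvals <- ifelse(isLab, stats::rbeta(nTot, 1, 4), stats::runif(nTot))

    peakList <- vector("list", nTot + nJunk)
    for (i in seq_len(nTot)) {
      comp <- compositions[[compIdx[i]]]
      cfg <- if (reg[i] == "plant") cfgPlant else cfgHuman
      baseMz <- monoisotopicMass(comp) +
        if (mode[i] == "positive") 1.007276 else -1.007276
      nat <- naturalDistribution(comp, 4, cfg@isotopeTable)
      distL <- if (isLab[i]) {
        lab <- labeledDistribution(comp, cfg@rho, 4, cfg@isotopeTable)
        mixDistributions(nat, lab, cfg@mixFraction)
      } else nat
      labIds <- sprintf("lab_s%02d", seq_len(cfg@nLabeledSamples))
      unlIds <- sprintf("unl_s%02d", seq_len(cfg@nUnlabeledSamples))
      peakList[[i]] <- rbind(
        .drawEnvelopes(distL, cfg, "labeled", ids[i], baseMz, rts[i], labIds),
        .drawEnvelopes(nat, cfg, "unlabeled", ids[i], baseMz, rts[i], unlIds))
    }

    ## junk: single-sample presence, incoherent m/z spacing
    junkIds <- if (nJunk) sprintf("%s_junk%03d", idPrefix, seq_len(nJunk))
               else character()
    for (j in seq_len(nJunk)) {
      baseMz <- stats::runif(1, 150, 550)
      nPk <- sample(3:5, 1)
      peakList[[nTot + j]] <- data.frame(
        candidate_id = junkIds[j],
        sample_id = "lab_s01",
        condition = "labeled",
        iso_index = 0:(nPk - 1L),
        mz = baseMz + cumsum(c(0, stats::runif(nPk - 1L, 0.3, 1.7))),
        rt = stats::runif(1, 2, 28),
        intensity = exp(stats::rnorm(nPk, log(cfgPlant@baseIntensity / 10),
                                     1)) + cfgPlant@detectionLimit,
        stringsAsFactors = FALSE)
    }

    peaks <- do.call(rbind, peakList)
    rownames(peaks) <- NULL
    candDf <- data.frame(
      candidate_id = c(ids, junkIds),
      base_mz = c(vapply(seq_len(nTot), function(i)
        monoisotopicMass(compositions[[compIdx[i]]]) +
          if (mode[i] == "positive") 1.007276 else -1.007276, numeric(1)),
        vapply(junkIds, function(j)
          min(peaks$mz[peaks$candidate_id == j]), numeric(1))),
      rt = c(rts, vapply(junkIds, function(j)
        peaks$rt[peaks$candidate_id == j][1], numeric(1))),
      ion_mode = c(mode, rep("positive", nJunk)),
      upstream_pvalue = c(pvals, stats::runif(nJunk)),
      stringsAsFactors = FALSE)
    truth <- data.frame(
      candidate_id = c(ids, junkIds),
      is_labeled = c(isLab, rep(FALSE, nJunk)),
      regime = c(reg, rep("junk", nJunk)),
      composition = c(names(compositions)[compIdx], rep(NA, nJunk)),
      stringsAsFactors = FALSE)
    list(candidates = CandidateSet(peaks, candDf), truth = truth)
  })
}
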