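.RATIO_NAMES <- c("M0/M1", "M1/M2", "M2/M3", "M3/M4")

#' Consecutive-isotopologue ratio summaries per condition
#'
#' For each candidate and condition, computes the mean and standard
#' deviation across envelopes of the ratios I(Mn)/I(Mn+1) for n = 0..3, on
#' raw intensities with no natural-isotope-abundance correction. A ratio is
#' defined in an envelope only when both peaks are observed; undefined
#' ratios are excluded from the mean (reported via the count, never as
#' zero). This is the reported-table orientation (M0/M1 ~ 4.7 for a typical
#' unlabeled small metabolite), the reciprocal of the r-features.
#'
#' @param cands A [CandidateSet-class].
#' @return Long data.frame: `candidate_id`, `condition`, `ratio`, `mean`,
#'   `sd`, `n` (number of envelopes where the ratio was defined; `mean` is
#'   `NA` when `n = 0`, `sd` is `NA` when `n < 2`).
#' @export
ratioSummary <- function(cands) {
  stopifnot(is(cands, "CandidateSet"))
  pk <- peaks(cands)
  key <- paste(pk$candidate_id, pk$sample_id, sep = "\r")
  envKeys <- unique(key)
  row <- match(key, envKeys)
  K <- max(4L, max(pk$iso_index)) + 1L
  I <- matrix(NA_real_, length(envKeys), K)
  I[cbind(row, pk$iso_index + 1L)] <- pk$intensity
  envCand <- pk$candidate_id[!duplicated(key)]
  envCond <- pk$condition[!duplicated(key)]

  res <- list()
  for (id in unique(envCand)) for (cond in c("unlabeled", "labeled")) {
    sel <- envCand == id & envCond == cond
    if (!any(sel)) next
    for (n in 0:3) {
      r <- I[sel, n + 1L] / I[sel, n + 2L]
      r <- r[is.finite(r)]
      res[[length(res) + 1L]] <- data.frame(
        candidate_id = id, condition = cond, ratio = .RATIO_NAMES[n + 1L],
        mean = if (length(r)) mean(r) else NA_real_,
        sd = if (length(r) >= 2L) stats::sd(r) else NA_real_,
        n = length(r), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Call deuterium incorporation from a ratio-summary pair
#'
#' Encodes the manual PeakView-style inspection as an explicit decision
#' rule. A candidate is `label-confirmed` when (a) the unlabeled-condition
#' mean M0/M1 exceeds the labeled-condition mean by at least `minFold`
#' (deuterium incorporation depresses M0/M1), and (b) the labeled condition
#' shows at least one heavier consecutive ratio (M1/M2, M2/M3, M3/M4) that
#' is defined while undefined in the unlabeled condition, or some ratio
#' whose between-condition shift exceeds the pooled standard deviation.
#' `insufficient-data` is returned when either condition has fewer than
#' `minN` envelopes with a defined M0/M1 ratio.
#'
#' @param summary Ratio-summary data.frame (as from [ratioSummary()]) for
#'   *one* candidate, containing both conditions.
#' @param minFold Minimum unlabeled/labeled fold change of mean M0/M1.
#' @param minN Minimum defined-M0/M1 envelope count per condition.
#' @return One-row data.frame: `candidate_id`, `decision`
#'   (`label-confirmed` / `not-confirmed` / `insufficient-data`),
#'   `fold_m0m1`, `extra_defined_ratios`, `max_sd_distance`.
#' @export
callLabel <- function(summary, minFold = 1.5, minN = 3) {
  id <- unique(summary$candidate_id)
  stopifnot(length(id) == 1L)
  get <- function(cond, ratio)
    summary[summary$condition == cond & summary$ratio == ratio, , drop = FALSE]
  u01 <- get("unlabeled", "M0/M1"); l01 <- get("labeled", "M0/M1")
  row <- function(decision, fold = NA_real_, extra = NA_integer_,
                  dist = NA_real_)
    data.frame(candidate_id = id, decision = decision, fold_m0m1 = fold,
               extra_defined_ratios = extra, max_sd_distance = dist,
               stringsAsFactors = FALSE)
  if (!nrow(u01) || !nrow(l01) || u01$n < minN || l01$n < minN)
    return(row("insufficient-data"))
  fold <- u01$mean / l01$mean

  heavier <- .RATIO_NAMES[-1L]
  extra <- 0L
  maxDist <- 0
  for (r in c("M0/M1", heavier)) {
    u <- get("unlabeled", r); l <- get("labeled", r)
    nu <- if (nrow(u)) u$n else 0L
    nl <- if (nrow(l)) l$n else 0L
    if (r != "M0/M1" && nl >= 1L && nu == 0L) extra <- extra + 1L
    if (nu >= 2L && nl >= 2L && is.finite(u$sd) && is.finite(l$sd)) {
      pooled <- sqrt((u$sd^2 + l$sd^2) / 2)
      if (pooled > 0)
        maxDist <- max(maxDist, abs(u$mean - l$mean) / pooled)
    }
  }
  confirmed <- fold >= minFold && (extra >= 1L || maxDist > 1)
  row(if (confirmed) "label-confirmed" else "not-confirmed",
      fold, extra, maxDist)
}

#' Call label incorporation for every candidate in a set
#'
#' @param cands A [CandidateSet-class] with envelopes in both conditions.
#' @inheritParams callLabel
#' @return data.frame with one [callLabel()] row per candidate.
#' @export
callLabels <- function(cands, minFold = 1.5, minN = 3) {
  rs <- ratioSummary(cands)
  do.call(rbind, lapply(unique(rs$candidate_id), function(id)
    callLabel(rs[rs$candidate_id == id, , drop = FALSE], minFold, minN)))
}
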