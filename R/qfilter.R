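## per-candidate rule checks; each returns TRUE when the candidate PASSES
.ruleChecks <- list(
  "insufficient-replicates" = function(pk, info, cfg) {
    env <- unique(pk[, c("sample_id", "condition")])
    sum(env$condition == "labeled") >= cfg@minSamplesPerCondition &&
      sum(env$condition == "unlabeled") >= cfg@minSamplesPerCondition
  },
  "low-intensity" = function(pk, info, cfg) {
    m0 <- pk$intensity[pk$iso_index == 0L]
    length(m0) > 0L && stats::median(m0) >= cfg@minM0Intensity
  },
  "rt-out-of-range" = function(pk, info, cfg) {
    rt <- stats::median(pk$rt)
    rt >= cfg@rtWindow[1] && rt <= cfg@rtWindow[2]
  },
  "rt-unstable" = function(pk, info, cfg) {
    env <- tapply(pk$rt, paste(pk$sample_id, pk$condition), stats::median)
    diff(range(env)) <= cfg@maxRtSpread
  },
  "incoherent-spacing" = function(pk, info, cfg) {
    if (is.infinite(cfg@mzSpacingTol)) return(TRUE)
    key <- paste(pk$sample_id, pk$condition)
    ok <- TRUE
    for (k in unique(key)) {
      sub <- pk[key == k, ]
      m0 <- sub$mz[sub$iso_index == 0L][1]
      if (is.na(m0)) next
      dev <- abs(sub$mz - (m0 + sub$iso_index * 1.00336))
      if (any(dev > cfg@mzSpacingTol)) { ok <- FALSE; break }
    }
    ok
  },
  "missing-m1" = function(pk, info, cfg) {
    key <- paste(pk$sample_id, pk$condition)
    withM1 <- unique(key[pk$iso_index == 1L])
    length(withM1) >= cfg@requireM1Fraction * length(unique(key))
  }
)

#' Rule-based quality filtering of candidates
#'
#' Step 1 of the scoring pipeline: remove noisy candidates erroneously
#' detected by upstream peak picking. Rules are applied per candidate in a
#' fixed, documented order -- presence (replicates per condition), M0
#' intensity, retention-time range, retention-time stability, m/z spacing
#' coherence, M1 availability -- and a rejected candidate carries the name of
#' the *first* failing rule. Kept and rejected sets partition the input, and
#' filtering is idempotent. The exact published rule list is not public;
#' this engine ships a reconstruction of its intent with every rule
#' individually toggleable via `enabled` in [filterConfig()].
#'
#' @param cands A [CandidateSet-class].
#' @param cfg A [FilterConfig-class].
#' @return List with `kept` (a [CandidateSet-class]) and `rejected`
#'   (data.frame: `candidate_id`, `reason`).
#' @examples
#' bench <- makeBenchmark(nLabeledCands = 3, nUnlabeledCands = 3,
#'                        nJunk = 2, seed = 1)
#' res <- applyFilters(bench$candidates, filterConfig())
#' res$rejected
#' @export
applyFilters <- function(cands, cfg = filterConfig()) {
  stopifnot(is(cands, "CandidateSet"))
  validObject(cfg)
  pk <- peaks(cands)
  info <- candidateInfo(cands)
  rules <- .FILTER_RULES[.FILTER_RULES %in% cfg@enabled]
  reasons <- character(0)
  rejectedIds <- character(0)
  for (id in info$candidate_id) {
    sub <- pk[pk$candidate_id == id, , drop = FALSE]
    for (r in rules) {
      if (!.ruleChecks[[r]](sub, info[info$candidate_id == id, ], cfg)) {
        rejectedIds <- c(rejectedIds, id)
        reasons <- c(reasons, r)
        break
      }
    }
  }
  keptIds <- setdiff(info$candidate_id, rejectedIds)
  list(
    kept = cands[keptIds],
    rejected = data.frame(candidate_id = rejectedIds, reason = reasons,
                          stringsAsFactors = FALSE))
}

#' Summarize filter rejections by reason
#'
#' @param rejected The `rejected` data.frame from [applyFilters()].
#' @return data.frame with columns `reason`, `n` (one row per reason).
#' @export
filterReport <- function(rejected) {
  if (is.null(rejected) || !nrow(rejected))
    return(data.frame(reason = character(), n = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(rejected$reason)
  data.frame(reason = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}
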