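#' Read a long-format candidate isotopologue table
#'
#' The interchange format for the whole pipeline: a UTF-8 comma- or
#' tab-delimited table (auto-detected, header mandatory) with columns
#' `candidate_id`, `sample_id`, `condition`, `iso_index`, `mz`, `rt`,
#' `intensity`, and optionally `ion_mode` and `upstream_pvalue`. Tables in
#' this shape can be exported from XCMS/HiResTEC-style peak tables; the
#' isotopologue index is explicit, never inferred from m/z.
#'
#' Malformed rows (non-numeric measurements, negative indices) are dropped
#' with a warning that reports their line numbers. Envelopes lacking an M0
#' peak are dropped with a warning. Candidates with fewer than
#' `minPerCondition` envelopes in either condition are dropped with a
#' warning.
#'
#' @param path Path to the table file.
#' @param minPerCondition Minimum envelopes required per condition (0 keeps
#'   everything).
#' @return A [CandidateSet-class].
#' @export
readCandidates <- function(path, minPerCondition = 0) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- readDelim(path)
  required <- .PEAK_COLS
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))

  ## line numbers in the file: header is line 1
  lineNo <- seq_len(nrow(raw)) + 1L
  for (col in c("iso_index", "mz", "rt", "intensity"))
    if (!is.numeric(raw[[col]]))
      raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  bad <- !is.finite(raw$mz) | !is.finite(raw$rt) |
    !is.finite(raw$intensity) | raw$intensity <= 0 |
    !is.finite(raw$iso_index) | raw$iso_index < 0 |
    raw$iso_index != round(raw$iso_index)
  if (any(bad)) {
    warning(sprintf("dropped %d malformed row(s) at line(s): %s",
                    sum(bad), paste(lineNo[bad], collapse = ", ")))
    raw <- raw[!bad, , drop = FALSE]
  }
  unknown <- setdiff(unique(raw$condition), c("labeled", "unlabeled"))
  if (length(unknown))
    stop(sprintf("unknown condition value(s): %s",
                 paste(unknown, collapse = ", ")))
  raw$iso_index <- as.integer(raw$iso_index)

  ## drop envelopes lacking M0
  key <- paste(raw$candidate_id, raw$sample_id, sep = "\r")
  hasM0 <- key %in% key[raw$iso_index == 0L]
  if (!all(hasM0)) {
    nDrop <- length(unique(key[!hasM0]))
    warning(sprintf("dropped %d envelope(s) lacking an M0 peak", nDrop))
    raw <- raw[hasM0, , drop = FALSE]
  }

  extra <- intersect(c("ion_mode", "upstream_pvalue", "base_mz", "cand_rt"),
                     names(raw))
  candCols <- raw[raw$iso_index == 0L, c("candidate_id", "mz", "rt", extra)]
  ids <- unique(raw$candidate_id)
  firstOf <- function(col, id) candCols[[col]][candCols$candidate_id == id][1]
  candDf <- data.frame(
    candidate_id = ids,
    base_mz = vapply(ids, function(i)
      if ("base_mz" %in% extra) firstOf("base_mz", i)
      else stats::median(candCols$mz[candCols$candidate_id == i]), numeric(1)),
    rt = vapply(ids, function(i)
      if ("cand_rt" %in% extra) firstOf("cand_rt", i)
      else stats::median(candCols$rt[candCols$candidate_id == i]), numeric(1)),
    ion_mode = if ("ion_mode" %in% extra)
      vapply(ids, function(i) firstOf("ion_mode", i), character(1))
      else rep("positive", length(ids)),
    upstream_pvalue = if ("upstream_pvalue" %in% extra)
      vapply(ids, function(i) firstOf("upstream_pvalue", i), numeric(1))
      else rep(NA_real_, length(ids)),
    stringsAsFactors = FALSE)
  raw <- raw[, .PEAK_COLS]

  if (minPerCondition > 0 && nrow(raw)) {
    env <- unique(raw[, c("candidate_id", "sample_id", "condition")])
    tab <- table(env$candidate_id, env$condition)
    full <- matrix(0L, nrow(tab), 2,
                   dimnames = list(rownames(tab), c("labeled", "unlabeled")))
    full[, colnames(tab)] <- tab
    ok <- rownames(full)[full[, "labeled"] >= minPerCondition &
                           full[, "unlabeled"] >= minPerCondition]
    dropped <- setdiff(ids, ok)
    if (length(dropped)) {
      warning(sprintf("dropped %d candidate(s) below %d envelopes/condition",
                      length(dropped), minPerCondition))
      raw <- raw[raw$candidate_id %in% ok, , drop = FALSE]
      candDf <- candDf[candDf$candidate_id %in% ok, , drop = FALSE]
    }
  }
  rownames(raw) <- NULL
  rownames(candDf) <- NULL
  CandidateSet(raw, candDf)
}

#' Write a CandidateSet to the long-format interchange table
#'
#' Numeric columns are written with enough digits that
#' `readCandidates(writeCandidates(x))` reproduces `x` exactly.
#'
#' @param cands A [CandidateSet-class].
#' @param path Output file; `.tsv` extension selects tab delimiting,
#'   anything else comma.
#' @return `path`, invisibly.
#' @export
writeCandidates <- function(cands, path) {
  stopifnot(is(cands, "CandidateSet"))
  pk <- peaks(cands)
  info <- candidateInfo(cands)
  m <- match(pk$candidate_id, info$candidate_id)
  pk$ion_mode <- info$ion_mode[m]
  pk$upstream_pvalue <- info$upstream_pvalue[m]
  pk$base_mz <- info$base_mz[m]
  pk$cand_rt <- info$rt[m]
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  writeDelim(pk, path, sep = sep)
  invisible(path)
}

#' Write a candidate score table
#'
#' One row per candidate (`candidate_id`, `p_L`, `p_U`, `score`, `rank`,
#' envelope counts per condition), sorted by descending score; ties are
#' broken by candidate id so the output is deterministic.
#'
#' @param scores data.frame as returned by [scoreCandidates()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeScores <- function(scores, path) {
  if (is.null(scores) || !nrow(scores)) stop("no scores")
  scores <- rankCandidates(scores)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  writeDelim(scores, path, sep = sep)
  invisible(path)
}

#' Read/write flat key-value configuration files
#'
#' The pipeline configuration is a flat `key = value` text format with `#`
#' comments; vector values are comma-separated.
#'
#' @param path File path.
#' @return Named list of character values.
#' @keywords internal
readKeyValue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad))
    stop(sprintf("malformed config line(s): %s",
                 paste(lines[bad], collapse = "; ")))
  out <- lapply(kv, function(m) trimws(m[3]))
  names(out) <- vapply(kv, function(m) trimws(m[2]), character(1))
  out
}

#' @rdname readKeyValue
#' @param values Named list/vector.
#' @keywords internal
writeKeyValue <- function(values, path) {
  lines <- vapply(names(values), function(k)
    paste0(k, " = ", paste(values[[k]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}
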