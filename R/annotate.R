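## standard monoisotopic mass deltas (Da)
.PROTON <- 1.007276
.NA_ION <- 22.989218
.H2O <- 18.010565
.FA <- 46.005480      # formic acid HCOOH
.HCOONA <- 67.987424  # sodium formate

#' Registry of LC-MS adducts
#'
#' Signed mass deltas added to the neutral monoisotopic mass to give the ion
#' m/z, from standard monoisotopic masses (proton 1.007276, Na+ 22.989218,
#' H2O 18.010565, HCOOH 46.005480, HCOONa 67.987424). `"[M-H]+"` is accepted
#' as a deprotonated negative-mode ion written with a sign typo (a message
#' is emitted when it is used). `"[M+?]+"` / `"[M+?]-"` are null adducts for
#' ions whose adduct is unknown: their neutral mass is undefined and they
#' pass through mode pairing ungrouped.
#'
#' @return data.frame with columns `name`, `delta`, `polarity`, `defined`.
#' @examples
#' adductRegistry()
#' @export
adductRegistry <- function() {
  data.frame(
    name = c("[M+H]+", "[M-H]-", "[M+Na]+", "[M-H+FA]-", "[M+H-H2O]+",
             "[M-H+HCOONa]-", "[M-H]+", "[M+?]+", "[M+?]-"),
    delta = c(.PROTON, -.PROTON, .NA_ION, .FA - .PROTON, .PROTON - .H2O,
              .HCOONA - .PROTON, -.PROTON, NA, NA),
    polarity = c("positive", "negative", "positive", "negative", "positive",
                 "negative", "negative", "positive", "negative"),
    defined = c(rep(TRUE, 7), FALSE, FALSE),
    stringsAsFactors = FALSE)
}

## canonical form: strip internal whitespace
.normAdduct <- function(name) gsub("[[:space:]]", "", name)

#' Neutral monoisotopic mass from a measured ion m/z
#'
#' `mz - delta(adduct)`, reported to 4 decimals. Unknown-adduct ions
#' (`"[M+?]±"`) give `NA`.
#'
#' @param mz Measured m/z (Da), > 0; vectorized.
#' @param adduct Adduct name(s) from the registry (whitespace tolerated,
#'   e.g. `"[M + H]+"`).
#' @param registry Adduct registry, see [adductRegistry()].
#' @return Neutral mass(es) in Da, rounded to 4 decimals.
#' @examples
#' neutralMass(366.0817, "[M-H]-")   # 367.0890
#' neutralMass(132.1011, "[M+H]+")   # 131.0938
#' @export
neutralMass <- function(mz, adduct, registry = adductRegistry()) {
  if (any(mz <= 0)) stop("mz must be > 0")
  adduct <- .normAdduct(adduct)
  m <- match(adduct, .normAdduct(registry$name))
  if (anyNA(m))
    stop(sprintf("unknown adduct(s): %s; registry contains: %s",
                 paste(unique(adduct[is.na(m)]), collapse = ", "),
                 paste(registry$name, collapse = ", ")))
  if (any(adduct == "[M-H]+"))
    message("'[M-H]+' interpreted as a deprotonated negative-mode ion ",
            "(sign typo)")
  round(mz - registry$delta[m], 4)
}

#' Invert an adduct: ion m/z from a neutral mass
#'
#' @param neutral Neutral monoisotopic mass (Da).
#' @inheritParams neutralMass
#' @return Ion m/z in Da.
#' @export
ionMz <- function(neutral, adduct, registry = adductRegistry()) {
  adduct <- .normAdduct(adduct)
  m <- match(adduct, .normAdduct(registry$name))
  if (anyNA(m))
    stop(sprintf("unknown adduct(s): %s",
                 paste(unique(adduct[is.na(m)]), collapse = ", ")))
  neutral + registry$delta[m]
}

#' Group features across ionization modes by shared neutral mass
#'
#' Features whose implied neutral masses agree within `tolDa` and whose
#' retention times agree within `tolRt` are grouped (single linkage); each
#' group reports the consensus neutral mass (mean). Features with an
#' undefined adduct remain singleton groups.
#'
#' @param features data.frame with columns `mz`, `rt`, `adduct`.
#' @param tolDa Neutral-mass tolerance (Da).
#' @param tolRt Retention-time tolerance (minutes).
#' @param registry Adduct registry.
#' @return `features` with appended `neutral`, `group`,
#'   `consensus_neutral` columns.
#' @examples
#' pairModes(data.frame(mz = c(225.0765, 227.0907, 249.0727), rt = 20,
#'                      adduct = c("[M-H]-", "[M+H]+", "[M+Na]+")))
#' @export
pairModes <- function(features, tolDa = 0.005, tolRt = 0.2,
                      registry = adductRegistry()) {
  features <- as.data.frame(features)
  n <- nrow(features)
  if (!n) {
    features$neutral <- numeric(0)
    features$group <- integer(0)
    features$consensus_neutral <- numeric(0)
    return(features)
  }
  neutral <- suppressMessages(
    neutralMass(features$mz, features$adduct, registry))
  ## single-linkage connected components under the dual tolerance
  group <- seq_len(n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (is.na(neutral[i]) || is.na(neutral[j])) next
    if (abs(neutral[i] - neutral[j]) <= tolDa &&
        abs(features$rt[i] - features$rt[j]) <= tolRt) {
      gi <- group[i]; gj <- group[j]
      group[group == gj] <- gi
    }
  }
  group <- match(group, unique(group))
  consensus <- vapply(group, function(g)
    mean(neutral[group == g]), numeric(1))
  features$neutral <- neutral
  features$group <- group
  features$consensus_neutral <- round(consensus, 4)
  features
}

#' Match a neutral mass against a composition library
#'
#' @param neutral Neutral monoisotopic mass (Da).
#' @param library Named list of [ElementalComposition-class] objects (e.g.
#'   [metaboliteLibrary()]).
#' @param tolPpm Mass tolerance in parts per million, > 0.
#' @return data.frame (`name`, `mass`, `ppm`) of compositions within
#'   tolerance, sorted by absolute ppm error; zero rows when nothing
#'   matches.
#' @examples
#' matchFormula(131.0939, metaboliteLibrary("B"), tolPpm = 10)
#' @export
matchFormula <- function(neutral, library, tolPpm = 10) {
  if (tolPpm <= 0) stop("tolPpm must be > 0")
  if (!length(library))
    return(data.frame(name = character(), mass = numeric(), ppm = numeric(),
                      stringsAsFactors = FALSE))
  mass <- vapply(library, monoisotopicMass, numeric(1))
  ppm <- (neutral - mass) / mass * 1e6
  out <- data.frame(name = names(library), mass = mass, ppm = ppm,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[abs(out$ppm) <= tolPpm, , drop = FALSE]
  out[order(abs(out$ppm)), , drop = FALSE]
}
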