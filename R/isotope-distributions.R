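#' Default natural isotope abundance table
#'
#' Representative IUPAC fractional abundances for the stable isotopes of C,
#' H, N, O and S, expressed over integer mass shifts (position 1 = +0 Da,
#' position 2 = +1 Da, ...). The table is configurable: any list with the
#' same shape can be passed wherever an isotope table is accepted, and each
#' element's abundances must sum to 1.
#'
#' @return Named list of numeric abundance vectors.
#' @examples
#' defaultIsotopeTable()$C   # 12C, 13C
#' @export
defaultIsotopeTable <- function() {
  list(
    C = c(0.9893, 0.0107),
    H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364),
    O = c(0.99757, 0.00038, 0.00205),
    S = c(0.95, 0.0075, 0.0425)
  )
}

## linear convolution of two abundance polynomials, truncated at maxLen
.conv <- function(a, b, maxLen = length(a) + length(b) - 1L) {
  out <- numeric(min(length(a) + length(b) - 1L, maxLen))
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    jmax <- min(length(b), length(out) - i + 1L)
    if (jmax < 1L) break
    idx <- i:(i + jmax - 1L)
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}

## abundance polynomial of n identical atoms, truncated at maxLen
.atomPower <- function(p, n, maxLen) {
  out <- 1
  base <- p
  while (n > 0L) {
    if (n %% 2L == 1L) out <- .conv(out, base, maxLen)
    base <- .conv(base, base, maxLen)
    n <- n %/% 2L
  }
  length(out) <- maxLen
  out[is.na(out)] <- 0
  out
}

#' Natural-abundance isotopologue distribution
#'
#' Unit-mass-aggregated natural isotope pattern of a molecule, obtained by
#' convolving the per-element multinomial isotope contributions. Peaks are
#' binned by integer mass shift (13C and 2H substitutions are not resolved,
#' matching TOF behavior); the pattern is truncated at `maxShift` and
#' renormalized.
#'
#' @param comp An [ElementalComposition-class].
#' @param maxShift Highest isotopologue index to keep (>= 2).
#' @param isotopeTable Per-element abundance table, see
#'   [defaultIsotopeTable()].
#' @return An [IsotopologueDistribution-class] with `maxShift + 1` entries.
#' @examples
#' d <- naturalDistribution(ElementalComposition(C = 6, H = 12, O = 6))
#' abundances(d)[2] / abundances(d)[1]   # ~ 0.068 for glucose
#' @export
naturalDistribution <- function(comp, maxShift = 4,
                                isotopeTable = defaultIsotopeTable()) {
  stopifnot(is(comp, "ElementalComposition"))
  validObject(comp)
  if (maxShift < 2) stop("maxShift must be >= 2")
  cnt <- atomCounts(comp)
  if (sum(cnt) == 0L) stop("empty formula")
  maxLen <- as.integer(maxShift) + 1L
  pat <- 1
  for (el in names(cnt)) {
    n <- cnt[[el]]
    if (n == 0L) next
    p <- isotopeTable[[el]]
    if (is.null(p)) stop(sprintf("no isotope abundances for element %s", el))
    pat <- .conv(pat, .atomPower(p, n, maxLen), maxLen)
  }
  length(pat) <- maxLen
  pat[is.na(pat)] <- 0
  IsotopologueDistribution(pat)
}

#' Deuterium-enriched isotopologue distribution
#'
#' Convolves the natural pattern with a Binomial(n_exch, rho) distribution
#' over the number of deuterium atoms incorporated at the eligible hydrogen
#' positions. `rho` is the effective per-position enrichment after
#' biosynthetic dilution, a free parameter of the simulation rather than the
#' D2O percentage of the growth water.
#'
#' @param comp An [ElementalComposition-class].
#' @param rho Per-position deuterium probability in [0, 1].
#' @inheritParams naturalDistribution
#' @return An [IsotopologueDistribution-class].
#' @examples
#' glc <- ElementalComposition(C = 6, H = 12, O = 6, exchangeableH = 7)
#' labeledDistribution(glc, rho = 0.15)
#' @export
labeledDistribution <- function(comp, rho, maxShift = 4,
                                isotopeTable = defaultIsotopeTable()) {
  if (length(rho) != 1L || is.na(rho) || rho < 0 || rho > 1)
    stop("rho must be a single probability in [0, 1]")
  nat <- naturalDistribution(comp, maxShift, isotopeTable)
  nex <- exchangeableH(comp)
  if (nex == 0L || rho == 0) return(nat)
  maxLen <- as.integer(maxShift) + 1L
  lab <- stats::dbinom(0:min(nex, maxShift), size = nex, prob = rho)
  pat <- .conv(abundances(nat), lab, maxLen)
  length(pat) <- maxLen
  pat[is.na(pat)] <- 0
  IsotopologueDistribution(pat)
}

#' Mixture of natural and labeled isotopologue distributions
#'
#' Models pool dilution in a consumer: the circulating metabolite pool is a
#' convex mixture of the pattern observed at baseline (natural) and the
#' pattern in the labeled food, with mixing fraction `f`.
#'
#' @param natural,labeled [IsotopologueDistribution-class] objects of equal
#'   length.
#' @param f Fraction of the pool derived from the labeled food, in [0, 1].
#' @return An [IsotopologueDistribution-class]:
#'   `f * labeled + (1 - f) * natural`.
#' @export
mixDistributions <- function(natural, labeled, f) {
  stopifnot(is(natural, "IsotopologueDistribution"),
            is(labeled, "IsotopologueDistribution"))
  if (length(natural) != length(labeled))
    stop("distributions must have the same length")
  if (length(f) != 1L || is.na(f) || f < 0 || f > 1)
    stop("f must be a single probability in [0, 1]")
  IsotopologueDistribution(f * abundances(labeled) +
                             (1 - f) * abundances(natural))
}
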