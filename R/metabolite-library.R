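#' Built-in library of metabolite elemental compositions
#'
#' A small panel of plant and mammalian metabolite formulas used by the
#' synthetic benchmark generator and by formula matching. The panel is split
#' into two disjoint halves: panel "A" (plant primary/secondary metabolites,
#' used for training-regime simulation) and panel "B" (amino acids and
#' common urine/plasma metabolites, used for the disjoint test regime in
#' transfer evaluation). The deuterium-eligible hydrogen counts are rounded
#' estimates of the carbon-bound hydrogens of each structure.
#'
#' @param panel `"all"`, `"A"` or `"B"`.
#' @return Named list of [ElementalComposition-class] objects.
#' @examples
#' lib <- metaboliteLibrary("A")
#' lib[["glucose"]]
#' @export
metaboliteLibrary <- function(panel = c("all", "A", "B")) {
  panel <- match.arg(panel)
  spec <- list(
    ## panel A: plant metabolites
    glucose            = c(6, 12, 0,  6, 0,  7, 1),
    sucrose            = c(12, 22, 0, 11, 0, 14, 1),
    citrate            = c(6,  8, 0,  7, 0,  4, 1),
    malate             = c(4,  6, 0,  5, 0,  3, 1),
    glutamine          = c(5, 10, 2,  3, 0,  5, 1),
    phenylalanine      = c(9, 11, 1,  2, 0,  8, 1),
    tyrosine           = c(9, 11, 1,  3, 0,  7, 1),
    tryptophan         = c(11, 12, 2, 2, 0,  8, 1),
    sinapate           = c(11, 12, 0, 5, 0,  8, 1),
    chlorogenate       = c(16, 18, 0, 9, 0, 11, 1),
    quercetin          = c(15, 10, 0, 7, 0,  5, 1),
    kaempferol         = c(15, 10, 0, 6, 0,  6, 1),
    sulforaphane       = c(6, 11, 1,  1, 2,  9, 1),
    glucoraphanin      = c(12, 23, 1, 10, 3, 14, 1),
    indole3acetate     = c(10, 9, 1,  2, 0,  7, 1),
    ascorbate          = c(6,  8, 0,  6, 0,  4, 1),
    succinate          = c(4,  6, 0,  4, 0,  4, 1),
    shikimate          = c(7, 10, 0,  5, 0,  6, 1),
    ferulate           = c(10, 10, 0, 4, 0,  7, 1),
    coumarate          = c(9,  8, 0,  3, 0,  6, 1),
    ## panel B: human biofluid metabolites
    isoleucine         = c(6, 13, 1,  2, 0, 10, 2),
    proline            = c(5,  9, 1,  2, 0,  7, 2),
    threonine          = c(4,  9, 1,  3, 0,  5, 2),
    methionine         = c(5, 11, 1,  2, 1,  8, 2),
    lysine             = c(6, 14, 2,  2, 0,  9, 2),
    histidine          = c(6,  9, 3,  2, 0,  5, 2),
    arginine           = c(6, 14, 4,  2, 0,  7, 2),
    glutamate          = c(5,  9, 1,  4, 0,  5, 2),
    aspartate          = c(4,  7, 1,  4, 0,  3, 2),
    dihydrosinapate    = c(11, 14, 0, 5, 0, 10, 2),
    hippurate          = c(9,  9, 1,  3, 0,  7, 2),
    creatinine         = c(4,  7, 3,  1, 0,  5, 2),
    urate              = c(5,  4, 4,  3, 0,  1, 2),
    citrulline         = c(6, 13, 3,  3, 0,  7, 2),
    taurine            = c(2,  7, 1,  3, 1,  4, 2),
    pantothenate       = c(9, 17, 1,  5, 0, 11, 2),
    nicotinate         = c(6,  5, 1,  2, 0,  4, 2),
    carnitine          = c(7, 15, 1,  3, 0, 12, 2),
    indoxylsulfate     = c(8,  7, 1,  4, 1,  5, 2),
    phenylacetylglycine = c(10, 11, 1, 3, 0, 7, 2)
  )
  keep <- switch(panel, all = seq_along(spec),
                 A = which(vapply(spec, `[`, numeric(1), 7) == 1),
                 B = which(vapply(spec, `[`, numeric(1), 7) == 2))
  out <- lapply(spec[keep], function(v)
    ElementalComposition(C = v[1], H = v[2], N = v[3], O = v[4], S = v[5],
                         exchangeableH = v[6]))
  out
}

## monoisotopic atomic masses (lightest isotope), Da
.ATOMIC_MASS <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                  O = 15.9949146196, S = 31.97207100)

#' Monoisotopic mass of an elemental composition
#'
#' @param comp An [ElementalComposition-class].
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopicMass(ElementalComposition(C = 6, H = 13, N = 1, O = 2))
#' @export
monoisotopicMass <- function(comp) {
  stopifnot(is(comp, "ElementalComposition"))
  sum(.ATOMIC_MASS * atomCounts(comp))
}
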