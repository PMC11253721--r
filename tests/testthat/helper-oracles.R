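# Independent oracles and shared fixtures for the test suite.

# Brute-force isotopologue distribution by direct enumeration over all
# per-atom isotope placements (feasible for molecules with <= 8 atoms).
# Deliberately independent of the package's convolution engine.
bruteForceDistribution <- function(comp, maxShift = 4,
                                   isotopeTable = defaultIsotopeTable()) {
  cnt <- atomCounts(comp)
  atomPs <- list()
  for (el in names(cnt))
    if (cnt[[el]] > 0L)
      atomPs <- c(atomPs, rep(list(isotopeTable[[el]]), cnt[[el]]))
  choices <- lapply(atomPs, function(p) seq_along(p) - 1L)
  grid <- as.matrix(expand.grid(choices))
  shift <- rowSums(grid)
  prob <- apply(grid, 1L, function(sh)
    prod(mapply(function(p, s) p[s + 1L], atomPs, sh)))
  agg <- tapply(prob, shift, sum)
  full <- numeric(maxShift + 1L)
  idx <- as.integer(names(agg))
  keep <- idx <= maxShift
  full[idx[keep] + 1L] <- agg[keep]
  full / sum(full)
}

# Long-format peak rows for one envelope with given intensities (named or
# positional by isotopologue index starting at M0).
envelopePeaks <- function(intens, id = "c1", sample = "s1",
                          condition = "labeled", mz0 = 300, rt = 10) {
  iso <- seq_along(intens) - 1L
  keep <- !is.na(intens)
  data.frame(candidate_id = id, sample_id = sample, condition = condition,
             iso_index = iso[keep], mz = mz0 + iso[keep] * 1.00336,
             rt = rt, intensity = intens[keep], stringsAsFactors = FALSE)
}

# Memoised expensive fixtures (built once per test run).
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Small two-regime benchmark used across modules.
smallBenchmark <- function() fixture("smallBenchmark",
  makeBenchmark(nLabeledCands = 12, nUnlabeledCands = 20, nJunk = 0,
                seed = 7))

# Classifier trained on a plant-panel benchmark.
trainedModel <- function() {
  fixture("trainedModel", {
    bench <- makeBenchmark(nLabeledCands = 40, nUnlabeledCands = 80,
                           seed = 101, compositions = metaboliteLibrary("A"),
                           idPrefix = "tr")
    ts <- buildTrainingSet(bench$candidates, bench$truth)
    trainClassifier(ts, modelConfig())
  })
}
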