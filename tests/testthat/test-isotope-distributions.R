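test_that("natural distributions match known single-element ratios", {
  dC <- naturalDistribution(ElementalComposition(C = 1), maxShift = 2)
  a <- abundances(dC)
  expect_equal(a[2] / a[1], 0.0107 / 0.9893, tolerance = 1e-12)

  dH <- naturalDistribution(ElementalComposition(H = 1), maxShift = 2)
  a <- abundances(dH)
  expect_equal(a[1], 0.999885, tolerance = 1e-9)
  expect_equal(a[2], 0.000115, tolerance = 1e-9)

  glc <- ElementalComposition(C = 6, H = 12, O = 6)
  a <- abundances(naturalDistribution(glc))
  expect_equal(a[2] / a[1], 0.068, tolerance = 0.01)
})

test_that("natural distribution agrees with brute-force enumeration", {
  comps <- list(
    ElementalComposition(C = 2, H = 3, N = 1, O = 1),
    ElementalComposition(C = 1, H = 4, O = 1),
    ElementalComposition(C = 2, O = 2, S = 1),
    ElementalComposition(C = 3, H = 5),
    ElementalComposition(N = 2, O = 3, S = 1)
  )
  for (comp in comps) {
    engine <- abundances(naturalDistribution(comp, maxShift = 4))
    oracle <- bruteForceDistribution(comp, maxShift = 4)
    expect_equal(engine, oracle, tolerance = 1e-10)
  }
})

test_that("every generated distribution sums to 1 within 1e-9", {
  for (comp in metaboliteLibrary("all")) {
    expect_equal(sum(abundances(naturalDistribution(comp))), 1,
                 tolerance = 1e-9)
    expect_equal(sum(abundances(labeledDistribution(comp, 0.15))), 1,
                 tolerance = 1e-9)
  }
})

test_that("empty or invalid compositions are rejected", {
  expect_error(ElementalComposition(), "empty formula")
  expect_error(ElementalComposition(C = 2, H = 1, exchangeableH = 3),
               "exchangeableH")
  expect_error(
    naturalDistribution(ElementalComposition(C = 2), maxShift = 1),
    "maxShift")
})

test_that("zero enrichment reproduces the natural pattern exactly", {
  comp <- ElementalComposition(C = 9, H = 11, N = 1, O = 3,
                               exchangeableH = 5)
  expect_identical(abundances(labeledDistribution(comp, 0)),
                   abundances(naturalDistribution(comp)))
})

test_that("deuterium-only envelope follows the binomial closed form", {
  # suppress the natural part: single-isotope table makes every element pure
  pure <- list(C = 1, H = 1, N = 1, O = 1, S = 1)
  comp <- ElementalComposition(H = 5, exchangeableH = 5)
  a <- abundances(labeledDistribution(comp, 0.2, maxShift = 5,
                                      isotopeTable = pure))
  expect_equal(a[1], 0.8^5, tolerance = 1e-12)
  expect_equal(a[2], 5 * 0.2 * 0.8^4, tolerance = 1e-12)
  expect_equal(a[1] / a[2], 0.8, tolerance = 1e-12)
})

test_that("full enrichment shifts the natural pattern up by n_exch units", {
  comp <- ElementalComposition(C = 4, H = 6, O = 2, exchangeableH = 3)
  nat <- abundances(naturalDistribution(comp, maxShift = 7))
  lab <- abundances(labeledDistribution(comp, 1, maxShift = 7))
  expect_equal(lab[1:3], c(0, 0, 0))
  expect_equal(lab[4:8], nat[1:5] / sum(nat[1:5]), tolerance = 1e-12)
})

test_that("mixing is a convex combination with the trivial endpoints", {
  nat <- IsotopologueDistribution(c(1, 0, 0, 0, 0))
  lab <- IsotopologueDistribution(c(0, 1, 0, 0, 0))
  expect_equal(abundances(mixDistributions(nat, lab, 0)), abundances(nat))
  expect_equal(abundances(mixDistributions(nat, lab, 1)), abundances(lab))
  expect_equal(abundances(mixDistributions(nat, lab, 0.5)),
               c(0.5, 0.5, 0, 0, 0))
  short <- IsotopologueDistribution(c(0.5, 0.5))
  expect_error(mixDistributions(nat, short, 0.5), "same length")
  expect_error(mixDistributions(nat, lab, 1.5), "probability")
})

test_that("M0 falls monotonically with enrichment and with mixing", {
  comp <- ElementalComposition(C = 10, H = 12, N = 1, O = 3,
                               exchangeableH = 7)
  nat <- naturalDistribution(comp)
  rhoGrid <- c(0.02, 0.05, 0.1, 0.2, 0.4, 0.8)
  a0 <- vapply(rhoGrid, function(r)
    abundances(labeledDistribution(comp, r))[1], numeric(1))
  expect_true(all(diff(a0) < 0))
  ## M0/M1 decreases as labeling increases
  m0m1 <- vapply(rhoGrid, function(r) {
    a <- abundances(labeledDistribution(comp, r))
    a[1] / a[2]
  }, numeric(1))
  expect_true(all(diff(m0m1) < 0))

  lab <- labeledDistribution(comp, 0.15)
  fGrid <- c(0.05, 0.1, 0.2, 0.5, 1)
  a0f <- vapply(fGrid, function(f)
    abundances(mixDistributions(nat, lab, f))[1], numeric(1))
  expect_true(all(diff(a0f) < 0))
})
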