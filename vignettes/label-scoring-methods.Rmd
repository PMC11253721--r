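---
title: "Scoring deuterium-labeled metabolite candidates: methods and design"
author: "deutracer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring deuterium-labeled metabolite candidates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deutracer)
```

## The problem

Intrinsic stable-isotope labeling of foods — growing a vegetable with
deuterium oxide mixed into its water so that biosynthesized metabolites
carry ²H — makes it possible to tell *food-derived* compounds in a
consumer's urine or plasma apart from host-derived compounds: after a meal
of the labeled food, only metabolites that actually came from the food show
an altered mass isotopologue distribution. In untargeted LC–MS data,
however, the isotope-tracing software that nominates candidate labeled
features produces large numbers of false positives, and the degree of
labeling seen in human biofluids is far lower than in the plant itself
(pool mixing: the circulating metabolite is a blend of the labeled dietary
molecules and the pre-existing unlabeled pool). `deutracer` implements a
machine-learning triage for this setting: it filters candidate
isotopologue envelopes, classifies each envelope's probability of coming
from a labeled compound, aggregates those probabilities into a
per-candidate contrast score, ranks candidates for manual validation, and
formalizes the final ratio-based validation step.

An *envelope* is the observed set of isotopologue peaks M0..M4 of one
candidate in one sample; it is the classifier's unit of observation. At
TOF resolution a ¹³C substitution (+1.00336 Da) and a ²H-for-¹H
substitution (+1.00628 Da) fall into the same unit-mass bin, so all
isotopologues are indexed by integer mass shift only.

## The pipeline

1. **Quality filtering** (`applyFilters`). A rule engine removes
   candidates that look like noisy upstream detections. Rules run in a
   fixed order — replicate presence in *both* conditions, median M0
   intensity, retention-time range and stability, unit-mass m/z spacing
   coherence, M1 availability — and a rejected candidate carries the first
   failing rule. The original hand-made rule list is not public; this
   engine reconstructs its intent, and every rule can be disabled.

2. **Feature engineering** (`extractFeatures`, `fitDiscretizer`,
   `fitM1Imputer`). Each envelope is described by the consecutive
   intensity ratios r1 = I(M1)/I(M0), r2 = I(M2)/I(M1), r3 = I(M3)/I(M2),
   the log10 M0 intensity, the M0 m/z, the excess of r1 over a
   natural-abundance expectation (`expectedNaturalR1`, which estimates the
   carbon count as `round(mz * 0.043)` and multiplies by the ¹³C/¹²C
   abundance ratio), and presence flags. Ratios are computed on raw
   intensities without natural-abundance correction, and an absent peak is
   an explicit missing value, never a zero. M2/M3 ratio features are
   discretized into quantile bins with an extra `"missing"` category
   (default 5 bins — few enough that `"missing"` stays a meaningful
   category, enough to retain ordering signal); a value equal to a bin
   edge goes to the right-closed upper bin. Because the M1 peak is the
   most informative and occasionally censored, missing-M1 features are
   imputed by a random-forest *classifier* that predicts the discretized
   r1 bin from m/z, intensity, the heavier-ratio bins and presence flags;
   the numeric r1 assigned is the training median of the predicted bin.
   The fitted bin edges and imputer travel inside the classifier object so
   train- and predict-time preprocessing are identical by construction.

3. **Classification** (`trainClassifier`, `predictProba`). A random
   forest with 100 trees, maximum depth 5 and a minimum of 10 instances
   per leaf (interpreted as minimum terminal-node size) predicts the
   probability that an envelope comes from a labeled compound. Training
   labels are envelope-level: the labeled-condition envelopes of truly
   labeled candidates are positives; everything else — including the
   unlabeled-condition envelopes of labeled candidates, which carry the
   natural pattern — is negative. Cross-validation is grouped by candidate
   id so envelopes of one candidate never straddle folds (the CV unit was
   not specified originally; grouping is the conservative choice against
   leakage), with 5 folds approximately stratified by candidate class.
   Fits are bit-reproducible (fixed seed, single thread).

4. **Scoring and ranking** (`scoreCandidates`, `compareRankings`). Per
   candidate, p_L and p_U are the unweighted mean predicted probabilities
   over labeled- and unlabeled-condition envelopes, and the score is
   p_L / (p_U + c) with c = 0.01. p_U is a reference point: a candidate
   whose envelopes score high in both conditions is down-weighted (score
   < 1 even at p_L = p_U = 0.5), which suppresses detections that merely
   *look* labeled everywhere. The score is strictly increasing in p_L,
   strictly decreasing in p_U, and bounded by 1/c = 100. Ranking is
   descending by score with candidate-id tie-breaks for determinism.
   `compareRankings` reproduces the blinded three-way comparison —
   classifier ranking vs. ascending upstream p-values vs. random selection
   — as precision at k, with the random arm averaged over reseeds.

5. **Ratio validation** (`ratioSummary`, `callLabel`). The final manual
   inspection step is encoded as an explicit rule on consecutive
   isotopologue ratios M_n/M_{n+1} (the reported-table orientation,
   reciprocal of the r-features). Per condition the mean ± SD across
   envelopes is computed; a ratio undefined in an envelope (either peak
   absent) is excluded rather than zeroed. A candidate is
   `label-confirmed` when the unlabeled/labeled fold change of mean M0/M1
   is at least `minFold` (default 1.5) *and* the labeled condition either
   shows a heavier consecutive ratio that the unlabeled condition lacks
   entirely or shows some ratio shifted by more than one pooled SD;
   `insufficient-data` is returned when either condition has fewer than
   `minN = 3` defined M0/M1 ratios.

6. **Adduct bookkeeping** (`neutralMass`, `pairModes`, `matchFormula`).
   Neutral monoisotopic masses are recovered by subtracting standard
   adduct deltas (proton 1.007276 Da, Na⁺ 22.989218, H₂O 18.010565, formic
   acid 46.005480, sodium formate 67.987424); features observed in both
   ionization modes are grouped when their implied neutral masses agree
   within 5 mDa and retention times within 0.2 min. Ions annotated with
   the internally inconsistent adduct string `"[M-H]+"` are treated as
   deprotonated negative-mode ions; the correction is messaged, never
   silent. Unknown (`"[M+?]"`) adducts carry no neutral mass and stay
   ungrouped.

## The synthetic benchmark

Real training data for this problem require labeled-plant feeding
experiments, so the package ships a simulator that generates
ground-truth-annotated envelopes with the statistical structure the
pipeline assumes.

* **Natural patterns** come from exact multinomial convolution of
  per-element isotope abundances (`naturalDistribution`), truncated at M4
  and renormalized. The default abundance table uses representative IUPAC
  values (¹³C 0.0107, ²H 0.000115, ¹⁵N 0.00364, ¹⁷O 0.00038, ¹⁸O 0.00205,
  ³³S 0.0075, ³⁴S 0.0425) and is overridable.
* **Enrichment** convolves the natural pattern with
  Binomial(n_exch, ρ) over deuterium counts at the deuterium-eligible
  (carbon-bound) hydrogen positions. ρ is an *effective* enrichment — the
  D₂O percentage of the growth water is diluted by biosynthesis in an
  unknown way, so ρ is a free parameter rather than a derived one.
* **Pool mixing** models a consumer's circulation as the convex mixture
  f·labeled + (1−f)·natural.
* **Observation noise**: peak intensity is base_intensity · a_n ·
  exp(N(0, σ²)), and peaks below a detection limit are censored — this
  censoring is the sole mechanism producing envelopes with missing
  M1/M2/M3 peaks.

Defaults define the two study regimes: plant-like ρ = 0.15, f = 1
(high incorporation, undiluted) and human-like ρ = 0.15, f = 0.2 (diluted
by pool mixing); 8 labeled and 8 unlabeled samples per candidate, matching
the feeding-study arm sizes; base intensity 10⁵ counts with σ = 0.2 and a
detection limit of 200 counts, chosen so that natural envelopes typically
show M0–M2 while human-regime labeled envelopes extend to M3 — the
"not all four peaks observed" phenomenology of real TOF data. Benchmark
candidate counts default to 272 labeled and 928 unlabeled, the published
training-set composition. Junk candidates (incoherent m/z spacing,
single-sample presence) exercise the filter engine. Upstream p-values are
simulated as Beta(1, 4) for truly labeled candidates and Uniform(0, 1)
otherwise — informative, but deliberately weaker than the classifier, the
qualitative situation the three-way ranking comparison probes.

The simulator does **not** model chromatographic peak shape, ion
suppression, co-elution, m/z calibration error, MS/MS spectra, or
deuterium-hydrogen back-exchange. Passing tests on simulated data
therefore demonstrate the pipeline's statistical machinery — filtering
logic, preprocessing identity, classifier transfer across composition
panels, score behavior — not performance on real chromatograms.

## Numerical and design choices

* Unit-mass aggregation throughout; isotopologue index is an explicit
  column in the interchange format and never inferred from m/z (spacing is
  *checked*, not used for assignment).
* Distributions are truncated at M4 then renormalized; truncation before
  or after convolution is equivalent for the retained entries, and every
  distribution sums to 1 within 1e-9.
* The interchange format is a delimited long-format text table (comma or
  tab, auto-detected); numerics are written with 17 significant digits so
  write-then-read is exact. Retention times are minutes.
* Tie-breaks: equal scores order by candidate id; a ratio value equal to a
  discretizer edge goes to the upper bin.
* Determinism: all stochastic steps derive from explicit seeds; forests
  run single-threaded with fixed seeds; a pipeline rerun under the same
  configuration is bit-identical (verified by checksum in the tests).
* The permutation null for the classifier permutes *envelope-level*
  labels. Permuting candidate-level ground truth instead leaves a subtle
  confound — positives are always labeled-condition envelopes, among which
  enriched envelopes are over-represented — and biases the null AUC above
  0.5 by several points.

## Problem sizes

The test-suite and acceptance computations use: the full 272/928 benchmark
for transfer evaluation (two disjoint composition panels, ~19,000
envelopes each) and for the ranking comparison; a 30/70-candidate
benchmark for the 20-reseed permutation null; a 60/140-candidate
human-regime benchmark for validation sensitivity/specificity; and
12–32-candidate benchmarks for unit and property tests. These sizes give
stable estimates of every property while keeping a full run on one CPU in
tens of seconds.

## Known limitations

* The hand-curated filtering rules and exact feature list used in the
  original workflow are not publicly documented; both are reconstructions
  of intent and are flagged as such in the documentation.
* The validation caller's sensitivity at the default `minFold = 1.5` is
  borderline for carbon-rich metabolites under weak labeling: a large
  molecule's natural ¹³C M1 is big, so the *relative* depression of M0/M1
  caused by a fixed deuterium dose shrinks with molecular size. Across
  independent simulated benchmarks sensitivity averages ~0.89
  (specificity ~1.0), with individual seeds ranging roughly 0.78–0.93.
  Lowering `minFold` trades specificity for sensitivity; the default is
  kept at 1.5 and the behavior documented rather than tuned.
* Candidates are scored per ionization-mode feature, not per metabolite;
  cross-mode aggregation happens only at the annotation stage
  (`pairModes`), mirroring how results tables report features.
* No natural-isotope-abundance correction is applied anywhere — the
  method compares conditions on raw ratios by design, since candidate
  formulas are generally unknown at this stage.
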