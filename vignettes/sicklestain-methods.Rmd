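---
title: "Models and methods behind sicklestain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sicklestain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sicklestain)
```

This vignette documents the models, the tunable parameters, and the design
choices behind the package, in the spirit of a methods section: what each
component assumes, why its defaults are what they are, and what the
synthetic-data machinery can and cannot tell you about real scanned stains.

## The assay and the S-index

In the paper-based solubility assay, lysed blood in a deoxygenating buffer
is dropped on chromatography paper. Insoluble deoxy-HbS polymers stay at
the deposition point and darken the stain center; soluble hemoglobin
spreads into a peripheral pink ring. The S-index condenses a stain to one
number:

$$ S \;=\; \frac{\operatorname{mean}\{255 - B_{ij} : (i,j) \in \text{center}\}}
                {\operatorname{mean}\{255 - B_{ij} : (i,j) \in \text{ring}\}} $$

with $B$ the blue channel of the 8-bit scan. Red and green channels never
enter the computation; the tests assert this invariance explicitly. $S = 1$
means no detectable center spot; values near 2 correspond to samples in
which most hemoglobin is HbS.

## Segmentation

The original analysis used a custom segmentation whose algorithm was not
published, so the package's segmenter is its own design, built on the
principle that it should use only the quantity the S-index is built on
(red color intensity $255 - B$) and degrade gracefully on negative stains:

1. **Foreground**: two-class Otsu threshold of $255 - B$, then the largest
   connected component. A component smaller than `min_area` (default 500
   px at the default render geometry), or an Otsu split whose classes
   differ by less than 20 intensity units, raises `no_stain_found`; a
   second component at least half the size of the first raises
   `ambiguous_stain` rather than guessing.
2. **Center**: the footprint centroid; the footprint radius comes from the
   component area ($r = \sqrt{A/\pi}$).
3. **Radial profile**: mean red intensity in 1-px annular bins.
4. **Boundary**: if the profile shows a genuine dark spot (inner/outer
   level ratio ≥ `contrast_threshold`, default 1.05), the center/ring
   boundary is placed at the steepest profile drop, refined to sub-pixel
   precision by converting the partial-coverage weights of the transition
   bins into a center pixel count and reading off the matching distance
   quantile. Otherwise the boundary defaults to `center_fraction` (0.35)
   of the footprint radius, so 0%-HbS stains still have a well-defined
   partition — without it the S-index of negatives would be undefined.

Pixels that are pure white (all channels ≥ 250) or fully saturated are
excluded from both masks because scanner clipping biases region means.
Masks are pixel-aligned; there are no sub-pixel mask boundaries.

On synthetic renders with known ground truth, this recovers both masks at
IoU ≥ 0.99 without noise and ≥ 0.90 with per-pixel noise SD up to 5 across
0–80% HbS; those bounds are asserted in the test suite.

## The synthetic stain generator

The generator exists so that every downstream statistic can be tested
against known truth. It renders a stain as two concentric regions on a
white page: a pink ring (red intensity 100, i.e. $B = 155$) and a center
whose red intensity is $100\,g(x)$, where the contrast function

$$ g(x) = 1 + A \frac{x^h}{x^h + k^h} $$

maps %HbS $x$ to the expected S-index. A logistic-saturating form is the
simplest curve consistent with the assay's phenomenology: no spot at
$x = 0$ ($g(0) = 1$), monotone growth, and saturation once nearly all
hemoglobin is insoluble. The per-formulation parameters are fixed once:

| formulation | $A$ | $k$ | $h$ | behavior |
|---|---|---|---|---|
| MS (15% w/v, canonical) | 1.25 | 22 | 2 | $g(10) = 1.21$: detectable at 10% HbS |
| MS 10% w/v | 0.85 | 30 | 2 | weaker early rise, lower plateau |
| MS 20% w/v | 0.90 | 16 | 2 | fast early rise, reduced amplitude |
| HS (3% w/v) | 1.00 | 45 | 2 | $g(10) = 1.05$: 10% HbS not separable |

These choices encode the empirical ordering the package's selection rule
must be able to reproduce: metabisulfite (MS) forms larger, better-trapped
deoxy-HbS aggregates than hydrosulfite (HS), so its curve rises faster
near the origin (detection limit 10% vs ~20% HbS), and among MS
concentrations the 15% w/v formulation maximizes the 0→20% S-index gain
(0.57 vs 0.26 and 0.55). `select_formulation()` applies the lexicographic
rule — greatest $S(20) - S(0)$, ties broken by the most gradual change
over 20–40% — and picks 15% MS from the generator's own curves.

Geometry defaults put the center-spot radius at 0.35 of the stain radius —
deliberately the same fraction the segmenter falls back to, so that
ground-truth masks of spot-free stains are recoverable rather than
arbitrary. Noise is additive truncated Gaussian per channel (clipped to
[0, 255], then rounded to 8 bits); boundary irregularity is an optional
band-limited radial perturbation (harmonics 2–4) scaled to a relative
amplitude `shape_jitter`. All randomness flows through one explicit seed
per operation, and identical specs with identical seeds produce
byte-identical rasters.

**Quantization.** Because renders are 8-bit, a noise-free S-index equals
$g$ only to about $\pm 0.005$ (the center intensity is rounded to an
integer); tests compare at that tolerance rather than pretending exact
equality is possible on an 8-bit raster.

**What the generator does not emulate**: real scanner illumination
gradients and color calibration error, paper fiber texture, irregular
wicking fronts, overlapping or clipped stains, and any dependence of ring
darkness on hematocrit or total hemoglobin. Passing tests therefore show
that the analysis correctly recovers the structure the generator encodes —
monotone contrast, step-decayed reagents, threshold-governed observers —
not that the segmenter is robust to every artifact of real scans.

## Reagent aging

Shelf-life data for this assay show an all-or-nothing pattern: a
formulation behaves like fresh reagent up to a limit of stability (LOS)
and then loses activity entirely. The package models this as a step
function (`reagent_activity()`): activity 1 through the LOS, 0 after, with
no gradual decay. The LOS table is MS 168 days (24 weeks) under both wet
and dry storage; HS 36 days dry and 6 days wet; and, as the single
modeled temperature effect, MS stored wet above 40 °C (the 62 °C desert
scenario) drops to 7 days. An expired reagent renders exactly like a
0%-HbS sample.

## Observer model

Raters are modeled as ordered-logit readers of the S-index: the latent
percept is $S + \varepsilon / \text{slope}$ with standard-logistic
$\varepsilon$, cut at ordered thresholds. Defaults place the
negative/positive cutpoint at 1.10 (midway between the MS contrast levels
of 0% and 10% HbS stains) and the AS/SS cutpoint at 2.06. As
slope → ∞ the rater becomes a hard threshold — asserted exactly in tests —
and at a cutpoint the two adjacent calls are equiprobable. The model is
deliberately minimal: real raters drift, fatigue, and anchor on reference
images; none of that is represented.

## Statistical components

- **Diagnostic metrics** are the five standard ratios of the 2×2 table.
  Zero-denominator metrics are reported as `NA` and named in `undefined`,
  never coerced to 0. Reporting convention: percentages to one decimal,
  kappas to two; unrounded values are always retained in the objects.
- **Fleiss' kappa** uses the standard formulation for a fixed number of
  ratings per subject. Intra-observer agreement treats one observer's
  replicate readings of each stain as the "raters"; the package requires a
  balanced replicate design and refuses partial ratings.
  `agreement_summary()` uses the population-SD convention (divisor $n$),
  which is what reproduces the published "mean ± SD" pairs from their
  individual values.
- **LOD by ROC**: visual calls are binary, so the ROC of a rater has a
  single operating point and AUC reduces to
  $(\text{sens} + \text{spec})/2$. Each candidate %HbS cutoff defines its
  own truth labeling; the candidate with the greatest AUC wins and ties
  break toward the lowest candidate, because the LOD is by definition the
  *lowest* detectable level. Candidates that make the truth single-class
  are excluded as undefined rather than scored.
- **Readout time** scans each class's per-minute score series for the
  earliest minute from which every later reading by every rater is
  correct; transient correct spells followed by relapses do not count.
  Total time adds the 10-minute preparation/incubation default.
- **Stability** uses Welch's two-sample t-test (two-sided, unequal
  variances) on replicate S-indices of 0%-HbS vs at-LOD samples, α = 0.05
  per time point with no multiplicity correction — each storage day is its
  own accept/reject decision, which matches how shelf-life criteria are
  applied in practice. A permutation test serves as the cross-check oracle
  in the suite. The LOS estimate is the last significant day strictly
  before the first non-significant one (0 if the first day already fails;
  right-censored at the final day if nothing fails). One statistical
  consequence is worth stating: days past the true step are genuine nulls,
  so each has an α chance of spurious significance, and the estimated LOS
  can exceed the true step day in about 5% of series. The property tests
  assert exact recovery in the large majority of seeded series and no
  underestimation, not universal exactness.
- **Shelf-life ratios** are compared in whole weeks (6 days ≈ 1 week,
  36 days ≈ 5 weeks, 168 days = 24 weeks), matching the convention in
  which such ratios are quoted; the unrounded ratio is kept alongside the
  integer label, with a "~" qualifier when the numerator is censored.
- **Kit costs** are summed in integer cents, so totals are exact at cent
  precision regardless of ledger length.

## Degenerate inputs and tie-breaks

- A pure-white ring (mean red intensity 0) makes the S-index undefined:
  `degenerate_input` error, not `Inf`.
- Two zero-variance groups with equal means give stability p = 1 by
  convention, flagged `degenerate`.
- Mixtures with both volumes zero, targets at or above the SCA component's
  %HbS, unknown formulations or storage conditions, unsorted stability
  days, and calls outside the declared label set all raise typed errors
  (`degenerate_mixture`, `infeasible_target`, `config_error`,
  `validation_error`) so callers can branch on failure identity.

## Problem sizes used by the test suite

The pipeline-recovery test renders 60 stains per %HbS level (five levels,
128-px rasters, noise SD 2) and requires segmentation IoU ≥ 0.90
throughout, monotone median S-index, exact recovery of the 10% MS
detection limit, and exact recovery of the HS step days from series of 10
replicates per group per day; the type-I rate of the stability test is
checked over 1000 null simulations against a three-sigma binomial band
around 0.05. The acceptance script runs the same pipeline at 30 stains per
level. These sizes were chosen as comfortably sufficient for the effect
sizes involved (the at-LOD contrast is ~10 within-group SDs).

## Known limitations

- The segmenter assumes one roughly circular stain per image; multi-stain
  sheets, perspective distortion, and color calibration targets are out of
  scope.
- The contrast curve's parameters are calibrated to reproduce the
  qualitative orderings above, not fitted to scanned data; absolute
  S-index values from real scans will differ.
- Fleiss' kappa is reported without confidence intervals, and the
  stability analysis does not model gradual (non-step) decay or
  temperatures other than room temperature and the single hot-storage
  flag.
- Blood mixture arithmetic treats hematocrit as metadata: physical Hct
  adjustment happens before mixing and does not enter the equation.
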