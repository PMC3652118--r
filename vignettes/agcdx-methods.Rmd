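---
title: "Methods: a two-stage fuzzy expert system for cervical cytology"
author: "agcdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-stage fuzzy expert system for cervical cytology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agcdx)
```

## The problem

Cervical cytology screening is reliable at its extremes — clearly normal
and clearly malignant fields — and least reliable in the middle, where
atypical glandular cells (AGC) exceed reactive change without showing
definite adenocarcinoma features. Readings there are subjective, and the
cost structure is asymmetric: a false negative delays treatment of a
curable disease. `agcdx` encodes the two information sources a
cytopathology service actually combines — the patient's clinical risk
background and the quantitative morphology of the stained nuclei — into an
auditable rule-based system whose every intermediate (membership degrees,
fired rules, activations) is inspectable.

## Mamdani inference and its numerical choices

Both stages are Mamdani fuzzy systems: piecewise-linear (triangle /
trapezoid) membership functions, `min` conjunction of antecedent degrees,
`min` (clipping) implication, `max` aggregation, centroid defuzzification.
All four operators are configurable on `mamdani_model()` (`prod`
conjunction and implication are supported); the defaults are the
conventional Mamdani controller choices and the only ones exercised by the
shipped configurations.

**Centroid discretization.** The aggregated output surface is sampled at
`resolution` (default 1001) uniform points and integrated with the
composite trapezoid rule. 1001 points keep the crisp score reproducible to
about three decimals on a [0, 100] universe, which is far below any
decision boundary's width; the test suite cross-checks the centroid
against an independent interpolation-plus-`pracma::trapz` oracle at 10^5
points to ≤ 1e-6 relative error.

**Ties and severity order.** The winning label is the output set with
maximal membership at the crisp score. Sets are ordered by severity in the
configuration, and exact ties (the DL overlap bands cross at scores 36 and
63) resolve to the *later* — more severe — set, because a missed positive
is costlier than an over-call in this screening context.

**Out-of-universe inputs and coverage gaps.** Crisp inputs are clamped to
the variable's universe with a warning (e.g. a mean eccentricity of 0.3
clamps to the HN floor of 0.5 and reads "regular"). The printed variable
definitions contain hairline gaps — e.g. nothing covers (0.5, 0.51) on the
binary universes — which are transcription artifacts of two-decimal
printing; a value falling inside such a gap is snapped just inside the
nearest set support, with a warning.

**A caveat on score monotonicity.** With `min` implication, clipping an
*asymmetric* output set at partial activation moves its centroid. In the
notch between two antecedent plateaus (where no rule reaches full
activation) the crisp score can therefore dip by a point or two even when
every fired rule points at the same consequent, recovering on the next
plateau. The class label never de-escalates along such a sweep, and
plateau-to-plateau scores are monotone; the tests assert exactly those two
properties rather than pointwise score monotonicity, which does not hold
for this (entirely standard) operator set. For the same reason, scaling
all activations by a common factor preserves the centroid only for
symmetric sets under `min` implication — under `prod` implication it holds
for any single set, and both true forms are tested.

## Stage 1: the clinical risk model

Seven inputs (E, IVSA, PS, NG, PG, ETS, LE) with the published set
intervals; 3·3·3·3·3·2·2 = 972 antecedent combinations; a two-set risk
output. Two details needed decisions:

* **Risk-output universe.** The sources give three inconsistent
  parameterizations of the risk output. The shipped default is the
  negative (0.5 1 1.5) / positive (1.51 2 2.5) form on [0.5, 2.5], chosen
  because the injury-resolution stage consumes the crisp risk score on
  exactly that universe — the stages compose without rescaling. The
  alternative (0 0 0.5)/(0.51 1 1.5) form ships as
  `inst/extdata/risk_output_alt.yaml`.

* **Rule base.** Only 20 of the validated risk rules are published; the
  criteria that pruned 972 candidate rules down to the validated set were
  never stated and are treated as unreproducible. The package therefore
  ships (a) the 20 published rules as a locked fixture
  (`printed_risk_rules()`), and (b) a *documented, non-clinical*
  severity-scoring policy (`risk_severity_policy()`) that fills in all 972
  consequents: many partners +2, unusually many +3, many pregnancies +2
  (+1 when the first pregnancy was young), STD +0.5, lesions +0.5, young
  sexual onset +0.5; score ≥ 2 ⇒ positive. Rule generation *fails* if the
  policy ever contradicts a published rule, so the fixture pins the
  policy. Combinations that are temporally impossible (sexual onset after
  every age in the age set; first pregnancy outside the onset/age
  ordering) are kept but disabled; for nulliparous (NG-null) antecedents
  the PG label is a dummy and PG-based impossibility is not enforced.

* **Nulliparous records.** The model expects a PG value for every record
  (the published rules combine a null pregnancy count with a PG label), so
  `assess_risk()` imputes the PG-universe midpoint with a message; the
  NG-null membership dominates the fired rules, so the imputed value never
  drives the outcome.

## Stage 2: image morphometry

The pipeline mirrors routine practice on hematoxylin-stained fields:
optional brightness/contrast adjustment, channel separation, nucleus
thresholding *on the green channel* (stained nuclei are darkest there),
opening + closing with a disk (radius 2 px), hole filling, small-object
removal (min 50 px), 8-connected labeling, and per-region moments.
Thresholding is Otsu's by default with a manual override, since acquisition
settings vary by microscope and operator. Radius and minimum area are
exposed parameters; the defaults suppress debris at typical ×400
magnifications where nuclei occupy thousands of pixels.

**The TN scale.** Staining should *increase* with darkness
(hyperchromasia), while raw intensity decreases; TN is therefore computed
on an inverted grayscale rescaled to the 0–150 staining universe,
`(255 − luminance) · 150/255`, so the published TN intervals (clear
50–80, medium 82–87, dark 92–150) apply unchanged. The raw-intensity
alternative is a configuration switch (`invert_staining = FALSE`).

**HN.** Whether nuclear "homogeneity" is a mean eccentricity or a
regular/irregular fraction is ambiguous; the mean of per-nucleus
eccentricities is the default, with `hn_stat = "fraction"` available.

**Nucleolus detection.** Inside each nucleus, pixels darker than
`mean − k·sd` (k = 1) of the region's intensity are spot candidates; the
candidate mask is opened with a 3×3 element so an accepted spot must
contain a solid 3×3 core, and surviving 8-connected spots with area in
[3 px, 25% of the nucleus] are counted. The opening is what makes the
count noise-proof: with Gaussian pixel noise alone, ~16% of pixels fall
below a one-sigma threshold, and isolated noise clusters of a few pixels
are common in a 10⁴-pixel nucleus, but a solid 3×3 noise block is
(p⁹ ≈ 10⁻⁷ per site) effectively impossible.

**Connectivity and coordinates.** Labeling is 8-connected; coordinates are
0-based (row, col). An embossing filter is provided for visual QC only and
has no effect on features.

## Stage 3: injury resolution

Inputs DN(3) · TN(3) · HN(2) · PN(3) · R(2) = 108 combinations; output DL
with Normal [0–41], AGC [31–68], Positive-to-malignity [58–100] trapezoids.
Five published rules are the locked fixture; `injury_severity_policy()`
fills in the rest (medium nuclei +1, large +3; medium staining +1, dark
+2; irregular +2; many nucleoli +1; positive risk +2; ≤ 2 ⇒ normal, 3–4 ⇒
AGC, ≥ 5 ⇒ positive), again pinned to the fixture. A strongly
hyperchromatic ("dark") nucleus masks its nucleoli, so every dark-staining
× detected-nucleoli combination is physically invalid and disabled. CIN
I/II/III sub-grading is out of scope: the crisp score suggests a class,
not a histological grade.

## Membership calibration from confidence intervals

`confidence_interval()` implements the sigma-known normal interval
`mean ± z_{α/2}·√(σ²/n)`. The published bounds only reproduce with the
*exact* quantile `qnorm(0.995) = 2.5758…` — the two-decimal 2.58 printed
alongside them overshoots by several units on these scales — so the exact
quantile is used. `intervals_to_membership()` turns ordered labeled
intervals into trapezoids: each interval is a degree-1 plateau, shoulders
fall linearly to the adjacent interval's near edge (so neighbors cross
between plateaus), and the outermost shoulders fall to the universe
bounds. Overlapping plateaus are truncated at the midpoint of their
overlap with a warning. Calibration is an optional recalibration path; the
published set boundaries remain the shipped defaults, since they are what
the validated system used. t-based small-sample intervals are deliberately
not offered — the calibration procedure being reproduced is the
known-variance form.

## The synthetic-data generator

`generate_image()` renders non-overlapping rotated ellipses
(rejection-sampled bounding circles, ≥ 8 px apart) with
supersampled-coverage anti-aliased edges on a lighter background, darker
interior nucleolus discs, and Gaussian pixel noise, then stores pixel-level
ground truth (mask labels, rasterized and analytic areas, drawn
eccentricities, rendered mean stainings, planted nucleolus counts). Nucleus
colors are constructed so that the green channel is darkest and the
inverted-grayscale staining of the rendered nucleus equals the drawn TN
value. Area draws are truncated at ±3 sd so frame sizing
(bounding-circle packing under 25% fill) is guaranteed feasible.

It emulates: controlled area/eccentricity/staining distributions per
diagnostic regime, visible nucleoli, additive sensor noise, and the
green-channel staining asymmetry. It does **not** emulate overlapping or
touching cells, cytoplasm texture, stain variability within a nucleus,
debris, or uneven illumination — so passing recovery tests demonstrates
the pipeline's correctness on well-separated nuclei above the noise floor,
not robustness to the full messiness of clinical fields (overlap
splitting, e.g. watershed, is explicitly out of scope).

Documented noise floor: at the default contrast (nucleus ≈ 60–100 gray
levels below background) recovery is exact up to `noise_sd ≈ 10`; the test
suite verifies that recovery error is monotone in `noise_sd` across 0 /
30 / 80. Two digitization facts bound the achievable precision and set the
test tolerances: rasterized area differs from the analytic ellipse area by
well under 2% at the areas used (≥ 150 px), and a digitized *circle* at a
fractional-pixel center carries a small moment asymmetry, so per-draw
eccentricity of a perfect disc fluctuates up to ≈ 0.07 (average ≈ 0.05)
even noiselessly; at the working eccentricities (0.6–0.85) this
sensitivity disappears and measured HN tracks the drawn mean to ~0.002.

`generate_cohort()` samples clinical records uniformly from the plateaus
of named risk sets, enforcing the temporal invariants (age ≥ onset, first
pregnancy ≥ onset) by rejection and flagging contradictory profiles.

## Problem sizes and determinism

The shipped verification uses 50 seeded fields of 5–30 nuclei for
ground-truth recovery, 100 seeded replicates (34/33/33 across the
small/medium/large area regimes) for calibration-interval coverage, 100
randomized activation patterns for the defuzzification oracle, and three
end-to-end fixtures pairing the published case records with
Normal/AGC/Positive-regime fields — sizes chosen so the full suite runs in
a few minutes on one core while keeping every stochastic margin wide
(regime coverage is designed at 99% against a 95% threshold). Every random
draw is seeded; identical inputs and configuration reproduce every report
byte for byte, and reports embed configuration hashes, input fingerprints,
and the package version.

## Known limitations

* The severity policies that complete the two rule bases are transparent
  heuristics pinned to the published excerpts — they are **not** clinical
  knowledge, and any deployment would replace them with a
  specialist-validated base via the configuration files.
* The published system's clinical validation (real patient images and the
  full validated rule bases) is not reproducible here; end-to-end checks
  run on synthetic stand-ins.
* One field of view per case; no multi-image aggregation, no overlapping
  nuclei, no whole-slide formats, no Bethesda reporting beyond the three
  output labels.
* The final call belongs to the specialist; the system is decision
  support, and its score is not calibrated to histological grade.
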