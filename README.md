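# agcdx

Diagnostic decision support for cervical neoplasia (CN) screening, focused
on the hard middle class: **atypical glandular cells (AGC)** — endocervical
cells whose nuclear atypia exceeds reactive change but falls short of
definite adenocarcinoma, where human readings disagree most and false
negatives are costliest.

`agcdx` implements a two-stage fuzzy expert system for cytotechnologists,
pathologists, and researchers in quantitative cytology:

1. **Risk model** — a Mamdani fuzzy inference system over seven
   clinical-background variables (age, onset of sexual activity, sexual
   partners, pregnancies, age at first pregnancy, STD history, cervical
   lesions) producing a crisp risk score and a Negative/Positive risk call.
2. **Image morphometry** — a cytology micrograph pipeline (level
   enhancement, green-channel Otsu thresholding, morphological cleanup,
   8-connected nucleus labeling, nucleolus detection) yielding four
   image-level features: mean nucleus area (DN), mean staining (TN), mean
   eccentricity (HN), and total nucleolus count (PN).
3. **Injury resolution** — a second Mamdani model fusing DN, TN, HN, PN and
   the risk score into a score on [0, 100] labeled **Normal / AGC /
   Positive-to-malignity**.

A seeded synthetic-image generator with pixel-level ground truth makes the
whole pipeline testable without patient material, and a confidence-interval
calibration procedure turns per-condition feature means into membership
plateaus.

## The model

Each linguistic set is a piecewise-linear membership function; e.g. the
trapezoid "young" with breakpoints (10, 15, 18, 22):

```
μ_young(t) = 0            t < 10 or t > 22
           = (t-10)/5     10 ≤ t ≤ 15
           = 1            15 ≤ t ≤ 18
           = 1-(t-18)/4   18 ≤ t ≤ 22
```

Inference is the classic Mamdani cycle. For rule *r* with antecedent labels
*A₁…A₇* the activation is `w_r = min_i μ_{A_i}(x_i)`; each consequent set
is clipped at `w_r`, clipped sets are aggregated by pointwise max, and the
crisp output is the centroid of the aggregated surface,

```
y* = ∫ y μ_agg(y) dy / ∫ μ_agg(y) dy,
```

evaluated by the trapezoid rule on a uniform 1001-point sampling of the
output universe. The winning label is the output set with maximal
membership at `y*`; exact ties break toward the more severe label. The
risk model enumerates 972 antecedent combinations (3·3·3·3·3·2·2), the
injury model 108 (3·3·2·3·2). Only excerpts of the validated rule bases
are published (20 risk rules, 5 injury rules); the shipped bases are
generated by documented, non-clinical severity-scoring policies pinned to
reproduce every published rule exactly (see the methods vignette).

Membership plateaus for the morphometry variables come from sigma-known
confidence intervals of per-condition feature means,
`mean ± z_{α/2} √(σ²/n)` with the exact normal quantile (2.5758… at 99%).

## Worked example

```r
library(agcdx)

# a clinical record (multiparous 43-year-old, no STD, no lesions)
rec <- clinical_record(age = 43, ivsa = 16, ps = 1, ng = 7, pg = 28,
                       ets = FALSE, le = FALSE)

# a synthetic cytology field in the AGC morphometry regime:
# medium-sized, moderately stained, elongated nuclei with visible nucleoli
gen <- generate_image(diagnosis_image_spec("agc", seed = 7))

diagnose(rec, gen$image)
#> === Diagnosis report ===
#> Background evaluation:
#>   risk: Negative (score 1.000)
#> Image data:
#>   nuclei: 5   DN: 8001.0 px   TN: 85.7   HN: 0.847   PN: 10
#> Injury resolution:
#>   AGC (score 49.50 / 100)
```

Reading the output: the clinical background alone carries no CN risk
(score 1.0 sits on the peak of the negative-risk set), but the nuclei
average ~8000 px (medium), staining 85.7 (medium, moderately
hyperchromatic), eccentricity 0.85 (irregular), with 10 nucleoli across 5
nuclei — a feature combination the rule base maps to the AGC class, score
49.5 inside the AGC plateau [41, 58].

Batch and file-based workflows are available through `cmd_risk()`,
`cmd_features()`, `cmd_diagnose()`, `cmd_calibrate()`, `cmd_simulate()`,
and the thin command-line wrapper `inst/cli/agcdx.R`:

```sh
Rscript inst/cli/agcdx.R simulate --image field.png --regime agc --seed 7
Rscript inst/cli/agcdx.R diagnose --record patient.csv --image field.png \
        --output report.json
```

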