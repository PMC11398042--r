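---
title: "Computed digital absorptiometry: model, protocol and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computed digital absorptiometry: model, protocol and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdar)
```

## The measurement problem

Computed digital absorptiometry (CDA) estimates *relative* bone mineral
density from a plain radiograph by co-imaging an aluminum step-wedge density
standard (ten steps S1–S10 of increasing thickness, S1 thinnest) beside the
joint. Each step attenuates the beam by a known, graded amount, so the gray
values recorded behind the wedge calibrate the gray scale of the whole image
in Hounsfield-like units (HU). Bone pixels can then be classified into the
per-step attenuation ranges, and the per-range pixel percentages act as a
relative density profile of the joint. The clinical question the pipeline
supports is which X-ray tube setting — tube voltage (kV) and current–time
product (mAs) — yields a calibration that covers the bone HU range without
corrupting the counts with background artifacts.

`cdar` implements the complete protocol: wedge calibration
(`build_calibration_table()`), color decomposition (`decompose()`), CIE76
color-pixel counting (`count_color_pixels()`, `percent_color()`), artifact
grading (`detect_artifacts()`), the comparative statistics
(`rm_anova_holm_sidak()`, `friedman_dunn()`), and a synthetic radiograph
generator (`render_radiograph()`, `generate_cohort()`) that stands in for
clinical data, which are not publicly deposited.

## The protocol, step by step

1. **Calibration.** For each wedge step, a measuring line is placed
   horizontally through the center of the step's footprint, spanning it from
   edge to edge. The raw minimum and maximum of the sampled HU values —
   no smoothing, no outlier rejection, band width 1 pixel by default —
   define that step's relative-density range. Ranges are calibrated
   *per radiograph*: every exposure of every subject gets its own table.
2. **Decomposition.** Each of the ten closed ranges `[Min, Max]` is masked
   with its assigned color (S1 `#FFFF00` … S10 `#A6CAF0`); an eleventh
   image paints the union of all ten ranges white (`#FFFFFF`). All eleven
   images are resized to 899 × 847 pixels and can be written as 24-bit BMP.
3. **Counting.** The density standard itself is masked black (`#000000`)
   and excluded from the counting domain. Every remaining pixel is credited
   to the nearest palette color by CIE76 distance in CIELAB (tolerance
   ΔE ≤ 10 by default), and per-step counts are divided by the white pixel
   count to give percent color pixels.
4. **Artifact grading.** Colored pixels lying *outside* the limb are
   background artifacts (typically hair near the limb whose gray values fall
   into the lowest step ranges). Their count relative to the white reference
   grades each image: none ≤ 0.005 < mild ≤ 0.05 < moderate ≤ 0.20 < severe.
5. **Comparison.** Calibration bounds are compared across settings with
   repeated-measures ANOVA plus Holm–Šidák post hoc; percent color pixels
   across steps with the Friedman test plus Dunn's comparisons.
   `recommend_setting()` selects the setting that reaches the lowest HU
   coverage without artifact occurrences.

### The white reference is limb-restricted

The white (bone-annotation) image counts only pixels *inside the limb* whose
HU lies in the union of the ten ranges, while the per-step color images are
unrestricted. This is a deliberate asymmetry: it is the only convention
under which percent color pixels can exceed 100 % when background structures
match a low step range, which is exactly the behaviour reported for
artifact-laden images in this protocol family, and it makes artifact
inflation quantifiable (the inflation sits in the numerator only).

### Counting happens after resizing

Whether pixels are counted before or after the 899 × 847 resize is not
dictated by the protocol descriptions we follow; `cdar` counts on the
resized images, matching the file pipeline (the BMP files *are* the resized
images). Since percent color is a ratio of counts subjected to the same
nearest-neighbour distortion, the choice has negligible effect on the
percentages. Nearest-neighbour is the only admissible resampling kernel
here: any interpolating kernel would invent colors outside the categorical
palette before counting.

## The synthetic radiograph generator

Because the clinical radiographs are available only on request, the package
ships a generative phantom whose defaults encode the study conditions: nine
limbs, five tube settings (50/60/70/80 kV at 1.2 mAs plus 60 kV at 12 mAs),
and a 512 × 512, 0.2 mm/pixel scene holding the ten-step wedge beside a
knee-like limb.

**Projection model.** Every pixel accumulates an optical depth
$A = \sum_m \mu_m(\mathrm{kV})\, t_m$ over the materials along its ray
(wedge aluminum, bone, soft tissue), and an affine map anchored at air
converts it to Hounsfield-like values:

$$\mathrm{HU} = g(\mathrm{mAs}) \cdot A - 1000, \qquad
  g(\mathrm{mAs}) = g_0\,\bigl(1 + 0.35 \log_{10}(\mathrm{mAs}/1.2)\bigr),
  \; g_0 = 1000.$$

The per-material effective attenuation coefficients decrease with kV, much
faster for aluminum and bone (high effective Z) than for soft tissue, which
is what slides the wedge scale down toward the tissue range as the beam
becomes more penetrating. The aluminum coefficients are calibrated so that
the S1 step mean at each preset sits at the midpoint of the published
reference ranges (at 50 kV; 1.2 mAs: 1005.6 HU, inside the reference
880.6–1130.6 band), and the step heights (6.69–12.13 mm, a free parameter:
the physical standard's dimensions are not published and these values make
no claim to equal them) are chosen so the 50 kV calibration spans roughly
880–2800 HU.

**Noise.** Gaussian in HU with sd $55 \cdot \sqrt{1.2/\mathrm{mAs}} \cdot
\mu_{\mathrm{Al}}(\mathrm{kV})/\mu_{\mathrm{Al}}(50)$. The mAs factor is the
usual quantum-noise proxy; the kV factor expresses that a low tube voltage
produces a high-contrast image — signal *and* fluctuations contract together
with the gray scale as kV rises. Without the contrast factor, the observed
Min–Max ranges at 80 kV would be wide relative to their (compressed) spacing
and neighbouring ranges would overlap several steps deep, which the real
calibrations do not show.

**mAs dispersion.** The gain term widens the spread between step values by
35 % per decade of mAs while the noise (hence each step's observed Min–Max
width) shrinks, so the 60 kV; 12 mAs calibration shows positive gaps between
consecutive ranges — the scattered, non-adjacent coverage characteristic of
high-current exposures. One fidelity limit is accepted knowingly: in the
reference data the high-mAs ranges also shift *downward*, which an affine HU
map anchored at air = −1000 cannot reproduce while mAs only scales
attenuation. The generator reproduces the dispersion, not the shift.

**Anatomy.** The limb is a soft-tissue ellipse (≈10–40 HU at 50 kV at its
center) containing three bone ellipses (femur, tibia, patella) with
projected thickness $t = t_{\max}(1-m)^2$, where $m$ is the squared
normalized ellipse radius. The quadratic exponent concentrates image area at
small bone thickness, so pixel counts fall from low to high attenuation
bands — the anatomical reason percent color pixels decrease from S1 to S10.
Bone attenuation tracks aluminum across kV, keeping the bone histogram
aligned with the wedge coverage at every preset. Per-limb jitter (±10 %
bone thickness, ±5 % size) differentiates the nine subjects.

**Background clutter.** `add_background_clutter()` paints filamentous
strokes near (but never inside) the limb whose HU values are drawn from the
dark end of the radiograph's own calibrated low-step ranges — emulating hair
that decomposes like the lowest steps. Severity controls the pixel budget as
a fraction of the white reference (mild 2 % on S1; moderate 12 %/4 % on
S1–S2; severe 30 %/12 %/3 % on S1–S3), chosen to land in the three grading
bands. The default cohort injects clutter into five of the nine limbs (two
mild, one moderate, two severe) and only at the three presets whose ranges
reach low HU (60 kV; 12 mAs, 70 kV, 80 kV) — at the two low settings the
wedge ranges start far above any background gray value, so hair cannot
interfere there. This plan reproduces the clinical artifact pattern,
including the per-(setting, step) occurrence counts.

### What the phantom does not emulate

No polyenergetic spectrum, scatter, heel effect, or detector MTF; no
anatomical realism beyond ellipses; no flat-field inhomogeneity; and the
high-mAs downward shift noted above. Tests passing on this phantom therefore
demonstrate that the *protocol arithmetic and decision logic* are correct
and that the qualitative exposure-dependence is reproduced — they do not
validate the method against real feline radiographs.

## Numerical and statistical choices

* Range endpoints are inclusive (Min/Max are attained sample values);
  overlapping ranges are left as-is, since each step is decomposed into its
  own image.
* The background fill `#404040` is a fixed sentinel outside the palette, so
  background, palette, white and black pixels are always distinguishable.
* The CIE76 tolerance default (ΔE = 10) is configuration: synthetic images
  are exact-palette, so counts are tolerance-insensitive; the margin guards
  against codec rounding on real files. Ties credit the lowest step.
* Artifact thresholds (0.005 / 0.05 / 0.20 of the white count) are package
  configuration standing in for a visual grading that has no published
  numeric criteria.
* `shapiro_wilk()` delegates to the vetted `stats::shapiro.test()`.
  The repeated-measures F uses the classical within-subject partition with
  no sphericity correction (a documented limitation). Holm–Šidák is the
  step-down `1-(1-p_{(i)})^{m-i+1}` with monotonicity enforcement. The
  Friedman statistic uses mid-ranks; exact within-row permutation p-values
  are available for small designs (`p_method = "exact"`), and Dunn's
  comparisons use Bonferroni as the family correction, the common reading
  of "Dunn's multiple comparisons".
* Degenerate inputs fail loudly: empty sample series, constant series in
  normality testing, zero white reference (no bone annotation), mixed
  exposures in replicate summaries, misaligned masks, malformed HEX codes.

## Problem sizes

The shipped simulations use 512 × 512 renders; the full synthetic study —
nine limbs × five presets, each decomposed into eleven 899 × 847 images and
quantified — is the unit of the cohort-level checks and of
`scripts/acceptance.R`. A complete cohort analysis takes a few minutes on a
single core.

## Worked example

```{r, eval = FALSE}
library(cdar)

# one limb, one exposure
rad <- render_radiograph(wedge_spec(), knee_tissue_spec(),
                         exposure_setting(60, 1.2), seed = 1)
res <- cda_pipeline(rad)
res$percent          # percent color pixels per step
attr(res$artifacts, "severity")

# the full synthetic study
an <- analyze_cohort(generate_cohort(seed = 1))
best <- recommend_setting(summarize_settings(an$results, an$summaries))
best$label           # "60 kV; 1.2 mAs"
```

## Known limitations

The HU-like scale read off projection radiographs is pseudo-quantitative;
the package treats it as given, as the protocol does. Anatomical ROI
segmentation (distal femur, proximal tibia, patella) and flat-field
correction are out of scope — the quantification unit is the whole joint.
The recommendation logic compares coverage and artifact occurrence only; it
does not model diagnostic task performance.
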