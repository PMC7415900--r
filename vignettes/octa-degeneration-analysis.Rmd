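---
title: "Quantifying retinal degeneration with OCT angiography: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal degeneration with OCT angiography: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octadegen)
library(dplyr)
```

## The scientific problem

In inherited retinal degeneration — modelled in the rat by the Royal College
of Surgeons (RCS) strain, where a *Mertk* defect prevents the retinal pigment
epithelium (RPE) from phagocytosing shed photoreceptor outer segments — the
photoreceptors die progressively, debris accumulates in the outer retina, and
the retinal and choroidal circulations remodel secondarily. Swept-source OCT
angiography (OCTA) can watch this happen longitudinally in the living eye:
structural B-scans carry layer thickness, and depth-resolved enface
angiograms separate the superficial vascular plexus (SVP), the deep capillary
plexus (DCP), and the choroidal circulation beneath the RPE.

This package implements the full quantification chain for such a study:

1. **Vessel index** for the retinal plexuses — the mean intensity of a
   vessel region minus the mean intensity of pooled intercapillary
   background regions on a median-filtered enface angiogram. It is an
   intensity-contrast statistic, deliberately free of any segmentation step.
2. **Sharpness index** for the choroidal plexus — the sum of
   central-difference gradient magnitudes of the 3x3-Gaussian-smoothed
   angiogram. The intact RPE is a strong scatterer that blurs everything
   beneath it, so choroidal sharpness is effectively an inverse dosimeter of
   RPE integrity: as the RPE degenerates the choroid snaps into focus.
3. **Layer thicknesses** from B-scans by vertical-gradient boundary
   detection, using the composite layers appropriate to a degenerating
   retina: ganglion cell complex (GCC), combined nuclear layer (INL-ONL,
   since OPL and ONL become inseparable after week 6), photoreceptor/debris,
   and total retina (ILM to RPE).
4. **Repeated-measures inference**: a two-way within-animal ANOVA
   (week x eye), Greenhouse-Geisser (GG) corrected for nonsphericity;
   Bonferroni-adjusted paired contrasts between consecutive visits; a linear
   orthogonal trend contrast ("P trend"); and one-way ANOVA across age
   groups for cross-sectional controls.

Because no instrument data ships with the package, a seeded synthetic cohort
generator produces B-scans, three-plexus angiograms, ROI sets and metadata
with known ground truth, and every downstream module is tested against that
truth.

## Conventions and units

All images are matrices of intensities in [0, 1] (integer files are scaled
by their dtype maximum — 255 or 65535 — never min-max rescaled, since the
vessel index compares intensities across images). Pixel coordinates put
x along columns, y along rows, the origin at the top-left pixel corner, and
pixel centers at half-integers. Physical pitch is configuration, not file
metadata: the wide-field protocol covers 15 x 9 mm in a 24 mm reference eye,
which scales by axial length to about 3.9 x 2.4 mm in the 6.3 mm rat eye
(`scan_field_in_eye()`), giving 7.8 um/px across 500 A-scans and 3.0 um/px
across 800 B-scans. The axial pitch default (1.95 um/px) is likewise a
configuration value; absolute thicknesses in micrometers are therefore only
as good as that calibration, and all cross-study comparisons in the package
are made on *percent changes*, which are pitch-free.

## The metrics

The vessel index of image $I$ with vessel mask $V$ and pooled background
mask $B$ is

$$\mathrm{VI} = \frac{\sum_{(i,j)\in V} I_{ij}}{|V|} - \frac{\sum_{(i,j)\in B} I_{ij}}{|B|}.$$

Background pixels are pooled across all background polygons (area-weighted)
rather than averaged per polygon, which is unbiased when polygons differ in
size. The optional 3x3 median prefilter is applied to one image that feeds
*both* terms, keeping the two terms on the same intensity scale. VI is
invariant to adding a constant to the image and scales linearly with
multiplicative intensity changes, which mitigates (but cannot eliminate)
unknown export-time contrast processing.

The choroidal sharpness index is

$$\alpha = \sum_{i,j\ \mathrm{interior}} \left| \nabla (G_3 * I)_{ij} \right|,$$

with $G_3$ the 3x3 binomial kernel ((1,2,1)/4 separably; sigma ~ 0.85 px —
the canonical 3x3 Gaussian approximation, fixed here because any true sigma
is a reproducibility hazard) and $\nabla$ central differences with the
one-pixel border excluded. The raw sum grows with image area, so the result
also carries a per-interior-pixel mean; the statistics stage uses the
per-pixel value by default so that differently sized exports remain
comparable.

## Boundary detection

The manual protocol this automates reads thickness at four sites: two
B-scans about 1 and 2 mm from the optic nerve head (ONH), two columns
+/- 0.5 mm lateral of the ONH column on each (the lateral offset is our
choice; it keeps sites clear of the large peripapillary vessels). The ONH is
found on the structural enface as the centroid of the darkest disc after
heavy smoothing (sigma = 10 px); bright vessels are first clipped to the
median and a fitted second-order illumination surface is removed so
vignetting cannot drag the centroid, and the final position is a local
quadratic vertex, which stays unbiased when the dip is truncated by the
image border.

Along a 15-column averaging band the detector finds, on the lightly
smoothed depth profile: the ILM as the first positive vertical-gradient peak
above an Otsu threshold on |gradient|; the outer retinal anchor as the
strongest negative edge below the ILM (the drop from the bright RPE band
into the weakly scattering sub-RPE space — the most contrasted outer edge at
every disease stage); the RPE top, and then the two interior interfaces
(GCC/INL-ONL, INL-ONL/PR-debris), each located by a short boxcar
step-matched filter and refined by the nearest gradient extremum with
3-point parabolic interpolation. The matched-filter anchoring matters under
speckle: because OCT speckle is multiplicative, raw gradient maxima are
systematically stronger in brighter bands, and selecting the largest
gradient peak biases interior boundaries toward bright layers; anchoring on
a fixed-length step filter removes that selection bias while the gradient
refinement keeps sub-pixel accuracy. Boundaries that cannot be found, or
that violate the fixed ILM < GCC/INL < INL/PR < RPE ordering, are flagged
undetected and the site is excluded from averaging rather than guessed.

On noise-free synthetic B-scans every boundary is recovered well within one
axial pixel; with heavy multiplicative speckle (gamma, shape 4) all four
boundaries stay within two pixels in >= 95% of renders at the baseline
disease stage, degrading gracefully (~92–96%) at late stages where the
RPE/debris contrast is intrinsically low.

## The statistics

`rm_anova_week()` implements the univariate two-within-factor ANOVA from
subject-by-cell means, testing each within-subject effect against its own
subject-interaction stratum. The GG epsilon is computed as
$\hat\varepsilon = \mathrm{tr}(\tilde S)^2 / ((k-1)\,\mathrm{tr}(\tilde S^2))$
from the covariance of the subject-level data projected onto an orthonormal
contrast basis (basis-invariant; exactly 1 for k = 2 and under compound
symmetry; bounded by $[1/(k-1), 1]$), and the week and week x eye p-values
are recomputed from the F distribution with both degrees of freedom
multiplied by $\hat\varepsilon$. Consecutive-week contrasts are paired
t-tests on eye-averaged animal means — deliberately not the ANOVA pooled
error, so they stay valid under exactly the sphericity violations the GG
correction worries about — with Bonferroni family size k - 1. The linear
trend contrast scores each animal with the integer orthogonal polynomial
coefficients (for six equally spaced visits: -5, -3, -1, 1, 3, 5) and tests
the scores against zero, two-sided. Degenerate zero-variance inputs return
conventional values (F = 0/p = 1 or F = Inf/p = 0) with warnings instead of
failing, so batch runs on synthetic edge cases never crash.

Two calibration notes, both visible in the test suite. First, the claim
"GG-corrected p is never smaller than the uncorrected p" is only true in the
rejection-relevant region: for F below roughly the critical value, shrinking
both degrees of freedom can *reduce* the upper-tail probability, so the
suite asserts monotonicity only there (and asserts that the corrected
critical value is always larger). Second, the type-I calibration of the
GG-corrected week test is run on 2000 null cohorts of 100 animals x 6 weeks
with AR(1) (rho = 0.6) within-animal errors. Autocorrelated errors are the
regime the correction exists for, and the large cohort isolates
implementation error from the well-known finite-sample conservativeness of
$\hat\varepsilon$: at the study's own size (6 animals) the corrected test is
strongly conservative (empirical size ~0.02 under sphericity) purely because
$\hat\varepsilon$ is biased downward in small samples — a property of the
method, not of this implementation.

## The synthetic cohort

`degeneration_params()` freezes the study conditions: 6 RCS animals, both
eyes, imaged every three weeks from week 3 to 18 (72 image sets), plus 14
control animals imaged once at ages spread over the same range (28 sets).
The RCS thinning schedule is anchored to the disease course: INL-ONL
collapses to 30.7% of baseline between weeks 3 and 6 and drifts down slowly
thereafter; GCC loses 12.1% of baseline by week 18 roughly linearly;
PR/debris loses 6.4% by week 6, 45.2% of baseline by week 12, then
stabilizes. Controls get mild linear nuclear/photoreceptor aging loss and no
vascular change. Absolute baselines (85/200/60 um) are plausible
configuration values — they are *not* measured quantities, which is why only
percent changes are meaningful. Per-animal biology is a lognormal thickness
multiplier (sigma = 0.05) held constant across weeks, so individual animals
differ while each animal's own percent change still reflects the schedule.

Vascular degeneration is mechanistic rather than cosmetic: each eye gets a
fixed capillary lattice and a fixed random deletion order, and week w simply
deletes the first `dropout(w)` fraction — so greater dropout removes a
superset of segments and the expected DCP vessel index is strictly
decreasing in dropout by construction. The SVP render does not depend on the
week at all. The choroidal texture is blurred with sigma = 4 * rho and
contrast-scaled by (1 - 0.7 * rho), rho being RPE integrity (1 at baseline,
0.2 from week 9), so sharpness rises as rho falls through both mechanisms;
choriocapillaris dropout lesions (dark discs) appear from week 15. All
enface images share a radial vignetting field (strength 0.3) and mild
multiplicative speckle; B-scans carry gamma speckle of shape 4. Four small
capillary-free exclusion zones are carved into each eye's lattice and serve
as the intercapillary background ROIs; the vessel ROI is auto-placed over
the densest lattice region clear of major vessels. One deliberate deviation
from an obvious parameterization: the RPE band reflectivity is
0.55 + 0.35 * rho rather than a steeper rho-coupling, so that the RPE band
remains the brightest outer band at every disease stage — otherwise no
gradient detector (nor a human reader) could place the PR/RPE interface on
late-stage scans at all.

What the generator does *not* emulate — projection artifacts, motion
stripes, flow-dependent decorrelation, leakage, real capillary topology —
bounds what passing tests mean: they demonstrate that the measurement chain
recovers programmed truth through realistic intensity statistics, not that
it would survive every artifact of real instrument exports.

## Problem sizes and determinism

Default synthetic fields are 160 x 160 px enface (24.4 x 15 um/px over the
3.9 x 2.4 mm field) and 160 x 288 px B-scans in 16-page stacks — sizes
chosen so a full cohort simulates, measures and analyses in about a minute
while every pixel-level contract is still exercised; nothing in the code
depends on these sizes, and the scan-protocol constants (500 A-scans, 800
B-scans) remain the documented pitch defaults for real exports. Every
artifact is a pure function of (parameters, seed): per-animal, per-visit and
per-stage seeds are derived from the base seed with a fixed integer-hash
splitter, and reruns are byte-identical, which the test suite asserts.

## Worked example

```{r example, eval = FALSE}
res <- run_pipeline(list(seed = 1, out_dir = "run1"))

res$thickness |>
  filter(group == "RCS") |>
  group_by(week) |>
  summarise(across(c(inl_onl_um, trt_um), mean))

res$stats |>
  filter(metric == "DCP_vessel_index", effect == "linear trend")

plot_trajectories(mutate(res$metrics, metric = paste(plexus, metric)))
```

The run directory additionally contains `metrics.csv`, `thickness.csv`,
`stats_report.csv`, a human-readable `summary.md` flagging per metric the
GG-corrected week effect, the trend direction, and which consecutive
intervals are significant at the Bonferroni-adjusted 0.05 level, plus a
config snapshot that replays the run exactly.

## Known limitations

- Absolute micrometer values depend on the configured axial pitch; only
  percent changes are calibration-free.
- The ROI scheme assumes reasonably uniform vignetting inside each polygon;
  extreme shading would bias the vessel index despite its offset invariance.
- The boundary detector is built for the four-boundary composite layer
  model of a degenerating retina; it does not attempt OPL/ONL separation or
  the external limiting membrane, and choroidal thickness is out of scope.
- Late-stage RPE/debris contrast is physically low; per-site failures there
  are flagged and excluded rather than silently imputed, so `n_sites` in the
  thickness table should be inspected when speckle is heavy.
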