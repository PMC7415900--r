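# octadegen

Longitudinal OCT-angiography (OCTA) quantification of retinal degeneration
in the rodent eye.

In inherited photoreceptor degeneration — the RCS rat being the classic
model — the retina thins in a characteristic sequence and the vasculature
remodels secondarily: the deep capillary plexus (DCP) rarefies while the
superficial plexus (SVP) is spared, and as the retinal pigment epithelium
(RPE) loses its scattering melanin the choroid beneath it comes into focus
on OCTA. This package turns those observations into numbers for anyone
running a longitudinal rodent OCTA study: imaging scientists quantifying
enface angiograms, and vision researchers who need the matching
repeated-measures inference.

## What it computes

**Vessel index** of a retinal plexus angiogram `I` with vessel mask `V` and
pooled intercapillary background mask `B`, after a 3x3 median prefilter:

    VI = sum(I[V]) / |V|  -  mean(I[B])

**Choroidal sharpness index**, a proxy for loss of RPE scattering:

    alpha = sum over interior pixels of | grad( G3 * I ) |

with `G3` the 3x3 binomial (Gaussian) kernel and central-difference
gradients (a per-interior-pixel mean is reported alongside the raw sum).

**Layer thicknesses** (GCC, combined INL-ONL, photoreceptor/debris, total
retina) from B-scans, by vertical-gradient boundary detection with
matched-filter anchoring and sub-pixel parabolic refinement, at four sites
placed 1 mm and 2 mm from the automatically located optic nerve head.

**Inference**: two-way repeated-measures ANOVA (week x eye within animal)
with Greenhouse-Geisser correction, Bonferroni-adjusted consecutive-week
paired contrasts, the orthogonal linear trend test (P trend), and one-way
ANOVA across age groups for cross-sectional controls.

A seeded synthetic cohort generator (`simulate_cohort()`) emulates an
RCS-like study — 6 followed animals x 2 eyes x 6 visits plus 14
cross-sectional controls — with full ground truth, so the entire pipeline
runs and is tested without any instrument data.

## Worked example

```r
library(octadegen)
library(dplyr)

res <- run_pipeline(list(seed = 1, out_dir = "run1"))

res$thickness |>
  filter(group == "RCS") |>
  group_by(week) |>
  summarise(across(c(gcc_um, inl_onl_um, pr_debris_um, trt_um),
                   ~round(mean(.x), 1)))
#>    week gcc_um inl_onl_um pr_debris_um trt_um
#> 1     3   85.1      205.          59.1   349
#> 2     6   83.2       62.7         55.5   201.
#> 3     9   80.8       60.7         43.5   185
#> 4    12   79         58.5         32.4   170.
#> 5    15   76.7       56.7         31.8   165.
#> 6    18   74.8       52.6         32.1   159.
```

The combined nuclear layer collapses between weeks 3 and 6 — here a 69.4%
loss of its baseline thickness (`percent_change(205, 62.7)`) — while the
ganglion cell complex declines slowly, about 12% over the whole study. The
statistics table confirms the vascular asymmetry that is the study's
hallmark: the DCP vessel index falls with a strongly significant decreasing
trend, the SVP shows no week effect.

```r
res$stats |>
  filter(metric == "DCP_vessel_index", effect %in% c("week", "linear trend")) |>
  select(effect, statistic, df1, epsilon_gg, p_adjusted)
#>   effect       statistic   df1 epsilon_gg p_adjusted
#> 1 week              81.8     5      0.368 0.00000165
#> 2 linear trend     -12.7     5     NA     0.0000528
```

Each run directory also contains `metrics.csv`, `thickness.csv`,
`stats_report.csv`, a `summary.md` that flags, per metric, the GG-corrected
week effect, the trend direction and the significant consecutive intervals,
and a config snapshot that replays the run byte-for-byte.

`plot_trajectories()` draws per-eye and group-mean trajectories for any
tidy metric table; `autoplot()` methods cover images and fitted ANOVA
objects, and `tidy()`/`glance()` return the fitted summaries as tibbles.

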