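---
title: "Characterizing scar collagen in H&E histology: segmentation, density and directional variance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing scar collagen in H&E histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(fiberDV)
```

## The problem

Burn scars remodel the dermis: skin appendages (hair follicles, glands)
disappear, collagen accumulates, and the remaining fiber bundles align into
parallel arrays instead of the isotropic basket-weave of healthy dermis. On a
hematoxylin-and-eosin (H&E) slide these changes are visible as a loss of
purple structures, an expansion of eosin-pink collagen, and a striking local
order of the pink texture. fiberDV turns those qualitative impressions into
four per-ROI numbers:

* **FS%** — fraction of pixels in the *foreground* segmentation
  (hematoxylin-dark nuclei, glands, follicles);
* **CAS%** — fraction of pixels in the *collagen area* segmentation;
* **CDM%** — mean of the collagen density map `m`;
* **DV%** — mean *directional variance* `V = 1 - R/m` of the fiber
  orientation field (0 = perfectly aligned, 1 = isotropic).

Scar reads as high CAS/CDM and low FS/DV relative to normal dermis.

## Color segmentation

Pixels are converted from 8-bit sRGB to CIE L\*a\*b\* (D65 white, standard
sRGB transfer function; the conversion is implemented directly from the CIE
formulas). Essentially all stain chromaticity lives in the a\* (green–red)
and b\* (blue–yellow) opponent layers, while L\* carries lightness, so
K-means with `k = 3` runs on the (a\*, b\*) pairs only. Each run is seeded
with k-means++ and Lloyd's algorithm iterates to convergence; the best of 10
restarts by within-cluster sum of squares is kept, and everything is
deterministic given the seed.

Cluster indices are arbitrary, so roles are assigned afterwards from the one
channel K-means never saw: the cluster with the highest mean L\* becomes
background (bare slide), the lowest becomes foreground (hematoxylin), and the
remaining cluster is collagen. Two clusters whose mean L\* coincide within
1e-6 make the assignment ill-posed and raise an error rather than guessing.
`k` stays at 3 even for ROIs that genuinely lack a class (a pure-scar crop
has almost no appendage pixels); the role rule still applies and the reported
fractions simply reflect the resulting split. For scoring segmentations of
such degenerate scenes against ground truth we therefore use the standard
permutation-invariant clustering accuracy (best bijection between the three
masks and the three classes); for scenes containing all three classes this
coincides with the role mapping.

Clustering is per ROI, not per whole slide, matching how regions are
compared.

## Density, orientation and directional variance

**Airy-disk kernel.** All local averaging uses a kernel proportional to the
airy diffraction pattern `[2 J1(x)/x]^2`, scaled so its first zero falls at
`radius_px` pixels, truncated there and normalized to unit sum. It is smooth,
rotationally symmetric and peaked at the center — a physically motivated
alternative to a Gaussian with strictly compact support.

**Density `m`.** The binary collagen mask convolved with the kernel gives the
kernel-weighted local fraction of collagen-positive pixels, `m in [0, 1]`.
Borders use reflect padding (edge row/column mirrored into the pad), so an
all-positive mask maps to exactly 1 everywhere. Convolution is FFT-backed;
values within 1e-9 of 0 or 1 are snapped so that the exact-endpoints contract
survives floating-point rounding.

**Orientation.** Fiber direction at a pixel is found by sampling the mask
along centered line probes at `n_angles` candidate angles spaced
`180/n_angles` degrees apart, each probe `2*window_radius + 1` unit steps
long with nearest-pixel rounding. A probe's score is the number of distinct
positive pixels it passes through (near 45 degrees two unit steps can round
to the same pixel; counting distinct pixels avoids double-counting), and the
arg-max angle wins, ties going to the smallest angle. A pixel whose best
score is 1 — no support beyond itself — has no defined orientation. Angles
are axial: a fiber at theta and theta + 180 degrees is the same fiber.

**Directional variance.** Axial angles are doubled, which is what makes them
vector-summable: theta and theta + 180 map to the same unit vector
`(cos 2theta, sin 2theta)`, while orthogonal fibers map to opposite vectors
and cancel. Both components are convolved with the same airy kernel, giving
the resultant magnitude `R`; the denominator `m` is recomputed from the
orientation-validity mask under the same kernel, so `R <= m` holds pointwise
by the triangle inequality and `V = 1 - R/m` lands in [0, 1] by construction
(clamped against overshoot below 1e-9). Pixels with `m = 0` are invalid —
background is routine, never an exception. For a local mix placing fraction
`p` of fibers at one axis and `1 - p` orthogonal, `V = 1 - |2p - 1|`: the
analytic cases `V = 0` (aligned), `V = 1` (50/50) and `V = 0.5` (75/25) that
the test suite checks. These identities hold where the kernel support sees
the stated mix, i.e. away from borders, where reflect padding locally
unbalances it; tests evaluate them on the interior.

### Defaults and what they mean

| parameter | default | units | why |
|---|---|---|---|
| kernel `radius_px` | 16 | px | neighborhood of ~30 px captures several fiber bundles without washing out regional contrast |
| `window_radius` | 8 | px | probe length 17 px distinguishes a 3-px-wide fiber's axis from its cross-section |
| `n_angles` | 18 | — | 10-degree steps; recovery error is at most half a step |
| K-means `restarts` | 10 | — | three well-separated stain clusters rarely need more |
| K-means seed | 0 | — | reproducibility; exposed everywhere |

All are exposed as function arguments and CLI flags; none is hard-coded.

## The synthetic generator

No public histology accompanies this problem, so the package ships a
generator that emulates H&E dermis with per-pixel ground truth: a near-white
background, eosin-pink collagen bundles drawn as thick anti-aliased segments
whose axial angles follow a von Mises distribution on doubled angles
(the standard axial construction — `kappa` then directly controls the
expected directional variance; `kappa = 0` is isotropic), and
hematoxylin-purple ellipses for nuclei and appendages drawn on top. Ground
truth records the last-drawn class per pixel and the drawing angle; overlaps
resolve as "last drawn wins". Per-channel Gaussian noise (sd 4 on the 8-bit
scale) is added last. The three spec colors must be pairwise at least 15
units apart in (a\*, b\*), otherwise the color-segmentation problem the scene
is supposed to exercise is ill-posed and the spec is rejected.

The presets encode the tissue contrast:

* **normal** — fiber coverage target 50%, `kappa = 0`, nuclei plus large
  gland/follicle ellipses (15% of structures);
* **scar** — coverage target 90%, `kappa = 8`, mean direction 0 degrees
  (scar collagen bundles run parallel to the epidermis, horizontal in a
  conventionally oriented dermis section); appendages are absent but small
  nuclei persist throughout, as they do in real scar tissue, which remains
  cellular even though follicles and glands are destroyed;
* **mixed** — left half scar, right half normal, stitched.

Fiber counts derive from the coverage target via the Poisson-coverage
relation `n = -log(1 - coverage) * H * W / (length * width)`. Preset bundles
are 6 px wide with length 0.6 times the short image side: wide strokes keep
the anti-aliased pink/white transition zone a small minority of pixels, as it
is in real tissue where bundles are tens of pixels wide at typical scanning
resolution. (With unrealistically thin strokes the 1-px transition zone
rivals the nuclei in pixel count and forms its own chromaticity cluster —
a failure mode of the *scene*, not of the segmentation.) The retained nuclei
in the scar preset matter for the same reason: a three-cluster model needs
three populations, and scar tissue genuinely has them.

What the generator does **not** emulate: stain variability between slides,
uneven illumination, out-of-focus blur, curved or branching fibers, nuclear
texture, and tissue-edge artifacts. Passing the recovery tests therefore
shows the algorithms are correct on scenes satisfying their assumptions; it
does not certify performance on real slides, where stain normalization and
quality control remain the user's responsibility.

Dataset utilities round out the workflow: right-angle rotation augmentation
(lossless; 93 inputs with the default four angles give 372 outputs) and a
seeded train/validate/test split whose validate and test sizes are floors of
their fractions with the remainder to train — the only simple rounding rule
that sends 372 items at (0.64, 0.16, 0.20) to exactly 239/59/74.

## Statistics

Group comparisons follow the conventional reporting style: mean ± SD per
group, a two-sided pooled-variance Student's t-test for two groups (Welch
behind a flag) and one-way ANOVA for more; for two groups the two agree
exactly (`F = t^2`). Degenerate inputs have explicit conventions: identical
constant groups give `p = 1`, constant groups with different means raise an
error instead of fabricating an infinite statistic. No multiple-testing
correction is applied across the four metrics; with four correlated
percentages per ROI this is a deliberate, documented choice, and users
comparing many groups should adjust externally.

The percentage denominators are: FS% and CAS% over all ROI pixels; CDM% the
mean of the density map; DV% the mean over valid pixels only, with the valid
count reported alongside. An ROI with no valid DV pixel reports DV% as
undefined (`NA`), never as 0.

## Numerical and scale choices

Unit tests run on scenes of 60–160 px and the end-to-end checks use
250x250 to 750x500 ROIs with 10 replicates per group — sizes chosen so the
full suite completes in about a minute while every ROI still contains
hundreds of fibers and structures. The t-test calibration check uses 2000
null replicates at n = 10 per group. The acceptance script
(`scripts/acceptance.R`) re-runs all of these from scratch at the same sizes.

## Known limitations

* Orientation is estimated from the binary collagen mask, not grayscale
  intensity; in nearly saturated neighborhoods many probes tie and the
  smallest-angle rule wins, biasing dense isotropic regions toward 0
  degrees. The doubled-angle variance is robust to this in practice (scar
  DV still separates cleanly from normal), but per-pixel angles in dense
  regions should be read with care.
* K-means with `k = 3` on chromaticity assumes three color populations;
  heavily faded or single-stain slides violate this and the role rule will
  still produce three masks whose interpretation is then up to the user.
* JPEG input is rejected outright (lossy compression corrupts stain
  chromaticity); no reader override is provided.
* Physical units are not tracked; all lengths are pixels and scanner
  resolution metadata is ignored.
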