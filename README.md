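# fiberDV

Quantitative characterization of scar versus normal dermis in
hematoxylin-and-eosin (H&E) histology images.

Scar remodeling has three readable signatures on an H&E slide: skin
appendages (hair follicles, glands) vanish, collagen accumulates, and the
surviving collagen bundles align into parallel arrays. fiberDV measures all
three on any rectangular ROI:

1. **Color segmentation.** Pixels are mapped to CIE L\*a\*b\* and the
   (a\*, b\*) chromaticity is clustered with K-means (k = 3, k-means++,
   best of 10 restarts). Roles follow mean lightness: the brightest cluster
   is background (BS), the darkest is foreground (FS — nuclei, glands,
   follicles), the remainder is the collagen area (CAS).
2. **Collagen density map.** The binary CAS mask is convolved with an
   airy-disk kernel (weights ∝ [2·J₁(x)/x]², truncated at the first zero,
   unit sum), giving the local collagen fraction m ∈ [0, 1] per pixel.
3. **Fiber orientation.** Each collagen pixel's axial direction
   θ ∈ [0°, 180°) is the angle whose centered line probe passes through the
   most collagen-positive pixels (18 candidate angles, 10° steps, by
   default); isolated pixels have no orientation.
4. **Directional variance.** Doubled angles make axial data vector-summable:
   X = cos 2θ, Y = sin 2θ are convolved with the same kernel, R = √(X²+Y²)
   is the resultant magnitude, and

   V = 1 − R / m,  V ∈ [0, 1]

   is 0 for perfectly aligned fibers and 1 for isotropic (or exactly
   cancelling) orientations.

Per-ROI metrics are FS%, CAS%, CDM% (mean density × 100) and DV% (mean V
over valid pixels × 100), compared across groups with a pooled Student's
t-test (two groups) or one-way ANOVA (more), reported as mean ± SD.

Because no public imaging data accompanies this problem, the package also
ships a synthetic H&E dermis generator with per-pixel ground truth (class
labels and fiber angles), tissue presets (`normal`, `scar`, `mixed`),
lossless right-angle rotation augmentation and seeded train/validate/test
splitting — every stage of the pipeline is testable against known truth.

## Worked example

```r
library(fiberDV)

g   <- generate_image(preset("scar", seed = 42, height = 250, width = 250))
seg <- segment_tissue(g$image, seed = 0)
seg
#> <segmentation 250 x 250: CAS 80.4%, FS 2.1%, BS 17.5%>

kern  <- airy_kernel(16)
dens  <- collagen_density(seg$cas, kern)
field <- estimate_orientation(seg$cas)
vmap  <- directional_variance(field, kern)
summarize_roi(seg, dens, vmap, roi_id = "demo", group = "scar")
#>   roi_id group fs_pct cas_pct cdm_pct   dv_pct n_pixels n_valid_dv
#> 1   demo  scar 2.1216 80.3712 80.3712 17.19392    62500      62500
```

A scar ROI reads as dense (CAS ≈ CDM ≈ 80%), appendage-poor (FS ≈ 2%) and
aligned (DV ≈ 17%). The same pipeline on a `normal` preset ROI gives
CAS ≈ 39%, FS ≈ 11%, DV ≈ 35% — sparser, structure-rich, isotropic. With a
few replicate ROIs per group the contrast is formally testable:

```r
roi <- function(p, s)
  run_characterize(generate_image(preset(p, seed = s, height = 250, width = 250))$image,
                   tempdir(), group = p)$metrics
normal <- do.call(rbind, lapply(1:3, roi, p = "normal"))
scar   <- do.call(rbind, lapply(4:6, roi, p = "scar"))
compare_regions(list(normal = normal, scar = scar), "cdm_pct")
#> <student_t: normal 40.788 +/- 2.349; scar 83.566 +/- 1.584>
#>   statistic = -26.1482, p = 1.271e-05
```

`run_characterize()` writes all artifacts (CAS/FS/BS masks, overlay, float
TIFF density/orientation/variance maps with PNG renderings, metrics CSV and
a parameter manifest) to an output directory; `run_compare()` turns metric
CSVs into a comparison table and report. The same workflow is scriptable
from a shell via `inst/cli/fiberdv` with subcommands `generate`, `augment`,
`split`, `characterize` and `compare`.

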