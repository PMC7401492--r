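# ppcmv

Automated quantification of **parapapillary choroidal microvasculature
(PPCMv) density** from en face OCT angiography (OCT-A) choriocapillaris
images centered on the optic disc.

Deep peripapillary perfusion is of interest in optic neuropathies such as
glaucoma and NAION, but en face choriocapillaris slabs are contaminated by
two artifacts that defeat naive thresholding: dark shadows cast by the
large retinal vessels overhead, and the device-black optic disc marking.
`ppcmv` implements a three-stage pipeline for analysts working with
disc-centered 4.5 × 4.5 mm AngioVue-style en face exports:

1. **Shadow localization.** The image is histogram-equalized and low-pass
   filtered, then thresholded with a locally adaptive (Niblack-style) rule
   on local first-order statistics: pixel *p* is shadow iff
   *E(p) < μ_w(p) − k·σ_w(p)*. Small components are removed and the mask is
   dilated one pixel, giving the shadow mask *U*.
2. **Capillary segmentation.** A *modified Otsu* threshold is computed on
   the histogram of the original normalized image with the shadow and disc
   pixels expurgated, and the above-threshold class gives the capillary
   mask *C*.
3. **Density.** Inside each annular region of interest,

   density = 100 · |C ∩ ROI| / |ROI ∩ U<sup>c</sup>|,

   i.e. the capillary percentage of shadow-free (evaluable) pixels. The
   ROIs are two 0.5-mm annuli around the circle circumscribing the disc
   (circle diameters 1 mm and 2 mm greater than the disc circle) and their
   superior/inferior hemifields.

The package also provides Bland–Altman agreement analysis against manual
measurements (bias, 95% limits of agreement, proportional-bias slope,
paired bias t-test), a synthetic en face generator with pixel-level ground
truth, and a batch driver. See `vignette("ppcmv-methods")` for the model,
parameter rationale and limitations.

## Worked example

```r
library(ppcmv)

g <- synthEnface(syntheticConfig(seed = 42L))  # synthetic eye + ground truth
g$image
#> EnFaceImage: 304 x 304 px, 0.0148 mm/px (4.50 x 4.50 mm)
#>   intensity range [0.000, 1.000]

measureImage(g$image, imageId = "eye42")
#> DensityReport 'eye42' (disc radius 0.766 mm)
#>       roi_name density_pct capillary_px evaluable_px shadow_px total_roi_px
#>  inner_annulus    25.23620         3045        12066      2490        14556
#>      inner_sup    21.96503         1319         6005      1258         7263
#>      inner_inf    28.47715         1726         6061      1232         7293
#>  outer_annulus    26.22785         4395        16757      4969        21726
#>      outer_sup    24.44605         2030         8304      2554        10858
#>      outer_inf    27.97823         2365         8453      2415        10868
```

Each row is one region of interest. `density_pct` is the capillary share
of the `evaluable_px` (ROI pixels outside the shadow mask); `shadow_px`
were excluded from both numerator and denominator. For this eye the
generator's true inner/outer annulus densities are 26.7% and 25.6%, so the
automated measurement lands within ~1.5 percentage points. Real images are
read with `readEnface("scan.png", scanWidthMm = 4.5)`; directories are
batch-processed with `runMeasure()` or the script in `inst/scripts/`.

Agreement between two measurement methods:

```r
blandAltman(c(20.1, 24.3, 17.9, 26.8, 22.4),
            c(21.0, 25.1, 19.4, 27.2, 23.9))
#> BlandAltmanResult (n = 5): bias 1.020%, LoA [0.086, 1.954]%
#>   LoA CI half-width 0.723%, slope(diff ~ mean) -0.1048
```

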