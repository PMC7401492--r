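---
title: "Quantifying parapapillary choroidal microvasculature density"
author: "ppcmv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying parapapillary choroidal microvasculature density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppcmv)
```

## The measurement problem

En face OCT angiography of the choriocapillaris around the optic nerve
head shows the parapapillary choroidal microvasculature (PPCMv) as a
bright, fine-grained flow texture. Two artifacts stand between that
texture and a defensible density number. First, the large retinal vessels
overhead cast dark shadows into the deep slab; counted naively they
masquerade as avascular choroid and depress density in a way that depends
on the retinal — not choroidal — anatomy. Second, the device renders the
optic disc as a solid black region whose pixels carry no flow information
at all. `ppcmv` therefore measures density only on *evaluable* pixels:
inside annular regions of interest that exclude the disc by construction,
and outside a shadow mask that is removed from numerator and denominator
alike:

$$\mathrm{density} = 100\cdot\frac{|C \cap \mathrm{ROI}|}
{|\mathrm{ROI} \cap U^{c}|}$$

with $C$ the segmented capillary mask and $U$ the shadow mask. Because
exclusion removes capillary and background pixels in proportion, the
statistic is insensitive to *how much* shadow crosses an ROI — provided
$U$ is accurate (see Limitations).

## Pipeline and parameters

`measureImage()` chains the stages; every tunable lives in
`ppcmvConfig()` and each stage is exported for use on its own.

**Normalization** (`readEnface`). Intensities are min–max normalized to
$[0,1]$. A zero-dynamic-range raster (a blank or failed export) maps to
all-zero rather than erroring, and then simply yields an empty capillary
mask downstream. The physical scale is `scanWidthMm / width_px`; the scan
width defaults to the 4.5-mm disc-centered protocol but is an input, not a
constant, because the export's pixel dimensions vary between devices.

**Preprocessing for shadow localization** (`preprocessEnface`). Histogram
equalization (256 bins) followed by Gaussian low-pass filtering
(`lowpassSigmaPx = 2`, truncated at $4\sigma$, reflective boundaries so
the mean is conserved). Sigma 2 px at the 4.5-mm pitch (≈15 µm/px)
suppresses speckle at the capillary scale while leaving 60–200 µm shadow
structures intact. The preprocessed image feeds *only* the shadow stage:
equalization is a rank transform that would change the meaning of the
Otsu threshold, so capillary segmentation runs on the original normalized
image. This split is a deliberate design choice where the pipeline
description leaves the wiring open.

**Shadow localization** (`shadowMask`). A Niblack-style locally adaptive
rule on local first-order statistics over a `windowPx = 25` square
window: pixel $p$ is shadow iff $E(p) < \mu_w(p) - k\,\sigma_w(p)$
(strict, so ties and constant images produce an empty mask). Components
smaller than `minObjectPx = 50` px are removed — this is what restricts
the mask to *large* retinal-vessel shadows — and the survivors are
dilated by `dilatePx = 1` as a partial-volume margin. The cleanup order
(filter, then dilate) is fixed so dilation cannot rescue sub-threshold
specks.

The default `k = 0.9` deserves a note. Small offsets (e.g. $k \approx
0.2$, a common choice for document binarization where the objects
dominate every window) are unusable here: on any stationary background
texture the rule then flags the $\Phi(-k) \approx 42\%$ darkest of every
neighborhood, and that dark phase percolates into components far larger
than any size filter can remove. With shadows that are locally *sparse*,
$k$ must sit high enough that ordinary texture fluctuation rarely crosses
it, yet low enough that true shadow pixels — which drag the local mean
down and inflate the local spread — still do. On synthetic eyes with
known shadow masks, $k = 0.9$ balances the two failure modes (dark
background falsely excluded inflates density; missed shadow pixels
depress it) to a mean absolute annulus-density error of about 1% at the
default study conditions; the window, size and dilation defaults are kept
at 25 px / 50 px / 1 px.

**Disc geometry** (`detectDisc`, `buildRois`). The disc is the largest
near-black (`blackLevel = 0.02`) connected component of at least
`minDiscAreaMm2 = 0.8` mm² nearest the image center; the black level is
near zero because the marking is device-drawn, and the area gate rejects
specks (a typical disc exceeds 1 mm²). The inner circle is the *minimum
enclosing circle* of that component — circumscription taken literally,
guaranteeing the disc never leaks into the annuli — computed by Welzl's
algorithm on the component's convex hull. The two annuli span
$(r, r+0.5\,\mathrm{mm}]$ and $(r+0.5, r+1.0\,\mathrm{mm}]$ in
pixel-center distance with half-open boundaries, so every pixel belongs
to at most one ring and the disc interior to none. Hemifields are split
by the image-horizontal line through the disc center (no disc–fovea axis
rotation; rows on the line count as superior). Pixel coordinates are
0-based, row-major, origin top-left, geometry on pixel centers — fixed so
masks are bit-reproducible.

**Segmentation** (`modifiedOtsu`, `capillaryMask`). A 256-bin histogram
on $[0,1]$ is built from pixels outside $U \cup \mathrm{disc}$; the
threshold maximizes between-class variance over interior bin edges, ties
broken toward the lowest qualifying edge (deterministic, and the
sensitive direction for capillaries). The capillary class is the
*strictly above*-threshold class; excluded pixels are never capillary, so
$C \subseteq U^c$ by construction. One global threshold serves the whole
image — `checkThresholdTransfer()` exists to verify, advisorily, that the
threshold is comparable on macular scans from the same device. Fewer than
two distinct non-excluded values is a degenerate histogram and an
explicit error; at the density stage an ROI with no evaluable pixel
yields a *missing* value (never zero, which would read as total
dropout). Bright halo artifacts that flank some shadows are not removed;
they predominantly fall outside the outer circle.

**Agreement** (`blandAltman`, `pairedBiasTest`). Differences are
`automated − manual`; limits of agreement are
$\bar d \pm 1.96\,s_d$ with the sample standard deviation, each with the
classic $1.96\,s_d\sqrt{3/n}$ confidence half-width (exact-t variants
exist; the classic form is used). The oblique trend is the least-squares
slope of differences on pair means. Zero-variance differences are flagged
degenerate: $p = 1$ at zero bias by the no-signal convention, else the
smallest representable positive double.

## The synthetic generator

`synthEnface()` supplies the ground truth that real exports cannot: a
capillary mask defined by thresholding a Gaussian random field (blob
correlation length 1.5 px) at the quantile matching a prescribed fill
fraction, so the key recovered quantity is controlled exactly; branching
random-walk shadow trees radiating from the disc (8 vessels of 0.06–0.20
mm width, 80% attenuation, persistent courses covering ~13–20% of the
field); additive Gaussian noise (sd 0.04); a ±5% linear illumination
ramp; and the device-black disc (0.75 mm radius) overlaid last, after
noise — the marking is drawn by the device on the final export, and
detection of a "pure black" region is only meaningful if it stays pure.
True per-ROI densities are computed from the generator's own masks by the
same pixel counting as the pipeline, so oracle comparisons are exact
rather than model-based. The default fill fraction 0.25 puts true
inner-annulus densities near the ~25% scale reported for healthy eyes;
`synthCohort()` draws per-eye fills from a truncated normal profile.

What the generator does *not* emulate: physical OCT speckle statistics,
projection/halo artifacts around shadows, signal-strength variation,
motion artifacts, or real vascular branching geometry. Passing tests
therefore demonstrate the algorithm's internal correctness and its
recovery behavior under controlled artifacts — not clinical performance,
which in practice is established by Bland–Altman comparison against
manual labeling on real images (the workflow `runValidate()` implements).

## Verification approach and problem sizes

The test suite cross-checks every numerical kernel against an independent
brute-force oracle: the modified Otsu threshold against an exhaustive
between-class-variance scan (100 random 32 × 32 images with random
exclusions, bit-exact), local statistics against direct window summation,
Eq.-1 counting against explicit pixel loops (50 random mask triples),
annulus areas against $\pi(r_2^2 - r_1^2)$ at the 304-px scale (within
2%, with exact hemifield partitions), and end-to-end density recovery on
ten 304-px synthetic eyes per noise level (mean absolute error under 3%
at default noise, under 6% at doubled noise). Shadow-exclusion invariance
is tested by scrambling intensities under the shadow mask and asserting
bit-identical densities, and batch determinism by byte-comparing repeated
CSV runs. These sizes keep the whole suite under a few minutes on one
core while leaving the discretization and Monte Carlo slack small
relative to the asserted tolerances.

## Known limitations

* **Shadow-load saturation.** When shadows approach ~40% of an ROI, local
  windows are dominated by shadow, the local mean collapses toward the
  shadow level and the Niblack rule starts missing shadow pixels;
  measured density then drifts low even though the density *definition*
  is load-invariant (verified with ground-truth masks). At realistic
  coverage (≤ ~25%) the effect is within the stated tolerances.
* The hemifield axis is image-horizontal; no compensation for head tilt
  or disc–fovea axis.
* No automated image-quality gate: poor scans are the operator's call to
  exclude, and per-image failures in batch runs are logged and skipped.
* One global capillary threshold per image; no per-region adaptation.
* Bright shadow-flank halos are left in place (they rarely reach the
  outer circle) and no signal-strength compensation is applied.
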