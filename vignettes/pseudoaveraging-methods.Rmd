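---
title: "Pseudoaveraging of enface OCTA scans: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudoaveraging of enface OCTA scans: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

OCT angiography infers blood flow from decorrelation between repeated
scans of the same retinal location. Single acquisitions are fast but noisy;
registering and averaging N repeated acquisitions raises the
signal-to-noise ratio by roughly $\sqrt{N}$ at the cost of a much longer
imaging session. *Pseudoaveraging* replaces the repeated acquisitions with
a learned image-to-image model: a patch-based U-Net is trained to map a
single-frame enface scan to the appearance of its multi-frame average, so
a single acquisition can be enhanced after the fact.

The clinically critical failure modes of such a denoiser are
*false-negative perfusion* (real vasculature erased because the model took
low signal for noise, mimicking capillary dropout) and *false-positive
perfusion* (noise rendered as fictional vessels). The package therefore
pairs the denoiser with an objective safety evaluation against known
ground truth.

Because no clinical OCTA data are distributed with the package, a
synthetic-data module generates seeded retinal-vasculature phantoms whose
statistical structure mimics the relevant properties of enface OCTA:
branching vessels, a foveal avascular zone (FAZ) with a thin contour ring,
multiplicative speckle, an additive decorrelation background floor,
horizontal motion-line artifacts, shadow patches, microaneurysms and
capillary dropout. Everything downstream (registration, averaging,
training, inference, evaluation) operates on those phantoms, and every
quality claim is made against their exact truth records.

## The synthetic phantom

`generate_phantom()` builds a noiseless perfusion map in $[0,1]$:

* **Vessel trunks.** 3-5 branching random walks start at the image border
  and head toward the fovea; branch angles are jittered, widths decay by a
  factor 0.72 per generation and slowly along each walk, and walkers stop
  at the FAZ ring. Stamp intensity grows with width (0.6-0.9), so trunks
  are brighter than capillaries, giving the width/brightness hierarchy of
  real enface projections.
* **Capillary bed.** A Gaussian random field (FFT low-pass, 2.5 px
  correlation length), rank-uniformized and thresholded at 16 % area
  coverage, with intensities 0.42-0.60.
* **FAZ.** A capillary-free disk (radius about 8.5 % of the image side)
  with a 2 px contour ring at intensity 0.55; grading of FAZ *contour
  continuity* uses this ring.
* **Pathology knob.** `healthy` adds nothing; `npdr` adds 1-3 elliptical
  capillary-dropout regions and 3-8 microaneurysm dots; `pdr` adds 3-6
  dropouts, 8-15 microaneurysms and attenuates a ~30 degree arc of the FAZ
  ring below the vessel threshold.

The truth record is self-consistent by construction: `vessel_mask` is
exactly `perfusion >= 0.35` (one global constant, so masks are
unambiguous) and `background_mask` marks zero perfusion. Vessel coverage
outside the FAZ lands in the 15-45 % range typical of 6x6 mm enface
projections.

The noise model (`noise_params()`) is
`clip(perfusion * (1 + speckle) + background, 0, 1)` with
`speckle ~ N(0, 0.30)` and `background ~ N(0.12, 0.04)` by default,
followed by Poisson-count (rate 2) motion-line rows - each equiprobably
replaced by bright noise or shifted horizontally by up to 6 px - and, with
probability 0.3, one multiplicative shadow patch (attenuation 0.5,
40-80 px a side). The defaults were chosen once as a plausible mid-range
single-frame regime: background noise clearly visible (CNR of small
vessels around 5-8), motion lines in most but not all scans, shadows in
about a third. Real OCTA departs from this model in ways the phantoms do
not capture - speckle is spatially correlated and non-Gaussian, projection
artifacts from superficial vessels shade deeper slabs, and defocus/media
opacity vary smoothly rather than as a crisp box - so green tests here
demonstrate correctness of the pipeline under the stated model, not
clinical performance.

The simulated eye motion between repeated frames is rigid (translation
up to 5 px, rotation up to 1 degree by default), which matches the
package's rigid registration model; axial motion and intra-frame
distortions are out of scope.

## Registration and averaging

`estimate_transform()` recovers the rigid transform between two frames in
three stages: a coarse rotation search (0.5 degree grid) scored by the
Hann-windowed phase-correlation peak; sub-pixel translation at the best
rotation via a matrix-multiply upsampled DFT (1/50 px grid); and a final
Nelder-Mead refinement of the normalized cross-correlation between the
reference and the aligned frame. The phase-only first stage gives
robustness on vessel imagery, the correlation refinement gives the last
fraction of a pixel and of a degree. Parameter recovery on the synthetic
truth is bounded by 0.5 px and 0.2 degrees across a 100-pair sweep (shifts
up to 10 px, rotations up to 2 degrees, default noise). Degenerate
feature-free frames are flagged (`attr(est, "failed")`) and the averaging
falls back to the identity transform for them.

`average_frames()` picks the best frame by `quality_score()` (mean
gradient magnitude over a background-noise estimate - an objective proxy
for the subjective best-of-4 selection, documented as such), aligns every
other frame by the inverse estimated transform, and takes a count-weighted
per-pixel mean over the frames valid at each pixel, so the output keeps
the input shape without cropping and the divisor is at least 1 everywhere.
With zero inter-frame motion and pure additive noise the averaged
background standard deviation follows the $\sigma/\sqrt{N}$ law within
10 %.

## The denoiser

The model is a 5-level U-Net on 64x64 patches: two 3x3 convolutions per
level (ReLU), 2x2 max-pool downsampling, nearest-neighbour upsampling
followed by a 1x1 convolution, skip concatenation at every level, 16 base
channels doubling per level, and a 1x1 output head. Input sides must be
divisible by $2^{levels-1} = 16$. "5-layer" is read as five resolution
levels, the standard reading of U-Net depth; the alternative reading
(five convolutional layers) would not admit 64x64 patches with meaningful
downsampling.

Two deliberate departures from the plain architecture:

* **Global residual head.** The head's output is added to the input and
  clamped to `[0, 1]` (`residual_head = "linear"`; a `"logit"` variant,
  `sigmoid(logit(x) + g)`, is available), and the head is initialized near
  zero, so the untrained network is (within ~0.05) the identity map. The
  denoiser therefore learns a *correction* to the input. This was chosen
  for three reasons: plain SGD with an L1 cost converges far too slowly
  from a cold start at desk scale; the identity prior preserves scan
  brightness, which the clinical workflow otherwise restores by explicit
  brightness/contrast matching; and it biases the model against the
  over-denoising failure mode in which low-signal perfusion is erased.
  The linear form is the default because the sigmoid's Jacobian damps
  gradients on dark background pixels by roughly half relative to
  mid-intensity vessels, measurably slowing background-noise learning.
* **1x1 up-convolutions.** Any convolution after nearest-neighbour
  upsampling satisfies the architecture contract; 1x1 halves the training
  cost at these sizes and showed no quality difference.

Training (`fit_pseudoaverager()`) is plain SGD with momentum on a masked
L1 cost: the mean absolute deviation from the target over valid target
pixels only. Masking applies to the loss, never to the input. Residual
motion rows (plus a 1 px halo) and shadow boxes in averaged targets are
masked by `target_artifact_mask()`, playing the role of the manual masking
of artifact-affected target patches in the clinical workflow.

Two pair kinds feed the trainer:

* *single-to-average*: the averaging reference frame (already aligned)
  paired with its 4-frame average;
* *peer-to-peer*: the lowest-quality frame of an eye, registered to the
  highest-quality frame, paired with it (low in, high out). These pairs
  teach the model to raise low-signal but perfused regions rather than
  flatten them - the false-negative-perfusion safety ingredient. Each
  epoch mixes a freshly drawn peer-to-peer sample sized 25 % of the
  single-to-average count (1:4), a chosen default, configurable.

Defaults: learning rate 0.05, momentum 0.9, 20 epochs, batch 32,
augmentation off. Flip/rot90 augmentation (up to the 8 dihedral variants
per pair per epoch) is available but off by default at desk scale, where
the patch lattice already covers the training scans densely relative to
the model's task. The run is a pure function of (pairs, spec, config):
shuffling, sampling and initialization all derive from the config seed,
and the compiled kernels are single-threaded, so reruns are bit-identical.

Patch extraction follows a stride lattice with edge-snapped final
rows/columns (complete coverage). For 500x500 scans the default stride is
14, giving 32x32 = 1024 patches, about a thousand per scan; elsewhere the
default stride is a quarter patch. The default *training* configuration
uses stride 64 on 256x256 scans - 16 patches per eye - because with
sixteen synthetic training eyes a denser, heavily overlapping lattice
adds computation but little information; the stride is a plain argument
where denser sampling is wanted.

## Inference

`pseudoaverage()` (also `predict()` on the fitted model) tiles the scan
with 64 px tiles at stride 32, snapping edge tiles inside the frame so no
synthetic padding enters the network, and blends overlapping predictions
with a cosine-squared (Hann-squared) window evaluated at half-pixel
offsets (strictly positive, so single-coverage pixels reduce to that
tile's prediction exactly). Cosine-squared windows at half-tile stride sum
to a constant over the interior, removing tile seams; the test suite
checks that cross-boundary pixel differences are distributed like ordinary
neighbouring-pixel differences.

`match_brightness_contrast()` applies the affine intensity map that
restores the reference scan's mean and standard deviation (then clips):
brightness/contrast is a two-parameter notion, so moment matching rather
than histogram matching. It is idempotent up to clipping, and a
zero-variance output degenerates to a mean shift. It is applied per scan
and is off by default in evaluation, since matching the *noisy* original's
moments would reinflate the background noise that the evaluation
measures.

## Evaluation

Human masked grading is replaced by objective proxies with fixed,
configurable constants (`tau = 0.15` perfusion threshold,
`min_component_px = 20`; both invented, both exposed):

* **CNR**: (vessel mean - background mean) / background SD over the truth
  masks; offset-invariant; the proxy for "appearance of small vessels".
* **Background sigma**: SD over true background pixels. The background
  mask excludes a 2 px margin around every vessel: averaging (and a
  denoiser trained toward averages) slightly blurs vessel edges, and
  without the partial-volume margin the statistic measures that blur
  rather than noise - the standard practice of keeping background
  measurements clear of bright structures.
* **Motion index**: mean absolute difference between each annotated motion
  row and the mean of its nearest unannotated neighbours; 0 without
  annotations. Cohort motion-reduction percentages are computed only over
  scans with at least one annotated row, mirroring the
  reduced denominators of graded motion metrics.
* **FN/FP perfusion**: a true-vessel connected component (>= 20 px) whose
  mean output intensity falls below `tau` flags false-negative perfusion;
  a bright output component (> 1 - `tau`, >= 20 px) lying entirely inside
  true background flags false-positive perfusion. The component-size floor
  keeps single speckle grains out of both detectors.
* **FAZ contour continuity**: fraction of 36 ten-degree bins of the truth
  ring whose mean intensity exceeds `tau` (ten degrees is roughly the
  "clock hour or less" granularity clinicians use).

`rank_scans()` reproduces the ranking protocol (highest rank best,
average ranks on ties) and compares variants pairwise with a Wilcoxon
signed-rank test implemented in the package: zero differences dropped
(Wilcoxon's original treatment, needed because equal ranking is allowed),
tie-averaged ranks, an exact shift-algorithm null for up to 25 retained
pairs, a tie-corrected continuity-corrected normal approximation above,
`NA` below 5 pairs, and two-sided p-values by default. The implementation
is validated against full sign enumeration for n <= 10 and against
`stats::wilcox.test` where the latter is exact.

## Numerical choices and degenerate inputs

* Bilinear warping with an explicit validity mask; out-of-frame pixels are
  filled with 0 and excluded from averaging. The warp round-trip
  (t then t^-1) is accurate to 0.02 only for band-limited content;
  at hard vessel edges bilinear interpolation error is first-order in the
  step height, which is why the round-trip invariant is checked on a
  smoothed field.
* Phase correlation regularizes the cross-power spectrum with a small
  epsilon; constant images are flagged as failed registrations rather
  than producing spurious peaks.
* The network kernels run in single precision with denormals flushed to
  zero (the near-zero residual head otherwise produces denormal traffic
  whose hardware cost varies wildly between CPUs); all results are
  deterministic for a fixed seed.
* A constant image has quality score 0, CNR is `NA` on zero-variance
  background, and `masked_l1_loss()` rejects an all-false mask; training
  pairs whose validity mask is entirely false are dropped.
* Ties in reference-frame selection go to the lowest frame index.

## Problem sizes

The packaged study runs at desk scale, chosen once: 256x256 px phantoms
(6x6 mm field), 16 training eyes with 4-frame stacks, 4 held-out eyes
with averages, 50 single-frame test eyes, 20 epochs. At these sizes the
full simulate-register-train-evaluate cycle is a coffee-break computation
on one core. The clinical-scale counts (5 training / 34 validation / 105
test eyes, 500x500 scans, ~1000 patches per scan) remain available
through the same interfaces (`simulate_study()`, `patch_grid()` stride 14)
for anyone content to wait.

## Known limitations

* The phantom's speckle is pixel-independent Gaussian; real OCTA speckle
  is correlated and signal-dependent. Conclusions about absolute metric
  values do not transfer to clinical scans.
* Registration is rigid; torsional or intra-frame (rolling) motion is
  neither simulated nor corrected, and axial registration through retinal
  layers is out of scope in a 2-D enface package.
* The quality score is a proxy; it ranks speckle and defocus sensibly but
  is not validated against human graders.
* The FN/FP detectors depend on the stated `tau` and component-size
  constants; both are exposed and their monotone behaviour is tested, but
  no claim of clinical calibration is made.
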