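---
title: "Simulating fibre-bundle endomicroscopy and training desk-scale super-resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating fibre-bundle endomicroscopy and training desk-scale super-resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Probe-based confocal laser endomicroscopy (pCLE) images tissue through a
coherent bundle of a few tens of thousands of optical fibres. Each fibre
acts as a single-pixel detector, and the fibres sit on an irregular,
near-hexagonal grid, so the raw signal is a set of scattered samples that a
reconstruction step maps onto a Cartesian image. The result is noisy,
low-contrast and resolution-limited by the fibre spacing, not by the pixel
grid. Exemplar-based super-resolution (SR) networks could improve these
images, but they need aligned low-resolution/high-resolution (LR/HR)
training pairs, and no higher-resolution endomicroscope exists to provide
ground truth.

`pclesr` implements the synthetic-training strategy for this setting: a
physically motivated forward model of the fibre bundle turns any clean HR
frame into a realistic LR counterpart that is perfectly aligned with it by
construction. Trained on such pairs, a fully-convolutional network learns
the inverse mapping and can be applied full-frame at test time.

## The forward model

The simulator composes three stages, mirroring how the instrument forms an
image.

**Fibre lattice.** `generate_fibre_lattice()` builds a hexagonal lattice
whose pitch is chosen so a target number of fibres falls inside the
circular field of view (FoV), then displaces every site by an independent
uniform jitter of magnitude at most `jitter_frac` times the pitch
(default 0.25). Real bundles are hexagonally packed with manufacturing
irregularity; the jittered lattice reproduces the irregular Voronoi
structure of observed bundles while staying fully configurable. Because
hexagonal shells are discrete, the generator shrinks the pitch slightly
when needed and keeps exactly the requested number of sites nearest the
FoV center.

**Signal pooling.** Each fibre integrates light over its catchment area.
The default model averages the HR pixels in the fibre's Voronoi cell
(`extract_fibre_signals()`; the cell partition is computed exactly as a
nearest-fibre map with lowest-index tie-breaking). Two acquisition
variants are provided: the mean of the `k = 7` pixels nearest the fibre
core — the convention used by the standard reconstruction pipeline — and
exact bilinear point sampling at the core, which reproduces affine
intensity fields exactly and anchors the interpolation-exactness checks.
A Voronoi cell mean of an affine field equals the field at the cell
*centroid*, not at the fibre position, so only the point-sampling variant
can satisfy an exact-reproduction bound; this distinction is deliberate
and tested.

**Noise and reconstruction.** Clean per-fibre signals `fs` are corrupted
as

```
nfs = (1 + m) * fs + a,   m ~ N(0, 0.05^2),   a ~ N(0, (0.01 * range(fs))^2)
```

with independent per-fibre draws; the additive standard deviation scales
with the per-frame clean-signal range because the signals carry arbitrary
linear units. No clipping is applied — downstream per-frame
standardization makes the absolute range irrelevant, and clipping would
distort the Gaussian model. The noisy signals are then interpolated back
onto the pixel grid by barycentric (piecewise-linear) interpolation over
the Delaunay triangulation of the fibre positions, which is how clinical
reconstructions are produced. In-FoV pixels outside the convex hull (a
thin rim) take the nearest fibre's value, so the frame is defined over
the whole FoV; out-of-FoV pixels are zero. The LR frame keeps the HR
pixel grid: the resolution loss comes from fibre sampling, so the SR
problem is enhancement at scale factor 1.

Numerical choices worth knowing: Delaunay is computed by Bowyer–Watson
with a long-double in-circle predicate; positions are perturbed by a fixed
deterministic `1e-9 * pitch` displacement beforehand so exactly
co-circular configurations (e.g. an unjittered lattice) get a pinned,
reproducible triangulation. Pixels on a shared triangle edge belong to the
lowest-index simplex; the interpolated value is unchanged up to float
error. All coordinates are (row, col) with pixel centers at integer
positions, 1-based.

## Phantoms and datasets

Real training targets in this setting are video-registration mosaics
propagated back into frame space: high-SNR images with structures spanning
several fibre spacings plus fine cellular texture. `generate_phantom_hr()`
emulates them with anisotropic Gaussian blobs over a smooth background
plus a fine-grained texture field (smoothed white noise, sd 0.08,
correlation length 1.3 px). The default blob sizes (sd 3.5–9 px and
6–16 px for the two texture strata) span roughly half to twice the fibre
pitch of the default 600-fibre bundle, matching the physical situation
where fibre spacing is sub-cellular. Early in development we observed that
phantoms whose finest structures are *smaller* than a Voronoi cell invert
the expected contrast ordering between LR and HR after display
normalization; such a regime is physically backwards for pCLE and the
defaults avoid it.

The two texture strata act as synthetic tissue-type labels so the
stratified 70/15/15 split (`split_dataset()`, largest-remainder rounding
within each stratum) is exercised exactly as it would be on a two-organ
corpus. `build_dataset()` orchestrates lattice → phantoms → simulation →
split and writes 32-bit float TIFFs plus a JSON manifest; per-frame noise
streams are derived from the global seed and a frame id, so regeneration
is byte-identical and order-independent. Frames are affinely encoded to
`[0, 1]` for TIFF storage with the true range recorded in the manifest.

Preprocessing follows the two-step protocol: standardize both frames of a
pair by the LR frame's in-FoV mean and standard deviation, then rescale
each frame individually to `[0, 1]`. Per-frame (rather than corpus-level)
statistics are used; the composition is one affine map per frame.
Training patches are non-overlapping 64 × 64 tiles aligned to the FoV
bounding box; a tile is kept only if its in-FoV fraction reaches the
`coverage` threshold (default 1, i.e. fully inside the FoV).

## Quality metrics

`ssim()` uses the standard windowed definition (11 × 11 Gaussian window,
sigma 1.5, k1 = 0.01, k2 = 0.03, data range 1 after preprocessing) with
*valid* windows — no padding — and averages over window centers inside
the FoV mask by default (a full-frame variant is available via
`mask = NA`).

`gcf()` implements the reference-free global contrast factor: pixel
values are treated as display intensities, gamma-linearized (`l = v^2.2`),
block-averaged into superpixels of sizes 1–200, converted to perceptual
lightness `L = 100 * sqrt(l)`, and scored by the mean absolute lightness
difference to 4-neighbours, combined across resolutions with the published
weighting polynomial. Within the FoV, block averages use only in-mask
pixels; blocks with no mask pixel are dropped. Ragged edge blocks mean
exact flip-invariance holds only on grids all levels tile evenly; this is
inherent to block-averaged multi-resolution contrast.

`evaluate_method()` reports the six aggregate scores (mean/sd of
SSIM(SR, HR), ΔGCF(SR, LR), ΔGCF(SR, HR)) and `composite_score()` averages
min-max-normalized SSIM and ΔGCF(SR, LR) across the compared methods
(always including the LR identity baseline). A factor that is constant
across methods carries no ranking information and is set to the neutral
value 0.5. Evaluation expects display-range images and *clips*
out-of-range predictions to `[0, 1]` instead of re-stretching them: a
per-frame min-max stretch is collapsed by single overshoot pixels, which
network predictions routinely contain, and we found it degrades SSIM by
~0.08 on otherwise identical outputs. Paired two-sided t-tests on
per-image scores (`paired_ttest()`) quantify significance.

## The SR harness

Two desk-scale fully-convolutional architectures are provided at scale
factor 1. `fsrcnn_like` follows the sparse-coding design — 5 × 5 feature
extraction (56 channels), 1 × 1 shrinking to 12, four 3 × 3 mapping
layers, 1 × 1 expansion, 9 × 9 reconstruction — with the deconvolution
replaced by a stride-1 convolution since LR and HR share a grid
(~12.6k parameters). `edsr_like` is a residual network without batch
normalization: a 3 × 3 head, four conv-ReLU-conv residual blocks at width
32, and a zero-initialized 3 × 3 tail plus a global input skip, so the
untrained network is exactly the identity (~74.6k parameters). Zero-init
makes early training a gentle perturbation of the identity and stabilizes
the harness's property tests.

Training is stochastic and patch-based: minibatches of 54 patches (drawn
from a per-epoch shuffle), Adam with default learning rate `1e-4`, and
either L1 or the mixed objective
`alpha * (1 - SSIM) + (1 - alpha) * L1` with `alpha = 0.84`, the value
established in the restoration-loss literature (the SSIM term uses the
same windowed definition as the metric, with an analytic gradient
validated against finite differences). Validation loss is monitored every
`val_interval` steps and the best-on-validation weights are returned.
The conv engine runs in float32 with im2col + BLAS sgemm; training is
deterministic given the seeds on a fixed BLAS configuration. Inference is
a single full-frame pass (the networks are fully convolutional), with the
FoV mask propagated.

Classical baselines mirror the standard comparisons: unsharp masking
(`baseline_sharpen()`) and frequency-domain Wiener deconvolution with a
Gaussian PSF of sigma 2 and constant noise-to-signal ratio
(`baseline_wiener()`, reflect-padded to suppress wrap-around).

## Validation experiments and problem sizes

The package's acceptance suite runs entirely on one CPU; the problem
sizes below are the package's own desk-scale choices.

* **Noise-model recovery.** 100,000 clean signals uniform on [0.5, 1]
  are corrupted by the simulator at its defaults; regressing squared
  residuals on squared clean signals recovers `sigma_m` as the square
  root of the slope and the additive coefficient from the intercept.
  Because the squared residuals are heteroskedastic and dominated by the
  multiplicative term (clean signals never approach zero), a single
  draw's intercept has ~40% relative sampling error; the experiment
  therefore averages the regression coefficients over 100 independent
  replicates, which is unbiased and brings the error to a few percent.
* **Interpolation exactness.** A 300-fibre, zero-noise, point-sampled
  simulation of an affine intensity field reproduces the field at every
  in-hull pixel to 1e-6.
* **Geometry oracles.** Nearest-fibre maps match exhaustive per-pixel
  search on ten random lattices; every Delaunay simplex passes a
  brute-force empty-circumcircle test.
* **End-to-end training.** A 24-pair dataset at the default conditions
  (256 × 256 frames, 600 fibres, default noise) is built, and the
  width-32/4-block residual network is trained with SSIM+L1, minibatch
  54. To keep the check inside a CPU test budget we run a short schedule
  (a few hundred steps) with a proportionally raised learning rate of
  `1e-3` over three seeds, and require, for at least two of the three (the
  full protocol likewise tolerates one failing seed), that on the held-out
  split mean SSIM(SR, HR) exceeds mean SSIM(LR, HR), mean ΔGCF(SR, LR) is
  positive, and the composite score beats the LR baseline. Longer
  schedules at the default learning rate give larger margins; the short
  schedule demonstrates the direction, not a headline number.

## What passing these checks does and does not show

The phantom generator emulates the *statistics* that matter for the
forward model — structure scale relative to fibre pitch, fine texture,
high SNR, a circular FoV, two strata — but not the content of real
tissue: no motion or deformation between frames, no registration
artifacts (ghosting, seams) such as mosaicking-derived HR estimates
contain, no fibre cross-talk or per-fibre gain variation, and no
vignetting. Results on synthetic pairs therefore bound what the pipeline
can do under a perfectly specified forward model; they do not certify
performance on device-acquired frames, where the domain gap between
simulated and real LR images is the central question. The simulator's
noise sigmas (0.05, 0.01) were chosen to mimic device frames visually in
the original setting and are exposed as parameters rather than treated as
universal constants.

Known limitations: the Bowyer–Watson implementation is O(n²) and sized
for desk-scale lattices (hundreds to a few thousand fibres), not the tens
of thousands in clinical bundles; GCF's ragged-edge behaviour on
non-tiling grids is documented above; training runs in float32, so
bitwise reproducibility assumes a fixed BLAS; and the CLI covers the
common paths of the package API rather than every option.
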