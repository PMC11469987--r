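---
title: "CT-free attenuation-map synthesis for kidney SPECT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CT-free attenuation-map synthesis for kidney SPECT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Quantitative Tc-99m DTPA kidney SPECT needs attenuation correction (AC): a
voxel map of linear attenuation coefficients (the mu-map, cm^-1 at 140 keV)
that is conventionally derived from a co-acquired CT. The CT contributes most
of the study's radiation dose, so replacing it with a mu-map *synthesized
from the SPECT data themselves* removes the CT component entirely. `mugen`
implements that pipeline at desk scale: a digital kidney phantom and SPECT
simulator stand in for patient SPECT/CT, and the normalization, network,
loss family, artifact diagnostics, metrics, and renal quantification are
implemented as reusable, tested components.

## The phantom and simulator

`phantom_spec()` describes a body ellipsoid, two kidneys (parenchyma
ellipsoid with an embedded renal-pelvis sub-ellipsoid), a cylindrical spine
surrogate, and optional iodine contrast. Geometry defaults are fractions of
the field of view, so one family scales from the 64 x 128 x 128 study grid
(4.5 mm voxels) down to the 32^3 grids (9 mm voxels) used for fast
experiments. Default attenuation values: air 0, soft tissue 0.154 cm^-1
(water at 140 keV), bone 0.25 cm^-1. Contrast adds +0.10 cm^-1 in the
pelvis (strong, visually obvious) and +0.01 cm^-1 in the parenchyma
(subtle) — configuration values, not physics claims. Each kidney takes up
2.5% of injected activity by default (5% bilateral); 10% is spread
uniformly as tissue background; the pelvis is a signal void (urine without
functioning parenchyma).

`simulate_spect()` is an image-space forward model: activity is multiplied
by the angle-averaged attenuation factor `mean_angles exp(-integral mu dl)`
(rays in the transverse plane; axis-aligned angles use the exact line
integral of the voxelized field, oblique angles a half-voxel midpoint
rule), blurred with a Gaussian PSF (sigma 6 mm photopeak, 12 mm scatter
window), scaled to counts, and Poisson-sampled in image space. The scatter
window (115-125 keV) is a 0.3-fraction, doubly-blurred echo of the
photopeak (126-154 keV); window labels are metadata. This deliberately
replaces projection-domain OSEM reconstruction: it preserves the causal
link (SPECT signal -> attenuation structure) the network must learn while
remaining testable against closed forms. It does not emulate
collimator-detector response, energy spectra, or anthropomorphic anatomy,
so passing tests show the method works on this family, not that it meets
clinical performance on patients.

Default count scale is 2e6 counts per unit injected activity at the full
grid and 2e5 at 32^3, giving parenchymal peak counts of order 10^1-10^2 per
voxel over a near-zero background — the strongly right-skewed intensity
regime that motivates logarithmic normalization.

## Input normalization

Both schemes map a count volume onto [0, 1] with maximum exactly 1.
Maximum normalization divides by the volume maximum; with localized renal
signal this leaves ~99% of voxels far below 0.1 (sample skewness well
above 2). Logarithmic maximum normalization, `ln(1 + x) / ln(1 + max x)`,
was chosen as the concrete log-max form because it needs no offset to
handle zero-count voxels, is strictly monotone, concave (so it dominates
max normalization voxel-wise and lifts low-signal tissue), and reduces
skewness on this data family. Normalization is per volume per channel
(each channel uses its own maximum). Skewness is the population
Fisher-Pearson `g1 = m3 / m2^(3/2)`; at 10^6 voxels the small-sample
correction is irrelevant.

## The generator

`build_generator()` constructs a modified 3D U-Net: per encoder level two
3 x 3 x 3 convolutions, each followed by a normalization layer and ReLU,
then 2 x 2 x 2 max pooling; channel count doubles per level from
`base_filters` (64 in the full-scale configuration, 4 skip connections);
the decoder mirrors with skip concatenation. Two design axes are exposed
because they are the modifications under study:

* **Normalization layer** — instance normalization (per sample, per
  channel; eps 1e-5, learnable affine) or batch normalization (joint
  batch + spatial statistics with running means for inference).
* **Up-sampling** — nearest-neighbor interpolation followed by a stride-1
  convolution, or a learned stride-2 transpose convolution with kernel 3.
  Kernel size not divisible by stride gives output voxels unequal numbers
  of kernel taps by coordinate parity; that uneven overlap is exactly the
  checkerboard-artifact mechanism, so kernel 3 (not 2) is essential to
  reproduce the phenomenon.

Convolutions use edge-replication padding rather than zero padding: a
constant feature map then stays *exactly* constant through
conv/norm/ReLU/interpolation, which makes the checkerboard dichotomy sharp
(interpolation path scores an exact 0 on constant input) and avoids
fabricated dark borders on body-contour volumes. The output head is a
1 x 1 x 1 convolution with a ReLU (attenuation is physically
non-negative). A hard ReLU head has a failure mode worth knowing about:
if the pre-activation goes negative across a whole tissue region the
clamp blocks all gradient there, and because the all-zero prediction is
L1-stable the network can lock up permanently under unlucky
initialization seeds. The head's backward pass therefore leaks a 0.01
gradient through the clamped region (forward semantics unchanged), which
keeps the fast convergence of the hard clamp — air voxels pinned at
exactly zero contribute no gradient noise — while making the dead state
recoverable. A purely linear training head with inference-time clamping
(`linear_clamped`) is also available; it never locks up but converges
more slowly at small step budgets. Weights are He-normal, deterministic
per seed, with a +0.01 head bias. The forward
and backward passes are implemented directly over BLAS-backed im2col
kernels; gradients were verified against central finite differences at
1e-5 relative tolerance during development.

## Loss family

The training objective is `L1 + omega x GDL`. The gradient-difference loss
uses forward differences on the valid interior (no padding, so no
fabricated boundary gradients), with either the absolute-gradient
comparison `||D G| - |D Y||^p` or the signed comparison `|D G - D Y|^p`,
p in {1, 2}. All reductions are means over valid voxels and axes so omega
(studied values 1, 3, 5; default 3, p = 1, absolute mode — the
best-performing setting) is comparable across grid sizes. The squared
voxel-wise (L2) loss is intentionally absent from the family. The exact
signed-variant formula from the antecedent PET work is not available, so
the signed mode follows the standard form above; it is an interpretation,
flagged as such.

## Training

Defaults follow the full-scale protocol: 100 epochs, batch size 8, Adam
(0.9/0.999) at 1e-3 with exponential decay 0.96 per epoch
(`lr(epoch) = 1e-3 x 0.96^(epoch-1)`; per-step decay would be implausibly
fast), flip augmentation along each axis with probability 0.5 applied
identically to input and label. "Early stopping during the first 10
epochs" is ambiguous; it is implemented as early stopping *disabled* for a
10-epoch warm-up and patience-based (default 10) afterwards — the only
reading under which training can proceed toward 100 epochs. The best
validation weights are restored, and the whole pipeline is a deterministic
function of its seeds on one device.

The scaled-down experiment used by the tests and the acceptance script
trains a base-8, depth-2 generator on 40 phantom pairs at 32^3 for 15
epochs. At that dataset size the batch size is reduced to 1 so the number
of gradient updates per epoch (32) stays near the full-scale protocol's
(~100 steps/epoch on 800 cases); with batch 8 the run would make only 60
updates in total and stop far short of convergence. Held-out performance
of roughly R^2 > 0.9 and %NMAE < 5 against ground-truth mu-maps is
reached in about 5-10 minutes on one CPU.

## Metrics and the checkerboard index

R^2, MSE (cm^-2), and %NMAE (mean absolute error over the target's range,
x100) are computed over all voxels; %NMAE uses each case's own range, and
dataset-level results are reported as mean +/- SD across cases. Error maps
follow the ground-truth-minus-prediction sign convention.

Checkerboard artifacts are assessed visually in the source study; `mugen`
adds a quantitative index. For each axis the volume minus its local
3-voxel running mean along that axis is formed (so smooth anatomy
contributes nothing — a linear ramp has zero residual), the absolute
alternating-sign sum is taken per line, summed over lines, normalized by
the total absolute residual, and averaged over axes. A pure period-2
alternation scores 1; residuals below 1e-10 of the volume maximum are
zeroed so that volumes constant up to floating-point rounding score an
exact 0. The per-line aggregation (rather than one global alternating sum)
is deliberate: a global sum cancels across lines for the pure 3D pattern
`(-1)^(i+j+k)` and would score the strongest possible artifact as 0.

## Attenuation correction and quantification

`chang_correct()` applies the first-order multiplicative correction
(divide by the angle-averaged attenuation factor, floored at 1e-3 to bound
noise amplification); an optional dual-energy-window scatter subtraction
(`primary - k x scatter`, default k 0.5, floored at 0) can precede it.
Full iterative reconstruction is out of scope — the first-order correction
suffices to demonstrate the quantitative consequences of mu-map errors.

`percent_uptake()` is `100 x (corrected counts in the combined bilateral
parenchyma mask) / injected counts`; in the simulator, injected counts are
`count_scale x injected_total`, so recovery is exact in the
no-attenuation, noise-free limit up to PSF spill-out. The measurement mask
is therefore the parenchyma label dilated by `ceiling(psf_sigma / voxel)`
voxels, recapturing blur leakage the way clinical VOIs do; with that
procedure a configured 5% bilateral uptake is recovered within 0.5
percentage points. GFR uses the published affine calibration
`GFR = %uptake x 9.1462 + 23.0653` (mL/min), applied to the combined
bilateral uptake (the calibration's mapping per kidney is not
reconstructible from the available material; per-kidney numbers are an
optional breakdown only). Dose arithmetic: SPECT 0.0049 mSv/MBq, CT
`DLP x 15 uSv per mGy-cm / 1000`, reduction `ct / (spect + ct)`.

## Numerical choices and degenerate inputs

* All-zero volumes are rejected by both normalizations (explicit
  degenerate-input error), constant targets by R^2 and %NMAE, zero
  variance by `skewness()`.
* Attenuation factors are exactly 1 where all path integrals vanish;
  uniform-slab factors agree with `exp(-mu L)` to better than 1e-6
  relative (exactly, for axis-aligned rays).
* Ties in max pooling resolve to the first voxel in array order;
  `sign(0) = 0` is used as the L1/GDL subgradient at kinks.
* Volumes are float32 on disk (NIfTI), float64 in memory.
* The supplement-level acquisition parameters of the source protocol
  (matrix, zoom, OSEM iterations) are unavailable; the simulator's
  defaults are placeholders chosen once for plausibility and marked as
  configuration.

## Known limitations

Poisson noise is applied in image space, not projection space; scatter has
no energy dependence; anatomy is ellipsoidal. The synthetic family
therefore exercises the *mechanisms* (signal-to-attenuation inference,
normalization imbalance, checkerboard formation, contrast neutrality
logic) but none of the patient-data performance figures; the package makes
no claim that phantom metrics transfer to clinical data.
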