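# mugen

CT-free attenuation correction for quantitative kidney SPECT, at desk
scale. Quantitative Tc-99m DTPA SPECT needs a voxel map of linear
attenuation coefficients (a μ-map, cm⁻¹ at 140 keV) to correct the
emission data; clinically that map comes from a co-acquired CT, which
contributes most of the study's radiation dose. `mugen` implements a
pipeline that synthesizes the μ-map from the SPECT data themselves with a
modified 3D U-Net, so the CT can be dropped — together with everything
needed to study that idea end to end on synthetic data:

* a **digital kidney phantom** (body/kidney/pelvis/spine geometry, iodine
  contrast, configurable uptake) and an attenuated-emission **SPECT
  simulator** producing paired photopeak (126–154 keV) and scatter-window
  (115–125 keV) count volumes with Gaussian PSF and Poisson noise;
* **input normalization**: maximum and logarithmic-maximum
  (`ln(1+x)/ln(1+max x)`) schemes plus skewness diagnostics;
* a **modified 3D U-Net generator** (instance normalization,
  nearest-neighbor interpolation up-sampling vs. stride-2 transpose
  convolution), with forward and backward passes implemented over
  BLAS-backed im2col kernels — no external deep-learning framework;
* the **loss family** `L₁ + ω·L_GDL` (gradient-difference loss, absolute
  or signed comparison, p ∈ {1,2}, studied weights ω ∈ {1,3,5});
* **metrics**: voxel-wise R², MSE, %NMAE, error maps, and a quantitative
  **checkerboard-artifact index** for the transpose-convolution artifact;
* **Chang first-order attenuation correction** and dual-energy-window
  scatter subtraction;
* **renal quantification**: %uptake of injected activity, the GFR
  calibration `GFR (mL/min) = %uptake × 9.1462 + 23.0653`, and
  effective-dose / dose-reduction arithmetic.

## Worked example

Simulate a contrast-enhanced phantom study, correct it with its own
ground-truth μ-map, and quantify renal function:

```r
library(mugen)

spec <- phantom_spec(contrast = TRUE)     # 64 x 128 x 128, 4.5 mm voxels
ph   <- generate_phantom(spec)            # mu-map + activity + labels
pair <- simulate_spect(ph$activity, ph$mu, acq_settings(seed = 7))

skewness(max_normalize(pair$primary)$values)      # 11.146
skewness(log_max_normalize(pair$primary)$values)  #  5.337

corrected <- chang_correct(pair$primary, ph$mu)
mask <- ph$labels$values %in% c(2, 3)             # bilateral parenchyma
dim(mask) <- spec$grid_shape
mask <- dilate_mask(mask, 2)                      # recapture PSF spill-out
quantify_uptake(corrected, mask, pair$injected_counts)
#> Renal parenchymal uptake: 5.3943% of injected activity
#> GFR: 72.4023 mL/min  (masks: parenchyma_L+parenchyma_R)

dose_reduction(effective_dose_spect(370), effective_dose_ct(100))
#> Effective dose: SPECT 1.8130 mSv + CT 1.5000 mSv = 3.3130 mSv
#> Potential reduction from CT-free imaging: 45.3%
```

The skewness drop (11.1 → 5.3) is the reason the pipeline defaults to
log-max input normalization: renal counts are localized over a near-zero
background, and the concave map lifts the low-signal tissue the network
must learn the body outline from. The phantom is configured with 5%
bilateral parenchymal uptake; the quantified 5.39% reflects attenuation
correction plus background spill inside the widened mask.

Training a generator on a synthetic cohort:

```r
cases <- make_training_pairs(48, seed = 101)           # 32^3 phantoms
tr <- prepare_cases(cases[1:32],  "PS", "log_max")
va <- prepare_cases(cases[33:40], "PS", "log_max")
te <- prepare_cases(cases[41:48], "PS", "log_max")
gen <- build_generator(net_config(in_channels = 2, base_filters = 8,
                                  depth = 2), c(32, 32, 32), seed = 7)
fit <- train_generator(gen, tr, va,
                       train_control(epochs = 15, batch_size = 1, seed = 11))
colMeans(evaluate_cases(fit, te)[c("r_squared", "nmae_percent")])
#>    r_squared nmae_percent
#>    0.9490585    0.8371336
```

`predict(fit, newdata)`, `plot(fit)` (loss curves), `summary(fit)` and
`residuals(fit, cases)` behave as for other fitted-model objects. A
command-line wrapper (`exec/mugen`) exposes `simulate`, `train`,
`evaluate`, `ablate`, `correct`, `quantify`, and `dose` subcommands.

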