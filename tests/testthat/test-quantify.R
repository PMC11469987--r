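# Renal quantification and dosimetry arithmetic.

test_that("percent uptake follows its definition", {
  v <- array(0, c(4, 4, 4))
  m <- array(FALSE, c(4, 4, 4))
  m[2:3, 2:3, 2:3] <- TRUE
  v[m] <- 10
  expect_equal(percent_uptake(v, m, injected_counts = sum(v)), 100)
  expect_equal(percent_uptake(array(0, c(4, 4, 4)), m, 100), 0)
  expect_error(percent_uptake(v, array(FALSE, c(4, 4, 4)), 100), "empty")
  expect_error(percent_uptake(v, m, 0), "positive")
})

test_that("GFR conversion is the printed affine calibration", {
  expect_equal(gfr_from_uptake(0), 23.0653)
  expect_equal(gfr_from_uptake(10), 114.5273)
  u <- seq(0, 20, by = 2.5)
  expect_true(all(diff(gfr_from_uptake(u)) > 0))
  expect_error(gfr_from_uptake(-1), ">= 0")
  q <- quantify_uptake(array(1, c(2, 2, 2)), array(TRUE, c(2, 2, 2)), 16)
  expect_identical(q$gfr_ml_min, q$percent_uptake * 9.1462 + 23.0653)
})

test_that("effective doses and reduction reproduce the reported bounds", {
  expect_equal(effective_dose_spect(370), 1.813)
  expect_equal(effective_dose_ct(100), 1.5)
  expect_equal(effective_dose_ct(450), 6.75)
  lo <- dose_reduction(effective_dose_spect(370), effective_dose_ct(100))
  hi <- dose_reduction(effective_dose_spect(370), effective_dose_ct(450))
  expect_equal(lo$total_mSv, 3.313)
  expect_equal(hi$total_mSv, 8.563)
  expect_equal(round(100 * lo$reduction_fraction, 1), 45.3)
  expect_equal(round(100 * hi$reduction_fraction, 1), 78.8)
  # internal consistency for arbitrary inputs
  r <- dose_reduction(2.2, 0)
  expect_equal(r$reduction_fraction, 0)
  expect_equal(r$total_mSv, r$spect_mSv + r$ct_mSv)
  expect_error(dose_reduction(0, 0), "positive")
})

test_that("contrast-extreme GFR gap reproduces the printed arithmetic", {
  expect_equal(contrast_extreme_gfr_gap(0.4530, 1.0658, -0.4394, 0.9316),
               2.8898)
  expect_equal(contrast_extreme_gfr_gap(0.4530, 1.0658, 0, 0), 1.5188)
  expect_equal(contrast_extreme_gfr_gap(0, 0, 0, 0), 0)
})

test_that("Dubois BSA matches the formula and cohort means", {
  expect_equal(round(dubois_bsa(69.24, 166.08), 2), 1.77)
  expect_equal(dubois_bsa(100, 100), 0.007184 * 100^0.425 * 100^0.725)
  expect_gt(dubois_bsa(80, 170), dubois_bsa(70, 170))
  expect_gt(dubois_bsa(70, 180), dubois_bsa(70, 170))
  expect_error(dubois_bsa(-1, 170), "positive")
})

test_that("5% parenchymal uptake is recovered through the quantify path", {
  # noise-free, mu = 0: only PSF blur separates measured from configured
  sp <- phantom_spec()  # default two kidneys at 0.025 each
  ph <- generate_phantom(sp)
  mu0 <- mugen:::new_mu_map(array(0, sp$grid_shape), sp$voxel_size_mm,
                            "ground_truth")
  acq <- acq_settings(count_scale = 1e6, noise = FALSE)
  pr <- simulate_spect(ph$activity, mu0, acq)
  cor <- chang_correct(pr$primary, mu0)
  mask <- ph$labels$values %in% c(2, 3)
  dim(mask) <- sp$grid_shape
  mask <- dilate_mask(mask, ceiling(acq$psf_sigma_primary_mm /
                                      sp$voxel_size_mm))
  u <- percent_uptake(cor, mask, pr$injected_counts)
  expect_lt(abs(u - 5), 0.5)
})

test_that("synthetic maps without pelvis contrast sit between the extremes", {
  # matched phantoms: same geometry/activity, contrast on vs off; the
  # "AI-like" map keeps parenchymal contrast but a contrast-free pelvis
  base <- tiny_phantom(contrast = TRUE)
  ph_c <- generate_phantom(base)
  spec_nc <- phantom_spec(base$grid_shape, base$voxel_size_mm,
                          body = base$body, kidneys = base$kidneys,
                          contrast = FALSE)
  ph_nc <- generate_phantom(spec_nc)
  spec_syn <- phantom_spec(base$grid_shape, base$voxel_size_mm,
                           body = base$body, kidneys = base$kidneys,
                           contrast = TRUE, contrast_pelvis_mu = 0)
  ph_syn <- generate_phantom(spec_syn)

  acq <- acq_settings(count_scale = 1e6, noise = FALSE)
  pr <- simulate_spect(ph_c$activity, ph_c$mu, acq)
  mask <- ph_c$labels$values %in% c(2, 3)
  dim(mask) <- base$grid_shape
  mask <- dilate_mask(mask, 1)
  up <- vapply(list(ph_nc$mu, ph_syn$mu, ph_c$mu), function(m)
    percent_uptake(chang_correct(pr$primary, m), mask, pr$injected_counts),
    numeric(1))
  expect_true(up[1] <= up[2] && up[2] <= up[3])
  expect_lt(up[1], up[3])  # the ordering is strict end to end
})
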