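# Phantom generation, attenuation physics, and the SPECT simulator.

test_that("phantom generation is deterministic and assigns tissue correctly", {
  sp <- tiny_phantom()
  ph1 <- generate_phantom(sp)
  ph2 <- generate_phantom(sp)
  expect_identical(ph1$mu$values, ph2$mu$values)
  expect_identical(ph1$activity$values, ph2$activity$values)

  # air voxels carry exactly zero attenuation
  air <- ph1$labels$values == 0
  expect_true(any(air))
  expect_true(all(ph1$mu$values[air] == 0))
  # pelvis is an activity signal void; parenchyma dominates background
  pel <- ph1$labels$values %in% c(4, 5)
  par <- ph1$labels$values %in% c(2, 3)
  body <- ph1$labels$values %in% c(1, 6)
  expect_true(all(ph1$activity$values[pel] == 0))
  expect_true(min(ph1$activity$values[par]) >= max(ph1$activity$values[body]))
  expect_equal(sum(ph1$activity$values),
               0.025 * 2 + sp$background_activity_fraction)
})

test_that("soft-tissue mu default matches water attenuation at 140 keV", {
  # log-log interpolation of tabulated water mass attenuation
  # (0.1 MeV: 0.1707, 0.15 MeV: 0.1505 cm^2/g; density 1 g/cm^3)
  lm <- log(0.1505 / 0.1707) / log(0.15 / 0.1)
  mu_water_140 <- 0.1707 * (0.14 / 0.1)^lm  # ~0.1538 cm^-1
  sp <- tiny_phantom()
  expect_lt(abs(sp$mu_values[["soft_tissue"]] - mu_water_140) / mu_water_140,
            0.02)
})

test_that("degenerate and invalid phantom specs are rejected", {
  # no kidneys + no background -> all-zero activity
  sp <- phantom_spec(c(16, 16, 16), 18, kidneys = list(),
                     background_activity_fraction = 0)
  ph <- generate_phantom(sp)
  expect_true(all(ph$activity$values == 0))

  # overlapping kidneys
  base <- tiny_phantom()
  kid <- base$kidneys
  kid[[2]]$center <- kid[[1]]$center + c(0, 0, 1)
  kid[[2]]$pelvis$center <- kid[[1]]$pelvis$center
  expect_error(generate_phantom(
    phantom_spec(base$grid_shape, base$voxel_size_mm, kidneys = kid)),
    "overlap")

  # kidney pushed outside the body
  kid <- base$kidneys
  kid[[1]]$center[3] <- 140
  kid[[1]]$pelvis$center[3] <- 140
  expect_error(generate_phantom(
    phantom_spec(base$grid_shape, base$voxel_size_mm, kidneys = kid)),
    "outside the body")

  # uptake bookkeeping
  expect_error(phantom_spec(background_activity_fraction = 1.2), "in \\[0, 1\\)")
})

test_that("contrast raises pelvis mu above parenchyma by the increment gap", {
  ph <- generate_phantom(tiny_phantom(contrast = TRUE))
  pel <- ph$labels$values %in% c(4, 5)
  par <- ph$labels$values %in% c(2, 3)
  gap <- mean(ph$mu$values[pel]) - mean(ph$mu$values[par])
  expect_gte(gap, 0.10 - 0.01 - 1e-12)  # pelvis +0.10 vs parenchyma +0.01
})

test_that("attenuation factor matches closed forms and stays in (0, 1]", {
  # mu = 0 -> factor exactly 1
  mu0 <- mugen:::new_mu_map(array(0, c(8, 8, 8)), 10, "ground_truth")
  expect_true(all(attenuation_factor(mu0, c(0, 90)) == 1))

  # uniform slab, single ray: factor = exp(-mu L); 10 mm voxels
  mu <- mugen:::new_mu_map(array(0.154, c(6, 30, 6)), 10, "ground_truth")
  f <- attenuation_factor(mu, 0)
  for (j in c(1, 10, 20)) {
    L_cm <- (30 - 0.5 - (j - 1)) * 1.0
    expect_lt(abs(f[3, j, 3] - exp(-0.154 * L_cm)) / exp(-0.154 * L_cm), 1e-6)
  }
  # oblique angles stay within (0, 1]
  fo <- attenuation_factor(mu, c(37, 142.5))
  expect_true(all(fo > 0 & fo <= 1))

  # doubling mu never increases any factor
  set.seed(4)
  mur <- array(runif(16^3, 0, 0.3), c(16, 16, 16))
  f1 <- attenuation_factor(mugen:::new_mu_map(mur, 9, "ground_truth"), c(0, 90))
  f2 <- attenuation_factor(mugen:::new_mu_map(2 * mur, 9, "ground_truth"), c(0, 90))
  expect_true(all(f2 <= f1 + 1e-12))

  expect_error(attenuation_factor(mu, numeric(0)), "angle")
})

test_that("simulator conserves counts, responds to attenuation, reproduces", {
  sp <- tiny_phantom()
  ph <- generate_phantom(sp)

  # zero activity -> zero counts in both windows
  act0 <- structure(list(values = array(0, sp$grid_shape), injected_total = 1),
                    class = "activity_map")
  pr0 <- simulate_spect(act0, ph$mu, acq_settings())
  expect_true(all(pr0$primary == 0) && all(pr0$scatter == 0))

  # mu = 0, no noise: total expected primary counts = count_scale * sum(act)
  mu0 <- mugen:::new_mu_map(array(0, sp$grid_shape), sp$voxel_size_mm,
                            "ground_truth")
  acq <- acq_settings(count_scale = 1e5, noise = FALSE)
  pr <- simulate_spect(ph$activity, mu0, acq)
  expect_lt(abs(sum(pr$primary) - 1e5 * sum(ph$activity$values)) /
              (1e5 * sum(ph$activity$values)), 0.02)  # edge truncation only

  # raising mu strictly lowers expected counts in attenuated regions
  sp16 <- phantom_spec(c(16, 16, 16), 18)
  ph16 <- generate_phantom(sp16)
  prA <- simulate_spect(ph16$activity, ph16$mu, acq_settings(noise = FALSE))
  mu2 <- mugen:::new_mu_map(ph16$mu$values * 2, 18, "ground_truth")
  prB <- simulate_spect(ph16$activity, mu2, acq_settings(noise = FALSE))
  hot <- prA$primary > max(prA$primary) * 0.05
  expect_true(all(prB$primary[hot] < prA$primary[hot]))

  # determinism: same acquisition seed -> identical noise realization
  pr1 <- simulate_spect(ph$activity, ph$mu, acq_settings(seed = 9))
  pr2 <- simulate_spect(ph$activity, ph$mu, acq_settings(seed = 9))
  expect_identical(pr1$primary, pr2$primary)
  # integer counts, scatter below primary at default scatter fraction
  expect_true(all(pr1$primary == round(pr1$primary)))
  expect_lt(sum(pr1$scatter), sum(pr1$primary))
})

test_that("datasets split 8:1:1, track contrast, and reproduce byte-identically", {
  dir1 <- file.path(tempdir(), "ds1")
  dir2 <- file.path(tempdir(), "ds2")
  unlink(c(dir1, dir2), recursive = TRUE)
  acq <- acq_settings(count_scale = 2e5)
  m1 <- make_dataset(10, dir1, grid_shape = c(16, 16, 16), voxel_size_mm = 18,
                     acq = acq, seed = 5)
  expect_equal(unname(table(m1$split)[c("train", "validation", "test")]),
               c(8L, 1L, 1L), ignore_attr = TRUE)
  m2 <- make_dataset(10, dir2, grid_shape = c(16, 16, 16), voxel_size_mm = 18,
                     acq = acq, seed = 5)
  t1 <- readLines(file.path(dir1, "manifest.tsv"))
  t2 <- readLines(file.path(dir2, "manifest.tsv"))
  expect_identical(gsub(dir1, "", t1, fixed = TRUE),
                   gsub(dir2, "", t2, fixed = TRUE))

  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("contrast flags follow the requested proportion", {
  cases <- make_training_pairs(200, grid_shape = c(16L, 16L, 16L),
                               voxel_size_mm = 18, contrast_proportion = 0.5,
                               acq = acq_settings(count_scale = 1e4),
                               seed = 31)
  p_hat <- mean(vapply(cases, `[[`, logical(1), "contrast"))
  # binomial 99% interval around 0.5 at n = 200
  expect_lt(abs(p_hat - 0.5), 2.58 * sqrt(0.25 / 200))
})
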