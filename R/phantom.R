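# Digital kidney phantom and dual-window SPECT simulator.
#
# Geometry lives in millimetres relative to the volume centre; volumes are
# (axial z, coronal y, sagittal x) arrays. Tissue-class codes used in label
# maps: 0 air, 1 body soft tissue, 2/3 left/right parenchyma, 4/5 left/right
# renal pelvis, 6 bone.

LABEL_CODES <- c(air = 0L, body = 1L, parenchyma_L = 2L, parenchyma_R = 3L,
                 pelvis_L = 4L, pelvis_R = 5L, bone = 6L)

#' Parametric kidney phantom description
#'
#' Builds the geometric and physical description of a digital two-kidney
#' abdomen phantom. Default geometry is expressed as fractions of the field
#' of view so the same family scales across grid sizes; all stored values
#' are absolute millimetres. Attenuation defaults: air 0, soft tissue 0.154,
#' bone 0.25 cm^-1 at 140 keV; iodine contrast adds +0.10 cm^-1 in the renal
#' pelvis and +0.01 cm^-1 in the parenchyma when `contrast = TRUE`.
#'
#' @param grid_shape Integer triple (axial, coronal, sagittal voxels).
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param body List with `center` and `semi` (mm, z/y/x) for the body
#'   ellipsoid; computed from the FOV when `NULL`.
#' @param kidneys List of kidney descriptors (each with `center`, `semi`,
#'   `pelvis = list(center, semi)`, `uptake`); `NULL` for the two-kidney
#'   default, `list()` for no kidneys. `uptake` is the fraction of injected
#'   activity taken up by that kidney's parenchyma (default 0.025 each).
#' @param bone List with `center_yx` (mm) and `radius_mm` for the spine
#'   surrogate cylinder; computed from the FOV when `NULL`.
#' @param mu_values Named attenuation coefficients (cm^-1) for
#'   `air`, `soft_tissue`, `bone`.
#' @param contrast Logical; add iodine-contrast increments to the mu-map.
#' @param contrast_pelvis_mu,contrast_parenchyma_mu Contrast increments
#'   (cm^-1) for pelvis and parenchyma.
#' @param hotspot Optional `list(center, radius_mm, fraction)` small
#'   high-activity sphere (checkerboard stress tests).
#' @param background_activity_fraction Fraction of injected activity spread
#'   uniformly over non-renal body tissue, in [0, 1).
#' @param seed Integer recorded in the spec (geometry itself is seed-free;
#'   the seed feeds downstream noise only).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 128L, 128L),
                         voxel_size_mm = 4.5,
                         body = NULL, kidneys = NULL, bone = NULL,
                         mu_values = c(air = 0, soft_tissue = 0.154, bone = 0.25),
                         contrast = FALSE,
                         contrast_pelvis_mu = 0.10,
                         contrast_parenchyma_mu = 0.01,
                         hotspot = NULL,
                         background_activity_fraction = 0.10,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 4))
    stop_mugen("grid_shape must be three integers >= 4")
  if (voxel_size_mm <= 0) stop_mugen("voxel_size_mm must be positive")
  half <- grid_shape * voxel_size_mm / 2
  if (is.null(body))
    body <- list(center = c(0, 0, 0),
                 semi = c(0.92 * half[1], 0.42 * half[2], 0.58 * half[3]))
  if (is.null(kidneys)) {
    bs <- body$semi
    kid <- function(side) {  # side +1 = left (x > 0), -1 = right
      ctr <- c(0, 0.25 * bs[2], side * 0.55 * bs[3]) + body$center
      semi <- c(0.32 * bs[1], 0.25 * bs[2], 0.16 * bs[3])
      list(center = ctr, semi = semi,
           pelvis = list(center = ctr + c(0, 0, -side * 0.35 * semi[3]),
                         semi = 0.45 * semi),
           uptake = 0.025)
    }
    kidneys <- list(kid(+1), kid(-1))
  }
  if (is.null(bone))
    bone <- list(center_yx = c(body$center[2] + 0.55 * body$semi[2],
                               body$center[3]),
                 radius_mm = 0.09 * body$semi[3])
  spec <- structure(list(
    grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
    body = body, kidneys = kidneys, bone = bone,
    mu_values = mu_values, contrast = isTRUE(contrast),
    contrast_pelvis_mu = contrast_pelvis_mu,
    contrast_parenchyma_mu = contrast_parenchyma_mu,
    hotspot = hotspot,
    background_activity_fraction = background_activity_fraction,
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (any(spec$body$semi <= 0)) stop_mugen("body semi-axes must be positive")
  for (k in spec$kidneys) {
    if (any(k$semi <= 0) || any(k$pelvis$semi <= 0))
      stop_mugen("kidney/pelvis semi-axes must be positive")
    if (k$uptake < 0) stop_mugen("kidney uptake must be >= 0")
  }
  if (any(spec$mu_values < 0)) stop_mugen("mu values must be >= 0")
  bg <- spec$background_activity_fraction
  if (bg < 0 || bg >= 1)
    stop_mugen("background_activity_fraction must be in [0, 1)")
  tot <- bg + sum(vapply(spec$kidneys, `[[`, numeric(1), "uptake")) +
    if (!is.null(spec$hotspot)) spec$hotspot$fraction else 0
  if (tot > 1)
    stop_mugen("uptake fractions plus background exceed 1 (", round(tot, 3), ")")
  invisible(spec)
}

# voxel-centre coordinate grids in mm (relative to volume centre)
coord_grids <- function(grid_shape, voxel) {
  ax <- lapply(1:3, function(a)
    (seq_len(grid_shape[a]) - 0.5 - grid_shape[a] / 2) * voxel)
  d <- grid_shape
  list(z = array(ax[[1]], d),
       y = array(rep(ax[[2]], each = d[1]), d),
       x = array(rep(ax[[3]], each = d[1] * d[2]), d))
}

inside_ellipsoid <- function(g, center, semi) {
  ((g$z - center[1]) / semi[1])^2 + ((g$y - center[2]) / semi[2])^2 +
    ((g$x - center[3]) / semi[3])^2 <= 1
}

#' Generate a paired mu-map, activity map, and label map from a phantom spec
#'
#' Deterministic rasterization of the phantom geometry: the same spec always
#' yields the same volumes (seeds only affect downstream Poisson noise).
#' The mu-map assigns tissue attenuation by class (plus contrast increments
#' when flagged); activity is uptake-weighted in the parenchyma, uniform
#' background elsewhere inside the body, and exactly zero in air and in the
#' renal pelvis (urine space without functioning parenchyma).
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `mu` (class `mu_map`), `activity`
#'   (class `activity_map`, voxel values are fractions of injected activity,
#'   `injected_total = 1`), and `labels` (class `label_map`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  d <- spec$grid_shape
  g <- coord_grids(d, spec$voxel_size_mm)
  body <- inside_ellipsoid(g, spec$body$center, spec$body$semi)
  labels <- array(LABEL_CODES[["air"]], d)
  labels[body] <- LABEL_CODES[["body"]]
  bone_m <- body & ((g$y - spec$bone$center_yx[1])^2 +
                    (g$x - spec$bone$center_yx[2])^2 <= spec$bone$radius_mm^2)
  labels[bone_m] <- LABEL_CODES[["bone"]]

  nk <- length(spec$kidneys)
  if (nk > 2) stop_mugen("at most two kidneys are supported")
  par_masks <- list(); pel_masks <- list()
  if (nk >= 1) {
    kmask <- lapply(spec$kidneys, function(k)
      inside_ellipsoid(g, k$center, k$semi))
    if (nk == 2 && any(kmask[[1]] & kmask[[2]]))
      stop_mugen("left and right kidneys overlap")
    for (i in seq_len(nk)) {
      k <- spec$kidneys[[i]]
      if (any(kmask[[i]] & !body))
        stop_mugen("kidney ", i, " extends outside the body ellipsoid")
      pel <- inside_ellipsoid(g, k$pelvis$center, k$pelvis$semi)
      if (any(pel & !kmask[[i]]))
        stop_mugen("pelvis of kidney ", i, " extends outside its parenchyma")
      par <- kmask[[i]] & !pel
      if (!any(par)) stop_mugen("kidney ", i, " parenchyma mask is empty")
      par_masks[[i]] <- par; pel_masks[[i]] <- pel
      labels[par] <- LABEL_CODES[[paste0("parenchyma_", c("L", "R")[i])]]
      labels[pel] <- LABEL_CODES[[paste0("pelvis_", c("L", "R")[i])]]
    }
  }

  mu <- array(spec$mu_values[["air"]], d)
  mu[labels >= 1] <- spec$mu_values[["soft_tissue"]]
  mu[labels == LABEL_CODES[["bone"]]] <- spec$mu_values[["bone"]]
  if (spec$contrast) {
    for (i in seq_len(nk)) {
      mu[par_masks[[i]]] <- mu[par_masks[[i]]] + spec$contrast_parenchyma_mu
      mu[pel_masks[[i]]] <- mu[pel_masks[[i]]] + spec$contrast_pelvis_mu
    }
  }

  act <- array(0, d)
  for (i in seq_len(nk)) {
    n <- sum(par_masks[[i]])
    act[par_masks[[i]]] <- spec$kidneys[[i]]$uptake / n
  }
  bgm <- labels == LABEL_CODES[["body"]] | labels == LABEL_CODES[["bone"]]
  bgv <- 0
  if (spec$background_activity_fraction > 0 && any(bgm)) {
    bgv <- spec$background_activity_fraction / sum(bgm)
    act[bgm] <- bgv
  }
  if (nk > 0) {
    parv <- unlist(lapply(par_masks, function(m) act[m]))
    if (length(parv) && min(parv) < bgv)
      stop_mugen("parenchymal activity per voxel falls below background; ",
                 "reduce background_activity_fraction or raise uptake")
  }
  if (!is.null(spec$hotspot)) {
    hs <- spec$hotspot
    sph <- ((g$z - hs$center[1])^2 + (g$y - hs$center[2])^2 +
            (g$x - hs$center[3])^2) <= hs$radius_mm^2
    sph <- sph & body
    if (!any(sph)) stop_mugen("hotspot sphere contains no in-body voxels")
    act[sph] <- act[sph] + hs$fraction / sum(sph)
  }

  list(mu = new_mu_map(mu, spec$voxel_size_mm, "ground_truth"),
       activity = structure(list(values = act, injected_total = 1),
                            class = "activity_map"),
       labels = structure(list(values = labels, classes = LABEL_CODES),
                          class = "label_map"))
}

new_mu_map <- function(values, voxel_size_mm, provenance) {
  check_volume(values, "mu")
  if (any(values < 0)) stop_mugen("mu values must be >= 0")
  structure(list(values = values, voxel_size_mm = voxel_size_mm,
                 provenance = provenance), class = "mu_map")
}

#' Angle-averaged attenuation factor
#'
#' For each voxel, the mean over projection angles of `exp(-integral mu dl)`
#' along a parallel ray from the voxel centre to the grid boundary toward
#' each angle's detector. Rays travel in the transverse plane: angle 0
#' points along +y (anterior), 90 degrees along +x. Line integrals use the
#' midpoint rule with half-voxel steps and nearest-voxel sampling, which is
#' exact for uniform media.
#'
#' @param mu A `mu_map` or non-negative 3D array (cm^-1); arrays use
#'   `voxel_size_mm`.
#' @param angles_deg Numeric vector of projection angles in degrees
#'   (at least one).
#' @param voxel_size_mm Voxel size when `mu` is a bare array.
#' @return 3D array of factors in (0, 1]; exactly 1 where all path
#'   integrals vanish.
#' @export
attenuation_factor <- function(mu, angles_deg, voxel_size_mm = 4.5) {
  if (inherits(mu, "mu_map")) { voxel_size_mm <- mu$voxel_size_mm; mu <- mu$values }
  check_volume(mu, "mu")
  if (any(mu < 0)) stop_mugen("mu must be >= 0")
  if (length(angles_deg) < 1) stop_mugen("at least one projection angle is required")
  d <- dim(mu)
  out <- cpp_atten_factor(as.numeric(mu), d[1], d[2], d[3],
                          voxel_size_mm / 10, as.numeric(angles_deg))
  array(out, d)
}

#' Acquisition settings for the SPECT simulator
#'
#' @param angles Projection angles in degrees (transverse plane).
#' @param psf_sigma_primary_mm,psf_sigma_scatter_mm Gaussian PSF sigma for
#'   the photopeak (126-154 keV) and scatter (115-125 keV) windows; the
#'   scatter channel must be at least as blurred as the primary.
#' @param scatter_fraction Scatter-window count fraction in (0, 1).
#' @param count_scale Total simulated counts per unit injected activity.
#' @param seed Integer seed for Poisson noise.
#' @param noise Apply Poisson noise (`FALSE` returns expectations).
#' @return List of class `acq_settings`.
#' @export
acq_settings <- function(angles = c(0, 90, 180, 270),
                         psf_sigma_primary_mm = 6,
                         psf_sigma_scatter_mm = 12,
                         scatter_fraction = 0.3,
                         count_scale = 2e6, seed = 1L, noise = TRUE) {
  if (scatter_fraction <= 0 || scatter_fraction >= 1)
    stop_mugen("scatter_fraction must be in (0, 1)")
  if (psf_sigma_scatter_mm < psf_sigma_primary_mm)
    stop_mugen("scatter PSF must be at least as wide as the primary PSF")
  structure(list(angles = angles,
                 psf_sigma_primary_mm = psf_sigma_primary_mm,
                 psf_sigma_scatter_mm = psf_sigma_scatter_mm,
                 scatter_fraction = scatter_fraction,
                 count_scale = count_scale, seed = as.integer(seed),
                 noise = isTRUE(noise)), class = "acq_settings")
}

gauss_blur <- function(vol, sigma_vox) {
  d <- dim(vol)
  array(cpp_gauss_blur(as.numeric(vol), d[1], d[2], d[3],
                       sigma_vox, sigma_vox, sigma_vox), d)
}

#' Simulate dual-energy-window SPECT from an activity map and mu-map
#'
#' Image-space forward model: activity is attenuated by the angle-averaged
#' attenuation factor, blurred with a Gaussian PSF per window, scaled to
#' counts, and Poisson-sampled. The scatter window is a broader, scaled echo
#' of the primary window (`scatter_fraction` x wider blur).
#'
#' @param activity An `activity_map` (voxel fractions of injected activity).
#' @param mu A `mu_map`.
#' @param acq [acq_settings()].
#' @return Object of class `spect_pair` with `primary` and `scatter` count
#'   volumes (integer-valued when `acq$noise`), window labels, and the
#'   injected count total `count_scale * injected_total`.
#' @export
simulate_spect <- function(activity, mu, acq = acq_settings()) {
  stopifnot(inherits(activity, "activity_map"), inherits(mu, "mu_map"))
  check_volume(activity$values, "activity")
  check_same_shape(activity$values, mu$values, c("activity", "mu"))
  if (any(activity$values < 0)) stop_mugen("activity must be >= 0")
  att <- attenuation_factor(mu, acq$angles)
  src <- activity$values * att
  vox <- mu$voxel_size_mm
  pm <- acq$count_scale * gauss_blur(src, acq$psf_sigma_primary_mm / vox)
  sm <- acq$scatter_fraction * acq$count_scale *
    gauss_blur(src, acq$psf_sigma_scatter_mm / vox)
  if (acq$noise) {
    set.seed(acq$seed)
    d <- dim(pm)
    pm <- array(rpois(length(pm), pm), d)
    sm <- array(rpois(length(sm), sm), d)
  }
  structure(list(primary = pm, scatter = sm,
                 windows = c(primary = "126-154 keV", scatter = "115-125 keV"),
                 voxel_size_mm = vox,
                 injected_counts = acq$count_scale * activity$injected_total),
            class = "spect_pair")
}

# draw one randomized case spec from the phantom family (consumes RNG state)
sample_phantom_spec <- function(grid_shape, voxel_size_mm, contrast,
                                ranges = list()) {
  rg <- modifyList(list(body_scale = c(0.9, 1.1),
                        kidney_scale = c(0.85, 1.15),
                        uptake = c(0.015, 0.035),
                        bg = c(0.05, 0.15),
                        shift_frac = 0.05), ranges)
  base <- phantom_spec(grid_shape, voxel_size_mm)
  body <- base$body
  body$semi <- body$semi * runif(1, rg$body_scale[1], rg$body_scale[2])
  half <- grid_shape * voxel_size_mm / 2
  kidneys <- lapply(base$kidneys, function(k) {
    s <- runif(1, rg$kidney_scale[1], rg$kidney_scale[2])
    shift <- runif(3, -1, 1) * rg$shift_frac * k$semi
    k$semi <- k$semi * s
    k$center <- k$center + shift
    k$pelvis$semi <- k$pelvis$semi * s
    k$pelvis$center <- k$pelvis$center + shift
    k$uptake <- runif(1, rg$uptake[1], rg$uptake[2])
    k
  })
  phantom_spec(grid_shape, voxel_size_mm, body = body, kidneys = kidneys,
               mu_values = base$mu_values, contrast = contrast,
               background_activity_fraction = runif(1, rg$bg[1], rg$bg[2]))
}

#' Generate a synthetic paired dataset on disk
#'
#' Samples randomized phantoms from the study family, simulates dual-window
#' SPECT, writes all volumes as NIfTI, and returns (and writes) a
#' tab-separated manifest with columns case_id, split, contrast,
#' path_primary, path_scatter, path_mu, path_labels. Cases are allocated to
#' train/validation/test splits by largest remainder, so counts differ from
#' the exact ratio by less than one case.
#'
#' @param n_cases Number of cases (>= 3).
#' @param out_dir Output directory (created if needed).
#' @param grid_shape,voxel_size_mm Grid geometry.
#' @param contrast_proportion Probability that a case carries iodine
#'   contrast (study value 0.54).
#' @param split Ratio triple for train/validation/test (sums to 1).
#' @param ranges Optional overrides for the per-parameter sampling ranges.
#' @param acq [acq_settings()] template (per-case seeds are derived).
#' @param seed Master seed; the same seed reproduces the dataset exactly.
#' @return Manifest data.frame, invisibly.
#' @export
make_dataset <- function(n_cases, out_dir,
                         grid_shape = c(64L, 128L, 128L), voxel_size_mm = 4.5,
                         contrast_proportion = 0.54,
                         split = c(0.8, 0.1, 0.1),
                         ranges = list(), acq = acq_settings(), seed = 1L) {
  if (n_cases < 3) stop_mugen("n_cases must be >= 3")
  if (abs(sum(split) - 1) > 1e-8) stop_mugen("split must sum to 1")
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0)
    stop_mugen("output directory is not writable: ", out_dir)
  counts <- floor(n_cases * split)
  rem <- n_cases - sum(counts)
  if (rem > 0) {
    frac <- n_cases * split - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  splits <- rep(c("train", "validation", "test"), counts)
  set.seed(seed)
  rows <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    contrast <- runif(1) < contrast_proportion
    spec <- sample_phantom_spec(grid_shape, voxel_size_mm, contrast, ranges)
    ph <- generate_phantom(spec)
    acq_i <- acq
    acq_i$seed <- sample.int(.Machine$integer.max, 1)
    pair <- simulate_spect(ph$activity, ph$mu, acq_i)
    id <- sprintf("case_%04d", i)
    paths <- file.path(out_dir, paste0(id, "_", c("primary", "scatter",
                                                  "mu", "labels"), ".nii.gz"))
    write_volume(pair$primary, voxel_size_mm, paths[1])
    write_volume(pair$scatter, voxel_size_mm, paths[2])
    write_volume(ph$mu$values, voxel_size_mm, paths[3])
    write_volume(ph$labels$values, voxel_size_mm, paths[4])
    rows[[i]] <- data.frame(case_id = id, split = splits[i],
                            contrast = as.integer(contrast),
                            path_primary = paths[1], path_scatter = paths[2],
                            path_mu = paths[3], path_labels = paths[4],
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Generate in-memory training cases from the phantom family
#'
#' Convenience wrapper used for desk-scale experiments and tests: samples
#' randomized phantoms, simulates SPECT, and returns raw cases that can be
#' normalized and assembled with [prepare_cases()].
#'
#' @inheritParams make_dataset
#' @param n Number of cases.
#' @param acq [acq_settings()] template; per-case Poisson seeds are derived
#'   from `seed`.
#' @return List of cases, each `list(pair, mu, labels, contrast)`.
#' @export
make_training_pairs <- function(n, grid_shape = c(32L, 32L, 32L),
                                voxel_size_mm = 9,
                                contrast_proportion = 0.54,
                                ranges = list(),
                                acq = acq_settings(count_scale = 2e5),
                                seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    contrast <- runif(1) < contrast_proportion
    spec <- sample_phantom_spec(grid_shape, voxel_size_mm, contrast, ranges)
    ph <- generate_phantom(spec)
    acq_i <- acq
    acq_i$seed <- sample.int(.Machine$integer.max, 1)
    pair <- simulate_spect(ph$activity, ph$mu, acq_i)
    list(pair = pair, mu = ph$mu, labels = ph$labels, contrast = contrast)
  })
}
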