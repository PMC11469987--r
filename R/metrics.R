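# Voxel-wise evaluation of synthetic mu-maps and a checkerboard-artifact
# index. Metrics follow the standard whole-volume definitions: R^2 against
# the grand mean of the target, MSE in cm^-2, and %NMAE normalized by the
# target's intensity range.

#' Voxel-wise R squared
#'
#' `1 - SS_res / SS_tot` over all voxels, with the target's grand mean as
#' the reference.
#'
#' @param G,Y Same-shape arrays or `mu_map`s (prediction, ground truth).
#' @return Scalar (<= 1, can be negative).
#' @export
r_squared <- function(G, Y) {
  G <- vol_values(G); Y <- vol_values(Y)
  check_same_shape(G, Y)
  ss_tot <- sum((Y - mean(Y))^2)
  if (ss_tot == 0) stop_mugen("R^2 undefined for a constant target")
  1 - sum((G - Y)^2) / ss_tot
}

#' Mean squared error
#'
#' @inheritParams r_squared
#' @return Mean squared voxel difference (cm^-2 for mu-maps).
#' @export
mse <- function(G, Y) {
  G <- vol_values(G); Y <- vol_values(Y)
  check_same_shape(G, Y)
  mean((G - Y)^2)
}

#' Percent normalized mean absolute error
#'
#' Mean absolute voxel difference divided by the target's intensity range,
#' times 100.
#'
#' @inheritParams r_squared
#' @return Scalar percentage.
#' @export
nmae_percent <- function(G, Y) {
  G <- vol_values(G); Y <- vol_values(Y)
  check_same_shape(G, Y)
  rng <- max(Y) - min(Y)
  if (rng <= 0) stop_mugen("%NMAE undefined for a constant target")
  100 * mean(abs(G - Y)) / rng
}

#' Signed error map (ground truth minus prediction)
#'
#' @inheritParams r_squared
#' @return 3D array `Y - G`.
#' @export
error_map <- function(G, Y) {
  G <- vol_values(G); Y <- vol_values(Y)
  check_same_shape(G, Y)
  Y - G
}

#' Checkerboard-artifact index
#'
#' Quantifies period-2 alternation, the signature of uneven kernel overlap
#' in strided transpose convolutions. For each axis the volume's local
#' 3-voxel running mean along that axis is removed; the index is the sum
#' over lines of the absolute alternating-sign sum of the residual,
#' normalized by the total absolute residual, averaged over the three axes.
#' Smooth volumes (where the residual vanishes) score 0; a pure period-2
#' alternation `V = (-1)^(i+j+k)` scores 1. Residuals below
#' `1e-10 * max|V|` are treated as exact zeros so that volumes constant up
#' to floating-point rounding score exactly 0.
#'
#' @param vol 3D array (each dim >= 3).
#' @param mask Optional logical mask restricting the evaluation.
#' @return Non-negative scalar in \[0, 1\].
#' @export
checkerboard_index <- function(vol, mask = NULL) {
  vol <- vol_values(vol)
  check_volume(vol, "vol")
  d <- dim(vol)
  if (any(d < 3)) stop_mugen("each dim must be >= 3 for the checkerboard index")
  if (!is.null(mask) && !identical(dim(mask), d))
    stop_mugen("mask shape mismatch")
  tol <- 1e-10 * max(abs(vol), 0)
  per_axis <- vapply(1:3, function(a) {
    n <- d[a]
    sl <- function(r) switch(a,
      vol[r, , , drop = FALSE], vol[, r, , drop = FALSE],
      vol[, , r, drop = FALSE])
    interior <- 2:(n - 1)
    resid <- sl(interior) -
      (sl(1:(n - 2)) + sl(interior) + sl(3:n)) / 3
    resid[abs(resid) < tol] <- 0
    if (!is.null(mask)) {
      mm <- switch(a, mask[interior, , , drop = FALSE],
                   mask[, interior, , drop = FALSE],
                   mask[, , interior, drop = FALSE])
      resid[!mm] <- 0
    }
    den <- sum(abs(resid))
    if (den == 0) return(0)
    signs <- (-1)^interior
    alt <- switch(a,
      resid * signs,
      sweep(resid, 2, signs, `*`),
      sweep(resid, 3, signs, `*`))
    num <- sum(abs(apply(alt, setdiff(1:3, a), sum)))
    num / den
  }, numeric(1))
  mean(per_axis)
}

#' Per-case metrics report
#'
#' @inheritParams r_squared
#' @param mask Optional region restriction for the checkerboard index.
#' @return One-row data.frame with `r_squared`, `mse`, `nmae_percent`,
#'   `checkerboard_index`, `n_voxels`.
#' @export
metrics_report <- function(G, Y, mask = NULL) {
  Gv <- vol_values(G)
  data.frame(r_squared = r_squared(G, Y), mse = mse(G, Y),
             nmae_percent = nmae_percent(G, Y),
             checkerboard_index = checkerboard_index(Gv, mask),
             n_voxels = length(Gv))
}

#' Aggregate per-case metric reports as mean and SD
#'
#' @param reports data.frame of per-case reports (rows from
#'   [metrics_report()]).
#' @return One-row data.frame of `<metric>_mean` / `<metric>_sd` columns.
#' @export
aggregate_metrics <- function(reports) {
  cols <- c("r_squared", "mse", "nmae_percent", "checkerboard_index")
  out <- lapply(cols, function(cn)
    c(mean = mean(reports[[cn]]), sd = stats::sd(reports[[cn]])))
  res <- as.data.frame(as.list(unlist(out)))
  names(res) <- as.vector(t(outer(cols, c("mean", "sd"), paste, sep = "_")))
  res$n_cases <- nrow(reports)
  res
}
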