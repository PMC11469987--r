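# Training objective family: L(G, Y) = L1(G, Y) + omega * L_GDL(G, Y).
#
# The gradient-difference loss (GDL) penalizes the mismatch between spatial
# forward-difference gradients of prediction and target along each of the
# three axes. "abs_of_gradients" compares gradient magnitudes
# (||D G| - |D Y||^p); "signed" compares the signed gradients
# (|D G - D Y|^p). All reductions are means over valid voxels and axes so
# the weighting factor omega is comparable across grid sizes. The squared
# voxel-wise (L2) loss is deliberately not part of the family.

#' Loss configuration
#'
#' @param omega Non-negative weighting factor for the GDL term (studied
#'   values 1, 3, 5; best-performing setting 3).
#' @param gdl_power GDL exponent p, 1 (absolute) or 2 (squared).
#' @param gdl_mode `"abs_of_gradients"` (compare gradient magnitudes,
#'   best-performing) or `"signed"` (compare signed gradients).
#' @param use_l1 Include the L1 term (kept for ablations).
#' @return Object of class `loss_config`.
#' @export
loss_config <- function(omega = 3, gdl_power = 1,
                        gdl_mode = c("abs_of_gradients", "signed"),
                        use_l1 = TRUE) {
  gdl_mode <- match.arg(gdl_mode)
  if (omega < 0) stop_mugen("omega must be >= 0")
  if (!gdl_power %in% c(1, 2)) stop_mugen("gdl_power must be 1 or 2")
  structure(list(omega = omega, gdl_power = gdl_power, gdl_mode = gdl_mode,
                 use_l1 = isTRUE(use_l1)), class = "loss_config")
}

#' Mean absolute (L1) loss
#'
#' @param G,Y Same-shape numeric arrays (prediction, target).
#' @return Mean over all voxels of `|G - Y|`.
#' @export
loss_l1 <- function(G, Y) {
  G <- vol_values(G); Y <- vol_values(Y)
  check_same_shape(G, Y)
  mean(abs(G - Y))
}

# forward difference along axis a (first 3 dims), length n-1 slab
fwd_diff <- function(v, a) {
  n <- dim(v)[a]
  idx <- function(r) switch(a,
    v[r, , , drop = FALSE], v[, r, , drop = FALSE], v[, , r, drop = FALSE])
  idx(2:n) - idx(1:(n - 1))
}

#' Gradient-difference loss
#'
#' @inheritParams loss_l1
#' @param p Exponent, 1 or 2.
#' @param mode `"abs_of_gradients"` or `"signed"`.
#' @return Mean over the three axes of the mean over valid voxels of the
#'   chosen gradient penalty.
#' @export
loss_gdl <- function(G, Y, p = 1, mode = c("abs_of_gradients", "signed")) {
  mode <- match.arg(mode)
  G <- vol_values(G); Y <- vol_values(Y)
  check_same_shape(G, Y)
  if (any(dim(G) < 2)) stop_mugen("each spatial dim must be >= 2 for GDL")
  if (!p %in% c(1, 2)) stop_mugen("p must be 1 or 2")
  per_axis <- vapply(1:3, function(a) {
    dg <- fwd_diff(G, a); dy <- fwd_diff(Y, a)
    r <- if (mode == "abs_of_gradients") abs(dg) - abs(dy) else dg - dy
    mean(abs(r)^p)
  }, numeric(1))
  mean(per_axis)
}

#' Combined training loss
#'
#' `L1 + omega * GDL` with the configuration's exponent and mode.
#'
#' @inheritParams loss_l1
#' @param cfg A [loss_config()].
#' @return Scalar loss.
#' @export
loss_total <- function(G, Y, cfg = loss_config()) {
  l <- if (cfg$use_l1) loss_l1(G, Y) else 0
  if (cfg$omega > 0)
    l <- l + cfg$omega * loss_gdl(G, Y, cfg$gdl_power, cfg$gdl_mode)
  l
}

# gradient of loss_total with respect to G (same shape as G); subgradient
# sign(0) = 0 at kinks
loss_total_grad <- function(G, Y, cfg = loss_config()) {
  check_same_shape(G, Y)
  d <- dim(G)
  grad <- if (cfg$use_l1) sign(G - Y) / length(G) else array(0, d)
  if (cfg$omega > 0) {
    for (a in 1:3) {
      dg <- fwd_diff(G, a); dy <- fwd_diff(Y, a)
      r <- if (cfg$gdl_mode == "abs_of_gradients") abs(dg) - abs(dy) else dg - dy
      # d/d(dg) of mean(|r|^p) over this axis, averaged over 3 axes
      dr <- if (cfg$gdl_power == 1) sign(r) else 2 * r
      dd <- dr / (length(r) * 3)
      if (cfg$gdl_mode == "abs_of_gradients") dd <- dd * sign(dg)
      dd <- cfg$omega * dd
      # scatter d/dG: dg[i] = G[i+1] - G[i]
      n <- d[a]
      add <- function(idx, val) {
        switch(a,
               grad[idx, , ] <<- grad[idx, , ] + val,
               grad[, idx, ] <<- grad[, idx, ] + val,
               grad[, , idx] <<- grad[, , idx] + val)
      }
      add(2:n, dd)
      add(1:(n - 1), -dd)
    }
  }
  grad
}
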