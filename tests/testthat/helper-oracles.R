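# Independent nested-loop reference implementations used to cross-check
# the vectorized/BLAS paths, plus small fixture builders. These oracles are
# deliberately naive (explicit loops over voxels).

oracle_l1 <- function(G, Y) {
  s <- 0
  for (i in seq_along(G)) s <- s + abs(G[i] - Y[i])
  s / length(G)
}

oracle_mse <- function(G, Y) {
  s <- 0
  for (i in seq_along(G)) s <- s + (G[i] - Y[i])^2
  s / length(G)
}

oracle_r2 <- function(G, Y) {
  yb <- mean(Y)
  ssr <- 0; sst <- 0
  for (i in seq_along(Y)) {
    ssr <- ssr + (G[i] - Y[i])^2
    sst <- sst + (Y[i] - yb)^2
  }
  1 - ssr / sst
}

oracle_nmae <- function(G, Y) {
  s <- 0
  for (i in seq_along(G)) s <- s + abs(G[i] - Y[i])
  100 * (s / length(G)) / (max(Y) - min(Y))
}

oracle_gdl <- function(G, Y, p, mode) {
  d <- dim(G)
  tot <- 0
  for (a in 1:3) {
    s <- 0; n <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      nb <- c(i, j, k); nb[a] <- nb[a] + 1
      if (nb[a] > d[a]) next
      dg <- G[nb[1], nb[2], nb[3]] - G[i, j, k]
      dy <- Y[nb[1], nb[2], nb[3]] - Y[i, j, k]
      r <- if (mode == "abs_of_gradients") abs(dg) - abs(dy) else dg - dy
      s <- s + abs(r)^p
      n <- n + 1
    }
    tot <- tot + s / n
  }
  tot / 3
}

oracle_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m3 / m2^1.5
}

# direct 3x3x3 convolution with edge-replication padding; w indexed
# [cin*27 + t + 1, cout] with t = (dz+1) + 3*(dy+1) + 9*(dx+1)
oracle_conv3 <- function(x, w, b) {
  d <- dim(x)
  cout <- ncol(w)
  y <- array(0, c(d[1:3], cout))
  cl <- function(v, n) min(max(v, 1L), n)
  for (co in seq_len(cout)) for (k in seq_len(d[3])) for (j in seq_len(d[2]))
    for (i in seq_len(d[1])) {
      acc <- b[co]
      for (ci in seq_len(d[4])) for (dx in -1:1) for (dy in -1:1)
        for (dz in -1:1) {
          t <- (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1)
          acc <- acc + x[cl(i + dz, d[1]), cl(j + dy, d[2]),
                         cl(k + dx, d[3]), ci] * w[(ci - 1) * 27 + t + 1, co]
        }
      y[i, j, k, co] <- acc
    }
  y
}

# 1D stride-2 kernel-3 transpose convolution (the overlap-count mechanism):
# out[o] = sum over kernel taps d in {-1,0,1} of in[i] * w[d+2] where
# o = 2 i + d (1-based bookkeeping below)
oracle_convt1d <- function(x, w) {
  n <- length(x)
  out <- numeric(2 * n)
  for (i in seq_len(n)) for (d in -1:1) {
    o <- 2 * (i - 1) + d + 1  # 0-based output index + 1
    if (o >= 1 && o <= 2 * n) out[o] <- out[o] + x[i] * w[d + 2]
  }
  out
}

oracle_checkerboard <- function(vol) {
  d <- dim(vol)
  tol <- 1e-10 * max(abs(vol))
  vals <- numeric(3)
  for (a in 1:3) {
    num <- 0; den <- 0
    perp <- setdiff(1:3, a)
    for (u in seq_len(d[perp[1]])) for (v in seq_len(d[perp[2]])) {
      alt <- 0
      for (i in 2:(d[a] - 1)) {
        idx <- integer(3); idx[a] <- i; idx[perp[1]] <- u; idx[perp[2]] <- v
        im <- idx; im[a] <- i - 1
        ip <- idx; ip[a] <- i + 1
        r <- vol[idx[1], idx[2], idx[3]] -
          (vol[im[1], im[2], im[3]] + vol[idx[1], idx[2], idx[3]] +
             vol[ip[1], ip[2], ip[3]]) / 3
        if (abs(r) < tol) r <- 0
        alt <- alt + (-1)^i * r
        den <- den + abs(r)
      }
      num <- num + abs(alt)
    }
    vals[a] <- if (den == 0) 0 else num / den
  }
  mean(vals)
}

# small fast phantom family used throughout the tests
tiny_phantom <- function(contrast = FALSE, grid = c(32L, 32L, 32L),
                         voxel = 9) {
  phantom_spec(grid, voxel, contrast = contrast)
}

tiny_cases <- function(n, seed, count_scale = 2e5) {
  make_training_pairs(n, seed = seed,
                      acq = acq_settings(count_scale = count_scale))
}
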