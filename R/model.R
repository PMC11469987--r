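# Modified 3D U-Net generator mapping 1-2 channel normalized SPECT input to
# a single-channel mu-map. Encoder levels apply two 3x3x3 convolutions
# (edge-replication padding) each followed by a normalization layer and
# ReLU, then 2x2x2 max pooling; the decoder mirrors the encoder with skip
# concatenation and either learned stride-2 transpose convolution (kernel 3
# - the configuration that produces checkerboard artifacts) or
# nearest-neighbor interpolation followed by a stride-1 convolution (the
# artifact-free configuration). Forward and backward passes are implemented
# directly over BLAS-backed im2col kernels; no external deep-learning
# framework is used.

#' Network configuration
#'
#' @param in_channels 1 (primary alone) or 2 (primary + scatter).
#' @param base_filters Filters at the first encoder level (study value 64).
#' @param depth Number of skip connections / down-samplings (study value 4).
#' @param norm_layer `"instance"` (per-sample, per-channel statistics; the
#'   modification under study) or `"batch"`.
#' @param upsampling `"nearest_interp"` (replication + stride-1 conv; the
#'   modification under study) or `"transpose_conv"` (kernel 3, stride 2).
#' @param conv_kernel Convolution kernel size (only 3 is implemented).
#' @param output_activation `"relu"` (non-negative output during training
#'   and inference; the backward pass leaks a 0.01 gradient through the
#'   clamped region so a region-wide dead head can recover) or
#'   `"linear_clamped"` (identity during training, clamped at 0 at
#'   inference).
#' @param eps Normalization epsilon.
#' @return Object of class `net_config`.
#' @export
net_config <- function(in_channels = 2L, base_filters = 64L, depth = 4L,
                       norm_layer = c("instance", "batch"),
                       upsampling = c("nearest_interp", "transpose_conv"),
                       conv_kernel = 3L,
                       output_activation = c("relu", "linear_clamped"),
                       eps = 1e-5) {
  norm_layer <- match.arg(norm_layer)
  upsampling <- match.arg(upsampling)
  output_activation <- match.arg(output_activation)
  if (!in_channels %in% 1:2) stop_mugen("in_channels must be 1 or 2")
  if (base_filters < 1) stop_mugen("base_filters must be >= 1")
  if (depth < 1) stop_mugen("depth must be >= 1")
  if (conv_kernel != 3L) stop_mugen("only conv_kernel = 3 is implemented")
  structure(list(in_channels = as.integer(in_channels),
                 base_filters = as.integer(base_filters),
                 depth = as.integer(depth), norm_layer = norm_layer,
                 upsampling = upsampling, conv_kernel = 3L,
                 output_activation = output_activation, eps = eps),
            class = "net_config")
}

#' Build a generator with randomly initialized weights
#'
#' He-normal initialization, deterministic for a fixed seed. Spatial input
#' dims must be divisible by `2^depth`.
#'
#' @param cfg A [net_config()].
#' @param input_shape Spatial grid (D, H, W).
#' @param seed Integer seed for weight initialization.
#' @return Object of class `mugen_generator`.
#' @export
build_generator <- function(cfg, input_shape = c(64L, 128L, 128L), seed = 1L) {
  stopifnot(inherits(cfg, "net_config"))
  input_shape <- as.integer(input_shape)
  div <- 2L^cfg$depth
  bad <- which(input_shape %% div != 0)
  if (length(bad))
    stop_mugen("spatial dimension ", paste(input_shape[bad], collapse = ", "),
               " (axis ", paste(bad, collapse = ", "),
               ") is not divisible by 2^depth = ", div)
  set.seed(seed)
  par <- list()
  he_conv <- function(cin, cout)
    matrix(stats::rnorm(27 * cin * cout, 0, sqrt(2 / (27 * cin))),
           27 * cin, cout)
  add_block <- function(prefix, cin, cout) {
    par[[paste0(prefix, ".c1.w")]] <<- he_conv(cin, cout)
    par[[paste0(prefix, ".c1.b")]] <<- numeric(cout)
    par[[paste0(prefix, ".n1.g")]] <<- rep(1, cout)
    par[[paste0(prefix, ".n1.b")]] <<- numeric(cout)
    par[[paste0(prefix, ".c2.w")]] <<- he_conv(cout, cout)
    par[[paste0(prefix, ".c2.b")]] <<- numeric(cout)
    par[[paste0(prefix, ".n2.g")]] <<- rep(1, cout)
    par[[paste0(prefix, ".n2.b")]] <<- numeric(cout)
  }
  bf <- cfg$base_filters
  for (L in seq_len(cfg$depth)) {
    cin <- if (L == 1) cfg$in_channels else bf * 2^(L - 2)
    add_block(paste0("e", L), cin, bf * 2^(L - 1))
  }
  add_block("bot", bf * 2^(cfg$depth - 1), bf * 2^cfg$depth)
  for (L in rev(seq_len(cfg$depth))) {
    cin_up <- bf * 2^L
    cout_up <- bf * 2^(L - 1)
    par[[paste0("d", L, ".up.w")]] <- he_conv(cin_up, cout_up)
    par[[paste0("d", L, ".up.b")]] <- numeric(cout_up)
    add_block(paste0("d", L), cin_up, cout_up)
  }
  par[["head.w"]] <- matrix(stats::rnorm(bf, 0, sqrt(2 / bf)), bf, 1)
  # small positive output bias keeps the ReLU head live at initialization
  # (a dead head zeroes all gradients and can stall training entirely)
  par[["head.b"]] <- 0.01
  structure(list(cfg = cfg, input_shape = input_shape, par = par,
                 bn_stats = list(), seed = as.integer(seed)),
            class = "mugen_generator")
}

#' Number of trainable parameters
#' @param gen A `mugen_generator`.
#' @return Integer parameter count.
#' @export
param_count <- function(gen) sum(vapply(gen$par, length, numeric(1)))

# ---- low-level layer wrappers -------------------------------------------

conv_fw <- function(x, w, b) {
  d <- dim(x)
  array(cpp_conv3_fw(as.numeric(x), w, b, d[1], d[2], d[3], d[4], ncol(w)),
        c(d[1:3], ncol(w)))
}

conv_bw <- function(x, w, dy) {
  d <- dim(x)
  r <- cpp_conv3_bw(as.numeric(x), w, as.numeric(dy),
                    d[1], d[2], d[3], d[4], ncol(w))
  list(dx = array(r$dx, d), dw = matrix(r$dw, nrow(w), ncol(w)), db = r$db)
}

convt_fw <- function(x, w, b) {
  d <- dim(x)
  array(cpp_convt3_fw(as.numeric(x), w, b, d[1], d[2], d[3], d[4], ncol(w)),
        c(2 * d[1:3], ncol(w)))
}

convt_bw <- function(x, w, dy) {
  d <- dim(x)
  r <- cpp_convt3_bw(as.numeric(x), w, as.numeric(dy),
                     d[1], d[2], d[3], d[4], ncol(w))
  list(dx = array(r$dx, d), dw = matrix(r$dw, nrow(w), ncol(w)), db = r$db)
}

#' Per-channel instance normalization (functional form)
#'
#' Standardizes each channel of a single sample over its spatial voxels:
#' `(x - mean) / sqrt(var + eps)`, then applies the affine scale and shift.
#'
#' @param x 4D array (D, H, W, C).
#' @param gamma,beta Per-channel affine parameters (default identity).
#' @param eps Variance guard.
#' @return 4D array of the same shape.
#' @export
instance_normalize <- function(x, gamma = NULL, beta = NULL, eps = 1e-5) {
  d <- dim(x)
  C <- d[4]
  if (is.null(gamma)) gamma <- rep(1, C)
  if (is.null(beta)) beta <- numeric(C)
  nv <- prod(d[1:3])
  xm <- matrix(x, nv, C)
  m <- colMeans(xm)
  v <- pmax(colMeans(xm^2) - m^2, 0)
  sdv <- sqrt(v + eps)
  xh <- (xm - rep(m, each = nv)) / rep(sdv, each = nv)
  array(xh * rep(gamma, each = nv) + rep(beta, each = nv), d)
}

#' Nearest-neighbor 2x up-sampling (replication)
#'
#' @param x 4D feature array (D, H, W, C).
#' @return Array with each spatial dim doubled (each voxel replicated
#'   2x2x2).
#' @export
upsample_nearest <- function(x) {
  d <- dim(x)
  array(cpp_upnn_fw(as.numeric(x), d[1], d[2], d[3], d[4]),
        c(2 * d[1:3], d[4]))
}

#' Transpose-convolution 2x up-sampling (kernel 3, stride 2)
#'
#' The kernel size is not divisible by the stride, so output voxels receive
#' unequal numbers of kernel taps by coordinate parity - the mechanism that
#' produces checkerboard artifacts.
#'
#' @param x 4D feature array (D, H, W, Cin).
#' @param w Weight matrix (27*Cin x Cout); random if `NULL`.
#' @param b Bias (length Cout).
#' @param seed Seed for the random kernel when `w` is `NULL`.
#' @return 4D array with each spatial dim doubled.
#' @export
upsample_transpose <- function(x, w = NULL, b = NULL, seed = 1L) {
  d <- dim(x)
  if (is.null(w)) {
    set.seed(seed)
    w <- matrix(stats::rnorm(27 * d[4] * d[4], 0, sqrt(2 / (27 * d[4]))),
                27 * d[4], d[4])
  }
  if (is.null(b)) b <- numeric(ncol(w))
  convt_fw(x, w, b)
}

# normalization over a list of samples; instance = per-sample stats,
# batch = joint stats over batch + spatial (running stats at eval)
norm_fw <- function(xs, g, bta, type, eps, training, stats_key, gen_env) {
  C <- length(g)
  if (type == "instance") {
    caches <- vector("list", length(xs))
    ys <- vector("list", length(xs))
    for (i in seq_along(xs)) {
      d <- dim(xs[[i]]); nv <- prod(d[1:3])
      xm <- matrix(xs[[i]], nv, C)
      m <- colMeans(xm)
      v <- pmax(colMeans(xm^2) - m^2, 0)
      sdv <- sqrt(v + eps)
      xh <- (xm - rep(m, each = nv)) / rep(sdv, each = nv)
      ys[[i]] <- array(xh * rep(g, each = nv) + rep(bta, each = nv), d)
      caches[[i]] <- list(xh = xh, sd = sdv, d = d)
    }
    list(ys = ys, cache = caches)
  } else {
    d <- dim(xs[[1]]); nv <- prod(d[1:3]); n <- length(xs)
    if (training || is.null(gen_env$bn_stats[[stats_key]])) {
      s1 <- numeric(C); s2 <- numeric(C)
      for (x in xs) {
        xm <- matrix(x, nv, C)
        s1 <- s1 + colSums(xm); s2 <- s2 + colSums(xm^2)
      }
      m <- s1 / (nv * n)
      v <- pmax(s2 / (nv * n) - m^2, 0)
      if (training) {
        old <- gen_env$bn_stats[[stats_key]]
        if (is.null(old)) old <- list(m = m, v = v)
        gen_env$bn_stats[[stats_key]] <-
          list(m = 0.9 * old$m + 0.1 * m, v = 0.9 * old$v + 0.1 * v)
      }
    } else {
      st <- gen_env$bn_stats[[stats_key]]
      m <- st$m; v <- st$v
    }
    sdv <- sqrt(v + eps)
    caches <- vector("list", n); ys <- vector("list", n)
    for (i in seq_len(n)) {
      xm <- matrix(xs[[i]], nv, C)
      xh <- (xm - rep(m, each = nv)) / rep(sdv, each = nv)
      ys[[i]] <- array(xh * rep(g, each = nv) + rep(bta, each = nv), d)
      caches[[i]] <- list(xh = xh, sd = sdv, d = d)
    }
    list(ys = ys, cache = caches)
  }
}

norm_bw <- function(dys, cache, g, type) {
  C <- length(g)
  n <- length(dys)
  dg <- numeric(C); db <- numeric(C)
  dxs <- vector("list", n)
  if (type == "instance") {
    for (i in seq_len(n)) {
      cc <- cache[[i]]; nv <- prod(cc$d[1:3])
      dym <- matrix(dys[[i]], nv, C)
      dg <- dg + colSums(dym * cc$xh)
      db <- db + colSums(dym)
      dxh <- dym * rep(g, each = nv)
      m1 <- colMeans(dxh)
      m2 <- colMeans(dxh * cc$xh)
      dxm <- (dxh - rep(m1, each = nv) - cc$xh * rep(m2, each = nv)) /
        rep(cc$sd, each = nv)
      dxs[[i]] <- array(dxm, cc$d)
    }
  } else {
    nv <- prod(cache[[1]]$d[1:3])
    N <- nv * n
    s1 <- numeric(C); s2 <- numeric(C)
    for (i in seq_len(n)) {
      dym <- matrix(dys[[i]], nv, C)
      dg <- dg + colSums(dym * cache[[i]]$xh)
      db <- db + colSums(dym)
      dxh <- dym * rep(g, each = nv)
      s1 <- s1 + colSums(dxh)
      s2 <- s2 + colSums(dxh * cache[[i]]$xh)
    }
    m1 <- s1 / N; m2 <- s2 / N
    for (i in seq_len(n)) {
      cc <- cache[[i]]
      dym <- matrix(dys[[i]], nv, C)
      dxh <- dym * rep(g, each = nv)
      dxm <- (dxh - rep(m1, each = nv) - cc$xh * rep(m2, each = nv)) /
        rep(cc$sd, each = nv)
      dxs[[i]] <- array(dxm, cc$d)
    }
  }
  list(dxs = dxs, dg = dg, db = db)
}

# ---- full forward / backward --------------------------------------------

# forward over a list of samples; returns ys and (if training) a cache for
# the backward pass. gen_env: environment holding gen (for batch-norm
# running stats updates).
mugen_forward <- function(gen, xs, training = FALSE) {
  cfg <- gen$cfg
  gen_env <- new.env()
  gen_env$bn_stats <- gen$bn_stats
  cache <- if (training) new.env(parent = emptyenv()) else NULL
  keep <- function(key, val) if (training) assign(key, val, envir = cache)

  block_fw <- function(xs, prefix) {
    for (stage in 1:2) {
      w <- gen$par[[paste0(prefix, ".c", stage, ".w")]]
      b <- gen$par[[paste0(prefix, ".c", stage, ".b")]]
      keep(paste0(prefix, ".c", stage, ".x"), xs)
      xs <- lapply(xs, conv_fw, w = w, b = b)
      nf <- norm_fw(xs, gen$par[[paste0(prefix, ".n", stage, ".g")]],
                    gen$par[[paste0(prefix, ".n", stage, ".b")]],
                    cfg$norm_layer, cfg$eps, training,
                    paste0(prefix, ".n", stage), gen_env)
      keep(paste0(prefix, ".n", stage, ".cache"), nf$cache)
      xs <- lapply(nf$ys, function(x) pmax(x, 0))
      keep(paste0(prefix, ".r", stage, ".y"), xs)
    }
    xs
  }

  skips <- vector("list", cfg$depth)
  for (L in seq_len(cfg$depth)) {
    xs <- block_fw(xs, paste0("e", L))
    skips[[L]] <- xs
    pooled <- lapply(xs, function(x) {
      d <- dim(x)
      r <- cpp_maxpool_fw(as.numeric(x), d[1], d[2], d[3], d[4])
      list(y = array(r$y, c(d[1:3] %/% 2L, d[4])), idx = r$idx, d = d)
    })
    keep(paste0("pool", L, ".cache"), pooled)
    xs <- lapply(pooled, `[[`, "y")
  }
  xs <- block_fw(xs, "bot")
  for (L in rev(seq_len(cfg$depth))) {
    w <- gen$par[[paste0("d", L, ".up.w")]]
    b <- gen$par[[paste0("d", L, ".up.b")]]
    if (cfg$upsampling == "transpose_conv") {
      keep(paste0("d", L, ".up.x"), xs)
      xs <- lapply(xs, convt_fw, w = w, b = b)
    } else {
      ups <- lapply(xs, upsample_nearest)
      keep(paste0("d", L, ".up.x"), ups)
      xs <- lapply(ups, conv_fw, w = w, b = b)
    }
    xs <- Map(function(u, s) {
      d <- dim(u)
      array(c(u, s), c(d[1:3], d[4] + dim(s)[4]))
    }, xs, skips[[L]])
    keep(paste0("d", L, ".upc"), ncol(gen$par[[paste0("d", L, ".up.w")]]))
    xs <- block_fw(xs, paste0("d", L))
  }
  w <- gen$par[["head.w"]]; b <- gen$par[["head.b"]]
  keep("head.x", xs)
  ys <- lapply(xs, function(x) {
    d <- dim(x)
    ym <- matrix(x, prod(d[1:3]), d[4]) %*% w + b
    array(ym, c(d[1:3], 1L))
  })
  if (cfg$output_activation == "relu") {
    ys <- lapply(ys, function(y) pmax(y, 0))
    keep("head.y", ys)
  } else if (!training) {
    ys <- lapply(ys, function(y) pmax(y, 0))
  }
  list(ys = ys, cache = cache, bn_stats = gen_env$bn_stats)
}

# backward pass: dys = d loss / d output per sample. Returns flat grad list
# aligned with gen$par.
mugen_backward <- function(gen, cache, dys) {
  cfg <- gen$cfg
  gr <- list()
  getc <- function(key) get(key, envir = cache)

  block_bw <- function(dys, prefix) {
    for (stage in 2:1) {
      ry <- getc(paste0(prefix, ".r", stage, ".y"))
      dys <- Map(function(dy, y) dy * (y > 0), dys, ry)
      nb <- norm_bw(dys, getc(paste0(prefix, ".n", stage, ".cache")),
                    gen$par[[paste0(prefix, ".n", stage, ".g")]],
                    cfg$norm_layer)
      gr[[paste0(prefix, ".n", stage, ".g")]] <<- nb$dg
      gr[[paste0(prefix, ".n", stage, ".b")]] <<- nb$db
      dys <- nb$dxs
      xs <- getc(paste0(prefix, ".c", stage, ".x"))
      w <- gen$par[[paste0(prefix, ".c", stage, ".w")]]
      dw <- matrix(0, nrow(w), ncol(w)); db <- numeric(ncol(w))
      dxs <- vector("list", length(dys))
      for (i in seq_along(dys)) {
        r <- conv_bw(xs[[i]], w, dys[[i]])
        dw <- dw + r$dw; db <- db + r$db; dxs[[i]] <- r$dx
      }
      gr[[paste0(prefix, ".c", stage, ".w")]] <<- dw
      gr[[paste0(prefix, ".c", stage, ".b")]] <<- db
      dys <- dxs
    }
    dys
  }

  # head; the ReLU head backward leaks a small gradient through the
  # clamped region - a hard zero there is irrecoverable (the all-zero
  # prediction is L1-stable) and can permanently stall training
  hx <- getc("head.x")
  w <- gen$par[["head.w"]]
  if (cfg$output_activation == "relu") {
    hy <- getc("head.y")
    dys <- Map(function(dy, y) dy * (0.01 + 0.99 * (y > 0)), dys, hy)
  }
  dwh <- matrix(0, nrow(w), 1); dbh <- 0
  dys <- Map(function(x, dy) {
    d <- dim(x); nv <- prod(d[1:3])
    dym <- matrix(dy, nv, 1)
    xm <- matrix(x, nv, d[4])
    dwh <<- dwh + crossprod(xm, dym)
    dbh <<- dbh + sum(dym)
    array(dym %*% t(w), d)
  }, hx, dys)
  gr[["head.w"]] <- dwh; gr[["head.b"]] <- dbh

  dskips <- vector("list", cfg$depth)
  for (L in seq_len(cfg$depth)) {
    dys <- block_bw(dys, paste0("d", L))
    upc <- getc(paste0("d", L, ".upc"))
    dup <- lapply(dys, function(dy) {
      d <- dim(dy)
      dy[, , , seq_len(upc), drop = FALSE]
    })
    dskips[[L]] <- lapply(dys, function(dy) {
      d <- dim(dy)
      dy[, , , (upc + 1):d[4], drop = FALSE]
    })
    ux <- getc(paste0("d", L, ".up.x"))
    w <- gen$par[[paste0("d", L, ".up.w")]]
    dw <- matrix(0, nrow(w), ncol(w)); db <- numeric(ncol(w))
    if (cfg$upsampling == "transpose_conv") {
      dxs <- vector("list", length(dup))
      for (i in seq_along(dup)) {
        r <- convt_bw(ux[[i]], w, dup[[i]])
        dw <- dw + r$dw; db <- db + r$db; dxs[[i]] <- r$dx
      }
    } else {
      dxs <- vector("list", length(dup))
      for (i in seq_along(dup)) {
        r <- conv_bw(ux[[i]], w, dup[[i]])
        dw <- dw + r$dw; db <- db + r$db
        d <- dim(r$dx)
        dxs[[i]] <- array(cpp_upnn_bw(as.numeric(r$dx), d[1] %/% 2L,
                                      d[2] %/% 2L, d[3] %/% 2L, d[4]),
                          c(d[1:3] %/% 2L, d[4]))
      }
    }
    gr[[paste0("d", L, ".up.w")]] <- dw
    gr[[paste0("d", L, ".up.b")]] <- db
    dys <- dxs
  }
  dys <- block_bw(dys, "bot")
  for (L in rev(seq_len(cfg$depth))) {
    pooled <- getc(paste0("pool", L, ".cache"))
    dys <- Map(function(dy, pc) {
      array(cpp_maxpool_bw(pc$idx, as.numeric(dy), prod(pc$d)), pc$d)
    }, dys, pooled)
    dys <- Map(`+`, dys, dskips[[L]])
    dys <- block_bw(dys, paste0("e", L))
  }
  gr
}

#' Generate a synthetic mu-map from a network input
#'
#' Deterministic inference pass; the output is non-negative under the
#' default ReLU head.
#'
#' @param gen A `mugen_generator` (typically from a fitted model).
#' @param x A `network_input` (from [assemble_input()]) or 4D array whose
#'   channel count matches the generator configuration.
#' @param voxel_size_mm Voxel size recorded on the returned map.
#' @return A `mu_map` with `provenance = "synthetic"`.
#' @export
predict_mu <- function(gen, x, voxel_size_mm = 4.5) {
  stopifnot(inherits(gen, "mugen_generator"))
  xa <- if (inherits(x, "network_input")) x$channels else x
  if (length(dim(xa)) != 4L) stop_mugen("input must be a 4D (D,H,W,C) array")
  if (dim(xa)[4] != gen$cfg$in_channels)
    stop_mugen("input has ", dim(xa)[4], " channels but the generator ",
               "expects ", gen$cfg$in_channels)
  out <- mugen_forward(gen, list(xa), training = FALSE)$ys[[1]]
  new_mu_map(array(out, dim(out)[1:3]), voxel_size_mm, "synthetic")
}

#' @export
print.mugen_generator <- function(x, ...) {
  cat(sprintf(paste0("3D U-Net mu-map generator: %d -> 1 channels, depth %d,",
                     " base %d filters\n"),
              x$cfg$in_channels, x$cfg$depth, x$cfg$base_filters))
  cat(sprintf("  norm: %s | upsampling: %s | parameters: %s\n",
              x$cfg$norm_layer, x$cfg$upsampling,
              format(param_count(x), big.mark = ",")))
  invisible(x)
}
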