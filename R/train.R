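# Training loop: Adam with per-epoch exponential learning-rate decay,
# per-axis random flip augmentation, patience-based early stopping disabled
# during a warm-up period, and best-validation-weight restoration. The full
# pipeline is a deterministic function of the seeds on one device.

#' Training configuration
#'
#' Defaults follow the study protocol: 100 epochs, batch size 8, adaptive
#' moment estimation at learning rate 1e-3 with exponential decay 0.96 per
#' epoch, flip augmentation along all three axes, early stopping on
#' validation loss disabled for the first 10 epochs.
#'
#' @param epochs Number of epochs (>= 1).
#' @param batch_size Mini-batch size (>= 1).
#' @param learning_rate Initial Adam learning rate.
#' @param lr_decay Per-epoch exponential decay factor in (0, 1];
#'   `lr(epoch) = learning_rate * lr_decay^(epoch - 1)`.
#' @param beta1,beta2 Adam moment coefficients.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param warmup_epochs Epochs during which early stopping is disabled.
#' @param augment Apply random flip augmentation (probability 0.5 per
#'   axis).
#' @param seed Integer seed controlling shuffling and augmentation.
#' @return Object of class `train_control`.
#' @export
train_control <- function(epochs = 100L, batch_size = 8L,
                          learning_rate = 1e-3, lr_decay = 0.96,
                          beta1 = 0.9, beta2 = 0.999,
                          patience = 10L, warmup_epochs = 10L,
                          augment = TRUE, seed = 1L) {
  if (epochs < 1) stop_mugen("epochs must be >= 1")
  if (batch_size < 1) stop_mugen("batch_size must be >= 1")
  if (lr_decay <= 0 || lr_decay > 1) stop_mugen("lr_decay must be in (0, 1]")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 beta1 = beta1, beta2 = beta2,
                 patience = as.integer(patience),
                 warmup_epochs = as.integer(warmup_epochs),
                 augment = isTRUE(augment), seed = as.integer(seed)),
            class = "train_control")
}

#' Random flip augmentation of an input/label pair
#'
#' Each spatial axis is flipped independently with probability 0.5; the
#' input channels and the label are flipped by the same axis subset, so
#' voxel-wise correspondence is preserved. Flipping twice with the same
#' axis mask restores the original pair.
#'
#' @param pair `list(x, y)` with `x` a 4D input array (or `network_input`)
#'   and `y` a 3D label array (or `mu_map`).
#' @param seed Optional seed for a deterministic axis mask (otherwise the
#'   current RNG stream is used).
#' @param axes Optional fixed axis subset overriding the random draw.
#' @return `list(x, y, axes)` with the flipped pair and the axis subset
#'   used.
#' @export
augment_flip <- function(pair, seed = NULL, axes = NULL) {
  x <- if (inherits(pair$x, "network_input")) pair$x$channels else pair$x
  y <- vol_values(pair$y)
  if (is.null(axes)) {
    if (!is.null(seed)) set.seed(seed)
    axes <- which(runif(3) < 0.5)
  }
  if (length(axes)) {
    x <- flip_axes(x, axes)
    y <- flip_axes(y, axes)
  }
  list(x = x, y = y, axes = axes)
}

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0), t = 0L)
}

adam_step <- function(par, gr, st, lr, b1, b2, eps = 1e-8) {
  st$t <- st$t + 1L
  corr1 <- 1 - b1^st$t
  corr2 <- 1 - b2^st$t
  for (k in names(par)) {
    g <- gr[[k]]
    st$m[[k]] <- b1 * st$m[[k]] + (1 - b1) * g
    st$v[[k]] <- b2 * st$v[[k]] + (1 - b2) * g^2
    par[[k]] <- par[[k]] -
      lr * (st$m[[k]] / corr1) / (sqrt(st$v[[k]] / corr2) + eps)
  }
  list(par = par, st = st)
}

case_xy <- function(cs) {
  x <- if (inherits(cs$x, "network_input")) cs$x$channels else cs$x
  y <- vol_values(cs$y)
  list(x = x, y = y)
}

#' Train the mu-map generator
#'
#' Minimizes the configured L1 + omega x GDL objective with Adam; records
#' per-epoch training loss, validation loss, and learning rate; restores
#' the parameters achieving the best validation loss.
#'
#' @param gen A `mugen_generator` from [build_generator()].
#' @param train,val Non-empty lists of cases `list(x, y)` (e.g. from
#'   [prepare_cases()]).
#' @param control A [train_control()].
#' @param loss A [loss_config()].
#' @return Object of class `mugen_fit`: the trained generator (best
#'   validation weights), the training history, the stopping reason, and
#'   the configurations used. A non-finite loss aborts with the epoch
#'   index.
#' @export
train_generator <- function(gen, train, val, control = train_control(),
                            loss = loss_config()) {
  stopifnot(inherits(gen, "mugen_generator"))
  if (!length(train) || !length(val))
    stop_mugen("train and val sets must be non-empty")
  train <- lapply(train, case_xy)
  val <- lapply(val, case_xy)
  d <- dim(train[[1]]$x)
  if (!identical(as.integer(d[1:3]), gen$input_shape))
    stop_mugen("data grid ", paste(d[1:3], collapse = "x"),
               " does not match the generator input shape")
  set.seed(control$seed)
  st <- adam_init(gen$par)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), lr = numeric())
  best_val <- Inf; best_par <- gen$par; best_bn <- gen$bn_stats
  best_epoch <- 0L; reason <- "completed all epochs"
  n <- length(train)
  for (epoch in seq_len(control$epochs)) {
    lr <- control$learning_rate * control$lr_decay^(epoch - 1)
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0
    for (b0 in seq(1, n, by = control$batch_size)) {
      idx <- ord[b0:min(b0 + control$batch_size - 1, n)]
      batch <- train[idx]
      if (control$augment)
        batch <- lapply(batch, function(cs) {
          a <- augment_flip(cs)
          list(x = a$x, y = a$y)
        })
      xs <- lapply(batch, `[[`, "x")
      fw <- mugen_forward(gen, xs, training = TRUE)
      gen$bn_stats <- fw$bn_stats
      bl <- 0
      dys <- vector("list", length(batch))
      for (i in seq_along(batch)) {
        G <- array(fw$ys[[i]], d[1:3])
        Y <- batch[[i]]$y
        bl <- bl + loss_total(G, Y, loss)
        dys[[i]] <- array(loss_total_grad(G, Y, loss) / length(batch),
                          c(d[1:3], 1L))
      }
      bl <- bl / length(batch)
      if (!is.finite(bl))
        stop_mugen("training diverged (non-finite loss) at epoch ", epoch)
      gr <- mugen_backward(gen, fw$cache, dys)
      upd <- adam_step(gen$par, gr, st, lr, control$beta1, control$beta2)
      gen$par <- upd$par; st <- upd$st
      ep_loss <- ep_loss + bl; nb <- nb + 1
    }
    vl <- mean(vapply(val, function(cs) {
      G <- array(mugen_forward(gen, list(cs$x))$ys[[1]], d[1:3])
      loss_total(G, cs$y, loss)
    }, numeric(1)))
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                   val_loss = vl, lr = lr))
    if (vl < best_val) {
      best_val <- vl; best_par <- gen$par; best_bn <- gen$bn_stats
      best_epoch <- epoch
    }
    if (epoch > control$warmup_epochs &&
        epoch - best_epoch >= control$patience) {
      reason <- sprintf("early stopping at epoch %d (no improvement for %d epochs)",
                        epoch, control$patience)
      break
    }
  }
  gen$par <- best_par; gen$bn_stats <- best_bn
  structure(list(generator = gen, history = hist, best_epoch = best_epoch,
                 stopping_reason = reason, control = control,
                 loss_config = loss), class = "mugen_fit")
}

#' Evaluate a generator on held-out cases
#'
#' @param object A `mugen_fit` or `mugen_generator`.
#' @param cases List of cases `list(x, y)`.
#' @return data.frame of per-case [metrics_report()] rows.
#' @export
evaluate_cases <- function(object, cases) {
  gen <- if (inherits(object, "mugen_fit")) object$generator else object
  do.call(rbind, lapply(cases, function(cs) {
    cs <- case_xy(cs)
    G <- predict_mu(gen, cs$x)
    metrics_report(G$values, cs$y)
  }))
}

#' Ablation ladder over input mode, normalization, loss, and up-sampling
#'
#' Trains one generator per configuration on the same raw cases and reports
#' test-set mean and SD of R^2, MSE, and %NMAE as a tab-separated-ready
#' table (one row per configuration, labels carried through as provided).
#'
#' @param train,val,test Lists of raw cases (from [make_training_pairs()]).
#' @param configs List of configurations, each a list with `input`
#'   (`"P"`/`"PS"`), `normalization` (`"max"`/`"log_max"`), `loss` (a
#'   [loss_config()]), `upsampling`, and optional `label`.
#' @param base_filters,depth Generator size shared across rows.
#' @param control A [train_control()].
#' @param seed Seed for generator initialization.
#' @return data.frame with configuration labels and aggregated metrics.
#' @export
run_ablation <- function(train, val, test, configs,
                         base_filters = 8L, depth = 2L,
                         control = train_control(), seed = 1L) {
  rows <- lapply(configs, function(cf) {
    tr <- prepare_cases(train, cf$input, cf$normalization)
    va <- prepare_cases(val, cf$input, cf$normalization)
    te <- prepare_cases(test, cf$input, cf$normalization)
    cfg <- net_config(in_channels = if (cf$input == "PS") 2L else 1L,
                      base_filters = base_filters, depth = depth,
                      upsampling = cf$upsampling)
    gen <- build_generator(cfg, dim(tr[[1]]$x$channels)[1:3], seed = seed)
    fit <- train_generator(gen, tr, va, control, cf$loss)
    rep <- aggregate_metrics(evaluate_cases(fit, te))
    cbind(data.frame(
      input = cf$input, normalization = cf$normalization,
      loss = if (!is.null(cf$label)) cf$label else
        sprintf("L1+%g x GDL^%d", cf$loss$omega, cf$loss$gdl_power),
      upsampling = cf$upsampling, stringsAsFactors = FALSE), rep)
  })
  do.call(rbind, rows)
}

#' Write an ablation (or metrics) table as tab-separated values
#'
#' @param tbl data.frame.
#' @param path Output path.
#' @export
write_report <- function(tbl, path) {
  write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- mugen_fit methods ---------------------------------------------------

#' @export
print.mugen_fit <- function(x, ...) {
  cat("Fitted mu-map generator\n")
  print(x$generator)
  cat(sprintf("  epochs run: %d | best epoch: %d (val loss %.6f)\n",
              nrow(x$history), x$best_epoch,
              x$history$val_loss[x$best_epoch]))
  cat("  ", x$stopping_reason, "\n", sep = "")
  invisible(x)
}

#' @export
summary.mugen_fit <- function(object, ...) {
  h <- object$history
  cat("Training history (loss = L1",
      if (object$loss_config$omega > 0)
        sprintf(" + %g x GDL^%d", object$loss_config$omega,
                object$loss_config$gdl_power), "):\n", sep = "")
  print(h[c(1, nrow(h)), ], row.names = FALSE)
  cat(sprintf("Best validation loss %.6f at epoch %d; %s\n",
              min(h$val_loss), object$best_epoch, object$stopping_reason))
  invisible(object)
}

#' Predict a synthetic mu-map from a fitted generator
#'
#' @param object A `mugen_fit`.
#' @param newdata A `network_input`, 4D array, or list of cases.
#' @param voxel_size_mm Voxel size recorded on the output.
#' @param ... Unused.
#' @return A `mu_map` (or list of `mu_map`s for a list input).
#' @export
predict.mugen_fit <- function(object, newdata, voxel_size_mm = 4.5, ...) {
  if (is.list(newdata) && !inherits(newdata, "network_input") &&
      !is.array(newdata) && !is.null(newdata[[1]]$x))
    return(lapply(newdata, function(cs)
      predict_mu(object$generator, cs$x, voxel_size_mm)))
  predict_mu(object$generator, newdata, voxel_size_mm)
}

#' Residual (error) maps on held-out cases
#'
#' @param object A `mugen_fit`.
#' @param cases List of cases `list(x, y)`.
#' @param ... Unused.
#' @return List of 3D arrays, ground truth minus prediction.
#' @export
residuals.mugen_fit <- function(object, cases, ...) {
  lapply(cases, function(cs) {
    cs <- case_xy(cs)
    error_map(predict_mu(object$generator, cs$x)$values, cs$y)
  })
}

#' Plot training and validation loss curves
#'
#' @param x A `mugen_fit`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.mugen_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("training", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}
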