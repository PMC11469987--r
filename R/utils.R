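# shared validation and small array helpers

stop_mugen <- function(...) stop(..., call. = FALSE)

check_volume <- function(x, name = "volume") {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop_mugen(name, " must be a 3D array")
  if (!all(is.finite(x)))
    stop_mugen(name, " contains non-finite values")
  invisible(x)
}

check_same_shape <- function(a, b, names = c("G", "Y")) {
  if (!identical(dim(a), dim(b)))
    stop_mugen("shape mismatch: ", names[1], " is ",
               paste(dim(a), collapse = "x"), " but ", names[2], " is ",
               paste(dim(b), collapse = "x"))
  invisible(NULL)
}

vol_values <- function(x) {
  if (is.list(x) && !is.null(x$values)) x$values else x
}

#' Flip a 3D array along a subset of axes
#'
#' @param x 3D array (or 4D array whose first three dims are spatial).
#' @param axes Integer vector of spatial axes to reverse (subset of 1:3).
#' @return Array of the same shape with the chosen axes reversed.
#' @export
flip_axes <- function(x, axes) {
  d <- dim(x)
  idx <- lapply(seq_along(d), function(a) {
    if (a <= 3 && a %in% axes) rev(seq_len(d[a])) else seq_len(d[a])
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Dilate a binary mask by a chessboard radius
#'
#' Morphological dilation with a cubic structuring element, used to widen a
#' parenchyma mask so that PSF spill-out is recaptured when measuring uptake.
#'
#' @param mask Logical 3D array.
#' @param r Non-negative integer radius in voxels.
#' @return Logical 3D array.
#' @export
dilate_mask <- function(mask, r = 1L) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop_mugen("mask must be a 3D array")
  m <- mask != 0
  if (r < 1) return(m)
  d <- dim(m)
  out <- m
  for (dz in -r:r) for (dy in -r:r) for (dx in -r:r) {
    if (dz == 0 && dy == 0 && dx == 0) next
    iz <- pmin(pmax(seq_len(d[1]) + dz, 1L), d[1])
    iy <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    ix <- pmin(pmax(seq_len(d[3]) + dx, 1L), d[3])
    out <- out | m[iz, iy, ix]
  }
  out
}

# flat key = value config files (comments with '#', blank lines ignored)
read_config <- function(path) {
  if (!file.exists(path)) stop_mugen("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop_mugen("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
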