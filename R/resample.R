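## Separable resampling between the native acquisition grid and the fixed
## model grid, and in-plane rotation augmentation. Images use a cubic
## convolution kernel (Catmull-Rom, a = -0.5, the classical "bicubic"
## interpolator) applied separably along each axis; label masks use nearest
## neighbour along each axis so no class code can be fabricated. Coordinates
## follow the pixel-center convention: target index t samples source
## coordinate (t + 0.5) * S/T - 0.5, which reduces to the identity when
## T == S.

cubic_kernel <- function(t, a = -0.5) {
  at <- abs(t)
  ifelse(at <= 1,
         (a + 2) * at^3 - (a + 3) * at^2 + 1,
         ifelse(at < 2, a * at^3 - 5 * a * at^2 + 8 * a * at - 4 * a, 0))
}

## Dense T x S matrix applying 1D cubic resampling (border-replicated).
cubic_resample_matrix <- function(S, T) {
  M <- matrix(0, T, S)
  src <- (seq_len(T) - 0.5) * S / T - 0.5          # 0-based source coords
  i0 <- floor(src)
  for (d in -1:2) {
    idx <- pmin(pmax(i0 + d, 0), S - 1)
    w <- cubic_kernel(src - (i0 + d))
    M[cbind(seq_len(T), idx + 1)] <- M[cbind(seq_len(T), idx + 1)] + w
  }
  M
}

## Nearest-neighbour source index (1-based) for each of T targets.
nn_resample_index <- function(S, T) {
  src <- (seq_len(T) - 0.5) * S / T - 0.5
  pmin(pmax(floor(src + 0.5), 0), S - 1) + 1
}

## Apply a T x S matrix along one axis of a 3D array.
apply_axis <- function(x, M, axis) {
  d <- dim(x)
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  yp <- M %*% matrix(xp, nrow = d[axis])
  dim(yp) <- c(nrow(M), d[perm[2]], d[perm[3]])
  aperm(yp, order(perm))
}

#' Resample a 3D array to a target shape
#'
#' @param x 3D numeric array.
#' @param target length-3 integer target shape.
#' @param method `"cubic"` (images) or `"nearest"` (label masks).
#' @return resampled array of dimension `target`.
#' @export
resample_array <- function(x, target, method = c("cubic", "nearest")) {
  method <- match.arg(method)
  d <- dim(x)
  if (length(d) != 3L || length(target) != 3L)
    stopf("'x' must be 3D and 'target' length 3")
  if (any(target < 1L)) stopf("target shape must be >= 1 on every axis")
  if (any(d < 1L)) stopf("cannot resample a zero-size array")
  if (method == "cubic") {
    for (ax in 1:3)
      if (target[ax] != d[ax])
        x <- apply_axis(x, cubic_resample_matrix(dim(x)[ax], target[ax]), ax)
    x
  } else {
    ix <- nn_resample_index(d[1], target[1])
    iy <- nn_resample_index(d[2], target[2])
    iz <- nn_resample_index(d[3], target[3])
    x[ix, iy, iz, drop = FALSE]
  }
}

#' Min-max normalize a volume to [0, 1]
#'
#' Linear map sending the volume minimum to 0 and maximum to 1. A constant
#' volume maps to all zeros with a warning rather than erroring; the raw range
#' is kept in `intensity_range` so the map is invertible in provenance.
#'
#' @param vol an [annotated_volume()].
#' @return a normalized [annotated_volume()].
#' @export
minmax_normalize <- function(vol) {
  if (!inherits(vol, "annotated_volume")) stopf("'vol' must be an annotated_volume")
  r <- range(vol$voxels)
  if (r[1] == r[2]) {
    warning("constant-intensity volume: min-max normalization yields all zeros",
            call. = FALSE)
    v <- array(0, dim = dim(vol$voxels))
  } else {
    v <- (vol$voxels - r[1]) / (r[2] - r[1])
  }
  annotated_volume(v, vol$pixel_spacing, vol$z_positions, intensity_range = r)
}

#' Resample a volume (and optionally its mask) onto the model grid
#'
#' Images are resampled with separable cubic interpolation and clamped back to
#' [0, 1] (cubic overshoot would otherwise break the normalization contract);
#' masks use nearest neighbour. Depth is resampled in both directions: 12-17
#' native slices all map onto the fixed model depth. The returned provenance
#' lets [resample_back()] invert the grid change.
#'
#' @param vol a normalized [annotated_volume()] (all voxels in [0, 1]).
#' @param mask optional paired [label_mask()].
#' @param shape model grid (H, W, D), default `c(240, 240, 16)`.
#' @return An object of class `model_grid_pair`: `image` is a (1, H, W, D)
#'   array in [0, 1], `mask` (if given) an (H, W, D) integer array, and
#'   `provenance` records the native geometry.
#' @export
to_model_grid <- function(vol, mask = NULL, shape = c(240, 240, 16)) {
  if (!inherits(vol, "annotated_volume")) stopf("'vol' must be an annotated_volume")
  v <- vol$voxels
  if (min(v) < 0 || max(v) > 1)
    stopf("'vol' must be min-max normalized to [0, 1] before model-grid resampling")
  if (!is.null(mask)) {
    if (!inherits(mask, "label_mask")) stopf("'mask' must be a label_mask")
    if (!identical(dim(mask$labels), dim(v)))
      stopf("mask and volume grids differ")
  }
  shape <- as.integer(shape)
  img <- clamp01(resample_array(v, shape, "cubic"))
  dim(img) <- c(1L, shape)
  m <- if (!is.null(mask)) {
    mm <- resample_array(mask$labels, shape, "nearest")
    storage.mode(mm) <- "integer"
    mm
  }
  structure(
    list(image = img,
         mask = m,
         provenance = list(shape = dim(v),
                           model_shape = shape,
                           pixel_spacing = vol$pixel_spacing,
                           z_positions = vol$z_positions,
                           intensity_range = vol$intensity_range)),
    class = "model_grid_pair")
}

#' @export
print.model_grid_pair <- function(x, ...) {
  cat(sprintf("<model_grid_pair> image (1, %s)%s; native grid %s\n",
              paste(dim(x$image)[-1], collapse = ", "),
              if (is.null(x$mask)) "" else " + mask",
              paste(x$provenance$shape, collapse = " x ")))
  invisible(x)
}

## Per-slice rotation sampling shared by image (cubic) and mask (nearest).
## Returns list(idx: n x k matrix of 1-based linear slice indices,
##              w: n x k weights, outside: logical n) for gather-style
## interpolation of every in-plane point at once.
rotation_taps <- function(H, W, angle_deg, method) {
  th <- angle_deg * pi / 180
  cr <- (H - 1) / 2; cc <- (W - 1) / 2
  g <- expand.grid(r = 0:(H - 1), c = 0:(W - 1))
  dr <- g$r - cr; dc <- g$c - cc
  ## inverse map: source = R(-theta) * target
  sr <- cos(th) * dr + sin(th) * dc + cr
  sc <- -sin(th) * dr + cos(th) * dc + cc
  outside <- sr < 0 | sr > H - 1 | sc < 0 | sc > W - 1
  if (method == "nearest") {
    ir <- pmin(pmax(floor(sr + 0.5), 0), H - 1)
    ic <- pmin(pmax(floor(sc + 0.5), 0), W - 1)
    list(idx = cbind(ir + ic * H + 1), w = cbind(rep(1, length(sr))),
         outside = outside)
  } else {
    r0 <- floor(sr); c0 <- floor(sc)
    idx <- matrix(0L, length(sr), 16L)
    w <- matrix(0, length(sr), 16L)
    k <- 0L
    for (dcc in -1:2) for (drr in -1:2) {
      k <- k + 1L
      ir <- pmin(pmax(r0 + drr, 0), H - 1)
      ic <- pmin(pmax(c0 + dcc, 0), W - 1)
      idx[, k] <- ir + ic * H + 1
      w[, k] <- cubic_kernel(sr - (r0 + drr)) * cubic_kernel(sc - (c0 + dcc))
    }
    list(idx = idx, w = w, outside = outside)
  }
}

rotate_stack <- function(x, angle_deg, method) {
  d <- dim(x)
  taps <- rotation_taps(d[1], d[2], angle_deg, method)
  xm <- matrix(x, nrow = d[1] * d[2])
  out <- matrix(0, d[1] * d[2], d[3])
  for (k in seq_len(ncol(taps$idx)))
    out <- out + taps$w[, k] * xm[taps$idx[, k], , drop = FALSE]
  out[taps$outside, ] <- 0
  array(out, dim = d)
}

#' Rotate a model-grid pair about the longitudinal axis
#'
#' Training-time augmentation: every axial slice is rotated by the same angle
#' about the slice center. The image is interpolated bicubically (then
#' clamped to [0, 1]); the mask by nearest neighbour; voxels mapped from
#' outside the field of view become background/0.
#'
#' @param pair a [to_model_grid()] result.
#' @param angle_deg rotation angle in degrees, must lie in [-10, 10].
#' @return a rotated `model_grid_pair`.
#' @export
augment_rotation <- function(pair, angle_deg) {
  if (!inherits(pair, "model_grid_pair")) stopf("'pair' must be a model_grid_pair")
  if (!is.finite(angle_deg) || abs(angle_deg) > 10)
    stopf("'angle_deg' must lie in [-10, 10], got %s", format(angle_deg))
  if (angle_deg == 0) return(pair)
  d <- dim(pair$image)[-1]
  img <- array(pair$image, dim = d)
  img <- clamp01(rotate_stack(img, angle_deg, "cubic"))
  dim(img) <- c(1L, d)
  out <- pair
  out$image <- img
  if (!is.null(pair$mask)) {
    m <- rotate_stack(pair$mask, angle_deg, "nearest")
    storage.mode(m) <- "integer"
    out$mask <- m
  }
  out
}
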