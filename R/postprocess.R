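## Back-resampling of model-grid predictions to the native acquisition grid
## and edge smoothing, in that order (predictions are resampled to the
## original number of slices first, then median-filtered).

#' Resample model-grid labels back to the native grid
#'
#' Nearest-neighbour on every axis, so the output class set is always a
#' subset of the input's. The provenance recorded by [to_model_grid()]
#' supplies the native shape and geometry.
#'
#' @param labels `(H, W, D)` integer array on the model grid (e.g.
#'   `probability_map$labels`), or a `probability_map`.
#' @param provenance the `provenance` list of a `model_grid_pair`; taken from
#'   `labels` itself when it is a `probability_map`.
#' @return a [label_mask()] on the native grid.
#' @export
resample_back <- function(labels, provenance = NULL) {
  if (inherits(labels, "probability_map")) {
    provenance <- provenance %||% labels$provenance
    labels <- labels$labels
  }
  if (is.null(provenance))
    stopf("'provenance' is required to invert the model-grid resampling")
  out <- resample_array(labels, provenance$shape, "nearest")
  storage.mode(out) <- "integer"
  label_mask(out, pixel_spacing = provenance$pixel_spacing,
             z_positions = provenance$z_positions)
}

## Binary 5x5x5 box-majority vote; border windows are clipped so the
## effective window shrinks at the edges. Computed as 125 shifted adds of the
## zero-padded indicator and of the in-bounds indicator.
binary_median5 <- function(bin) {
  d <- dim(bin)
  r <- 2L
  pd <- d + 2L * r
  pad <- array(0, pd)
  ones <- array(0, pd)
  idx <- list(r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3]))
  pad[idx[[1]], idx[[2]], idx[[3]]] <- bin
  ones[idx[[1]], idx[[2]], idx[[3]]] <- 1
  cnt <- array(0, d)
  tot <- array(0, d)
  for (dk in 0:(2 * r)) for (dj in 0:(2 * r)) for (di in 0:(2 * r)) {
    cnt <- cnt + pad[di + seq_len(d[1]), dj + seq_len(d[2]), dk + seq_len(d[3])]
    tot <- tot + ones[di + seq_len(d[1]), dj + seq_len(d[2]), dk + seq_len(d[3])]
  }
  cnt * 2 > tot
}

#' 3D median smoothing of a 3-class mask
#'
#' A direct median across the codes \{0, 1, 2\} could fabricate label 1
#' between background and spine regions, so filtering is per-class binary
#' with a (5, 5, 5) majority window, merged with priority spine > thorax >
#' background; voxels claimed by no class become background. The window acts
#' in index space exactly as stated by its size, despite the slice-direction
#' anisotropy.
#'
#' @param mask a [label_mask()].
#' @return the smoothed [label_mask()].
#' @export
median_smooth <- function(mask) {
  if (!inherits(mask, "label_mask")) stopf("'mask' must be a label_mask")
  sp <- binary_median5(mask$labels == 2L)
  th <- binary_median5(mask$labels == 1L)
  out <- array(0L, dim(mask$labels))
  out[th] <- 1L
  out[sp] <- 2L
  label_mask(out, pixel_spacing = mask$pixel_spacing,
             z_positions = mask$z_positions)
}
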