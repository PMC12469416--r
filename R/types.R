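## Core containers: an annotated grayscale volume with physical geometry and
## a 3-class label mask sharing its grid. Both are light S3 records; every
## physical measurement downstream reads geometry from these, never from
## array indices alone.

CLASS_CODES <- c(background = 0L, thorax = 1L, spine = 2L)

#' Construct an annotated image volume
#'
#' A grayscale 3D volume together with the physical geometry needed for
#' measurement: isotropic in-plane pixel spacing and the ordered physical
#' z-position of every axial slice. Slice positions may be non-uniform, as in
#' sparse axial chest MRI where 4 mm slices are separated by 20-25 mm gaps.
#'
#' @param voxels numeric 3D array, dimensions (rows, cols, slices) = (H, W, D).
#' @param pixel_spacing length-2 numeric, in-plane spacing in mm (row, col).
#' @param z_positions length-D numeric, strictly increasing slice centers (mm).
#' @param intensity_range optional length-2 numeric recording the raw data
#'   range before normalization.
#' @return An object of class `annotated_volume`.
#' @export
annotated_volume <- function(voxels, pixel_spacing, z_positions,
                             intensity_range = range(voxels)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stopf("'voxels' must be a 3D array")
  d <- dim(voxels)
  if (any(d < 1L)) stopf("all volume dimensions must be >= 1")
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (length(pixel_spacing) != 2L || any(!is.finite(pixel_spacing)) ||
      any(pixel_spacing <= 0))
    stopf("'pixel_spacing' must be two strictly positive numbers (mm)")
  z_positions <- as.numeric(z_positions)
  if (length(z_positions) != d[3L])
    stopf("'z_positions' has %d entries but the volume has %d slices",
          length(z_positions), d[3L])
  if (d[3L] > 1L && any(diff(z_positions) <= 0))
    stopf("'z_positions' must be strictly increasing")
  structure(
    list(voxels = voxels,
         pixel_spacing = pixel_spacing,
         z_positions = z_positions,
         intensity_range = as.numeric(intensity_range)),
    class = "annotated_volume")
}

#' @export
print.annotated_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<annotated_volume> %d x %d x %d voxels\n", d[1], d[2], d[3]))
  cat(sprintf("  pixel spacing : %.5g x %.5g mm\n",
              x$pixel_spacing[1], x$pixel_spacing[2]))
  cat(sprintf("  z extent      : [%.1f, %.1f] mm over %d slices\n",
              min(x$z_positions), max(x$z_positions), d[3]))
  cat(sprintf("  intensities   : [%.4g, %.4g]\n",
              x$intensity_range[1], x$intensity_range[2]))
  invisible(x)
}

#' Construct a 3-class label mask on a volume grid
#'
#' Class codes: 0 background, 1 thoracic volume (excluding spine), 2 spine.
#'
#' @param labels integer 3D array with values in \{0, 1, 2\}.
#' @param volume optional paired [annotated_volume()]; when given, shape and
#'   geometry are checked and attached.
#' @param pixel_spacing,z_positions geometry, when no paired volume is given.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, volume = NULL, pixel_spacing = NULL,
                       z_positions = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stopf("'labels' must be a 3D array")
  u <- unique(as.vector(labels))
  if (!all(u %in% c(0, 1, 2)))
    stopf("mask contains class codes outside {0, 1, 2}: %s",
          paste(sort(setdiff(u, 0:2)), collapse = ", "))
  storage.mode(labels) <- "integer"
  if (!is.null(volume)) {
    if (!identical(dim(labels), dim(volume$voxels)))
      stopf("mask shape (%s) does not match its paired volume (%s)",
            paste(dim(labels), collapse = "x"),
            paste(dim(volume$voxels), collapse = "x"))
    pixel_spacing <- volume$pixel_spacing
    z_positions <- volume$z_positions
  }
  if (is.null(pixel_spacing) || is.null(z_positions))
    stopf("a label_mask needs geometry: give 'volume' or pixel_spacing + z_positions")
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (any(pixel_spacing <= 0)) stopf("'pixel_spacing' must be positive")
  z_positions <- as.numeric(z_positions)
  if (length(z_positions) != dim(labels)[3L])
    stopf("'z_positions' has %d entries but the mask has %d slices",
          length(z_positions), dim(labels)[3L])
  if (length(z_positions) > 1L && any(diff(z_positions) <= 0))
    stopf("'z_positions' must be strictly increasing")
  structure(
    list(labels = labels,
         pixel_spacing = pixel_spacing,
         z_positions = z_positions,
         class_codes = CLASS_CODES),
    class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$labels)
  tab <- tabulate(as.vector(x$labels) + 1L, nbins = 3L)
  cat(sprintf("<label_mask> %d x %d x %d voxels\n", d[1], d[2], d[3]))
  cat(sprintf("  background %d | thorax %d | spine %d\n", tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Extract measurement geometry from a volume or mask
#'
#' @param x an [annotated_volume()] or [label_mask()].
#' @return list with `pixel_spacing` (mm) and `z_positions` (mm).
#' @export
geometry_of <- function(x) {
  if (!inherits(x, c("annotated_volume", "label_mask")))
    stopf("'x' must be an annotated_volume or label_mask")
  list(pixel_spacing = x$pixel_spacing, z_positions = x$z_positions)
}
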