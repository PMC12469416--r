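## NIfTI input/output. Images and masks are written as .nii.gz with the
## affine encoding in-plane pixel spacing and the mean slice spacing; sparse
## acquisitions with non-uniform slice positions additionally carry a JSON
## sidecar ("<stem>.zpos.json", field z_positions_mm) holding the exact slice
## centers, which takes precedence on read.

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", "", path, ignore.case = TRUE) |> paste0(".zpos.json")
}

volume_affine <- function(pixel_spacing, z_positions) {
  dz <- if (length(z_positions) > 1L) mean(diff(z_positions)) else 1
  aff <- diag(c(pixel_spacing[1], pixel_spacing[2], dz, 1))
  aff[3, 4] <- z_positions[1]
  structure(aff, code = 2L)
}

#' Write a volume to NIfTI
#'
#' @param vol an [annotated_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!inherits(vol, "annotated_volume")) stopf("'vol' must be an annotated_volume")
  img <- RNifti::asNifti(vol$voxels, datatype = "double")
  img <- RNifti::`sform<-`(img, volume_affine(vol$pixel_spacing, vol$z_positions))
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(z_positions_mm = vol$z_positions,
         pixel_spacing_mm = vol$pixel_spacing,
         intensity_range = vol$intensity_range),
    sidecar_path(path), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

read_geometry <- function(img, path, n_slices) {
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    side <- jsonlite::read_json(sp, simplifyVector = TRUE)
    z <- as.numeric(side$z_positions_mm)
    if (length(z) != n_slices)
      stopf("z-positions sidecar lists %d values but the volume has %d slices",
            length(z), n_slices)
    px <- as.numeric(side$pixel_spacing_mm)
    list(pixel_spacing = px, z_positions = z,
         intensity_range = side$intensity_range)
  } else {
    pd <- RNifti::pixdim(img)
    z0 <- RNifti::xform(img)[3, 4]
    list(pixel_spacing = pd[1:2],
         z_positions = z0 + (seq_len(n_slices) - 1) * pd[3],
         intensity_range = NULL)
  }
}

#' Read a volume from NIfTI
#'
#' Geometry comes from the JSON sidecar when present (exact, possibly
#' non-uniform slice positions), otherwise from the NIfTI affine (uniform
#' spacing assumed).
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @return an [annotated_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  img <- RNifti::readNifti(path)
  v <- array(as.numeric(img), dim = dim(img))
  if (length(dim(v)) != 3L) stopf("expected a 3D NIfTI volume: %s", path)
  g <- read_geometry(img, path, dim(v)[3])
  annotated_volume(v, g$pixel_spacing, g$z_positions,
                   intensity_range = g$intensity_range %||% range(v))
}

#' Write a label mask to NIfTI
#'
#' @param mask a [label_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!inherits(mask, "label_mask")) stopf("'mask' must be a label_mask")
  img <- RNifti::asNifti(mask$labels, datatype = "int16")
  img <- RNifti::`sform<-`(img, volume_affine(mask$pixel_spacing, mask$z_positions))
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(z_positions_mm = mask$z_positions,
         pixel_spacing_mm = mask$pixel_spacing),
    sidecar_path(path), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a label mask from NIfTI
#'
#' @param path path to the mask file.
#' @param paired_volume optional [annotated_volume()] the mask must pair
#'   with; shape and geometry are then cross-checked.
#' @return a [label_mask()].
#' @export
read_mask <- function(path, paired_volume = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  img <- RNifti::readNifti(path)
  m <- array(as.integer(img), dim = dim(img))
  if (length(dim(m)) != 3L) stopf("expected a 3D NIfTI mask: %s", path)
  g <- read_geometry(img, path, dim(m)[3])
  if (!is.null(paired_volume)) {
    if (!identical(dim(m), dim(paired_volume$voxels)))
      stopf("mask %s does not pair with the volume: shape %s vs %s", path,
            paste(dim(m), collapse = "x"),
            paste(dim(paired_volume$voxels), collapse = "x"))
    if (max(abs(g$z_positions - paired_volume$z_positions)) > 1e-6 ||
        max(abs(g$pixel_spacing - paired_volume$pixel_spacing)) > 1e-6)
      stopf("mask %s does not pair with the volume: geometry differs", path)
    return(label_mask(m, volume = paired_volume))
  }
  label_mask(m, pixel_spacing = g$pixel_spacing, z_positions = g$z_positions)
}

#' Write a per-class probability map as 4D NIfTI
#'
#' Channels are stored on the 4th axis in class-code order.
#'
#' @param prob a `probability_map` (see [predict_unet3d()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probability_map <- function(prob, path) {
  if (!inherits(prob, "probability_map")) stopf("'prob' must be a probability_map")
  p <- aperm(prob$probs, c(2, 3, 4, 1))   # (H, W, D, class)
  img <- RNifti::asNifti(p, datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}
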