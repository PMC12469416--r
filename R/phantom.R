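## Synthetic sparse-slice chest phantoms.
##
## A phantom is a stack of axial sample planes at slice-center positions z_k.
## Each plane renders a thoracic ellipse (semi-axes a_k, b_k) containing a
## circular spine cross-section whose center follows a parametric lateral/AP
## curve in z. Every vertebra_period-th slice additionally carries a posterior
## spinous-process bar, reproducing the center-of-mass shift that alternating
## vertebra/disk slice sampling causes in real sparse stacks. The inter-slice
## gaps are deliberately NOT rendered: the acquisition never observes them, so
## slab integration is the quantification module's decision, not the
## generator's.

#' Specify a synthetic chest phantom
#'
#' Defaults emulate a sparse axial T2w chest acquisition: 4 mm slices with
#' 20-25 mm gaps, 12-17 slices, isotropic in-plane pixels of 0.46875-0.625 mm.
#' The `tiny` preset (64x64 in-plane at 4 mm pixels) keeps the same physical
#' anatomy on a coarse grid for fast CPU training tests; the study
#' pixel-spacing range is only enforced for `preset = "study"`.
#'
#' @param cohort `"child"` or `"adult"`; affects nothing directly but is
#'   carried into reports.
#' @param n_slices number of axial slices (12-17 for the study preset).
#' @param slice_thickness slice thickness in mm (default 4).
#' @param inter_slice_gap gap between consecutive slices in mm (20-25 for the
#'   study preset); slice-center spacing is `slice_thickness + inter_slice_gap`.
#' @param pixel_spacing isotropic in-plane pixel size in mm.
#' @param in_plane_size image matrix size (pixels per side).
#' @param thorax_axes 2-column matrix (or length-2 vector recycled) of
#'   per-slice ellipse semi-axes `a_k` (left-right) and `b_k` (AP), in mm.
#' @param spine_curve list with `amplitude_x`, `amplitude_y` (mm),
#'   `wavelength` (mm) and `phase` (rad) of the spine-center deviation vs z.
#' @param spine_center length-2 base position (x, y) of the spine in mm,
#'   relative to the thorax center; positive y is posterior.
#' @param spine_radius spine cross-section radius in mm.
#' @param process_length posterior spinous-process bar length in mm on
#'   vertebra-type slices (0 disables).
#' @param vertebra_period every `vertebra_period`-th slice is vertebra-type
#'   and carries the process bar.
#' @param noise_sigma additive Gaussian intensity noise (arbitrary units).
#' @param seed integer RNG seed for the noise.
#' @param preset `"study"` (enforce acquisition-range invariants) or `"tiny"`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(cohort = c("adult", "child"),
                         n_slices = 14L,
                         slice_thickness = 4,
                         inter_slice_gap = 24,
                         pixel_spacing = 0.5,
                         in_plane_size = 256L,
                         thorax_axes = c(55, 40),
                         spine_curve = list(amplitude_x = 10, amplitude_y = 4,
                                            wavelength = 350, phase = 0),
                         spine_center = NULL,
                         spine_radius = 12,
                         process_length = 20,
                         vertebra_period = 2L,
                         noise_sigma = 10,
                         seed = 1L,
                         preset = c("study", "tiny")) {
  cohort <- match.arg(cohort)
  preset <- match.arg(preset)
  n_slices <- as.integer(n_slices)
  if (is.null(dim(thorax_axes)))
    thorax_axes <- matrix(rep(as.numeric(thorax_axes), length.out = 2L),
                          nrow = n_slices, ncol = 2L, byrow = TRUE)
  thorax_axes <- as.matrix(thorax_axes)
  if (nrow(thorax_axes) == 1L)
    thorax_axes <- thorax_axes[rep(1L, n_slices), , drop = FALSE]
  if (is.null(spine_center))
    spine_center <- c(0, 0.35 * mean(thorax_axes[, 2L]))
  spec <- structure(
    list(cohort = cohort, n_slices = n_slices,
         slice_thickness = as.numeric(slice_thickness),
         inter_slice_gap = as.numeric(inter_slice_gap),
         pixel_spacing = as.numeric(pixel_spacing),
         in_plane_size = as.integer(in_plane_size),
         thorax_axes = thorax_axes,
         spine_curve = spine_curve,
         spine_center = as.numeric(spine_center),
         spine_radius = as.numeric(spine_radius),
         process_length = as.numeric(process_length),
         vertebra_period = as.integer(vertebra_period),
         noise_sigma = as.numeric(noise_sigma),
         seed = as.integer(seed),
         preset = preset),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' Validate a phantom specification
#'
#' Checks positivity of all spacings, the study acquisition ranges when
#' `preset = "study"`, that the thorax ellipse fits the field of view, and
#' that the spine tube (plus process bar) stays inside the thorax ellipse on
#' every slice. Errors name the offending field.
#'
#' @param spec a [phantom_spec()].
#' @return `spec`, invisibly.
#' @export
validate_phantom_spec <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stopf("not a phantom_spec")
  assert_pos(spec$slice_thickness, "slice_thickness")
  assert_pos(spec$inter_slice_gap, "inter_slice_gap")
  assert_pos(spec$pixel_spacing, "pixel_spacing")
  assert_pos(spec$spine_radius, "spine_radius")
  if (spec$process_length < 0) stopf("'process_length' must be >= 0")
  if (spec$vertebra_period < 1L) stopf("'vertebra_period' must be >= 1")
  if (spec$noise_sigma < 0) stopf("'noise_sigma' must be >= 0")
  if (spec$in_plane_size < 8L) stopf("'in_plane_size' must be >= 8 pixels")
  if (spec$preset == "study") {
    if (spec$n_slices < 12L || spec$n_slices > 17L)
      stopf("'n_slices' must be in [12, 17] for the study preset, got %d",
            spec$n_slices)
    if (spec$inter_slice_gap < 20 || spec$inter_slice_gap > 25)
      stopf("'inter_slice_gap' must be in [20, 25] mm for the study preset")
    if (spec$pixel_spacing < 0.46875 || spec$pixel_spacing > 0.625)
      stopf("'pixel_spacing' must be in [0.46875, 0.625] mm for the study preset")
  } else if (spec$n_slices < 2L) {
    stopf("'n_slices' must be >= 2")
  }
  if (nrow(spec$thorax_axes) != spec$n_slices)
    stopf("'thorax_axes' must have one row per slice (%d), got %d",
          spec$n_slices, nrow(spec$thorax_axes))
  if (any(spec$thorax_axes <= 0)) stopf("'thorax_axes' must be positive (mm)")
  fov <- spec$in_plane_size * spec$pixel_spacing
  if (2 * max(spec$thorax_axes[, 1L]) >= fov ||
      2 * max(spec$thorax_axes[, 2L]) >= fov)
    stopf("'thorax_axes' do not fit the %.1f mm field of view ('in_plane_size' x 'pixel_spacing')",
          fov)
  sc <- spec$spine_curve
  for (f in c("amplitude_x", "amplitude_y", "wavelength", "phase"))
    if (is.null(sc[[f]]) || !is.finite(sc[[f]]))
      stopf("'spine_curve$%s' must be a finite number", f)
  if (sc$wavelength <= 0) stopf("'spine_curve$wavelength' must be positive")
  ## spine containment: sample the tube boundary (and process-bar corners) on
  ## every slice and require all points strictly inside the ellipse
  ctr <- spine_centers(spec)
  th <- seq(0, 2 * pi, length.out = 33L)[-33L]
  for (k in seq_len(spec$n_slices)) {
    a <- spec$thorax_axes[k, 1L]; b <- spec$thorax_axes[k, 2L]
    px <- ctr[k, 1L] + spec$spine_radius * cos(th)
    py <- ctr[k, 2L] + spec$spine_radius * sin(th)
    if (spec$process_length > 0) {
      w <- 0.3 * spec$spine_radius
      bx <- ctr[k, 1L] + c(-w, w, -w, w)
      by <- ctr[k, 2L] + spec$spine_radius + c(0, 0, spec$process_length,
                                               spec$process_length)
      px <- c(px, bx); py <- c(py, by)
    }
    if (any((px / a)^2 + (py / b)^2 >= 1))
      stopf("'spine_curve'/'spine_center'/'spine_radius': spine leaves the thorax ellipse on slice %d", k)
  }
  invisible(spec)
}

## Slice-center z positions (mm), starting at 0.
phantom_z_positions <- function(spec) {
  (seq_len(spec$n_slices) - 1L) * (spec$slice_thickness + spec$inter_slice_gap)
}

## Spine-center (x, y) per slice, in mm relative to the thorax center.
spine_centers <- function(spec) {
  z <- phantom_z_positions(spec)
  sc <- spec$spine_curve
  th <- 2 * pi * z / sc$wavelength + sc$phase
  cbind(x = spec$spine_center[1L] + sc$amplitude_x * sin(th),
        y = spec$spine_center[2L] + sc$amplitude_y * sin(th))
}

#' Analytic 3D spinal length of a phantom
#'
#' The length of the polyline through the spine-curve samples at the slice
#' z-positions: `sum_k ||c(z_{k+1}) - c(z_k)||`, in cm. This is the exact
#' value that center-of-mass quantification recovers on a noise-free phantom
#' without process bars.
#'
#' @param spec a valid [phantom_spec()].
#' @return spinal length in cm.
#' @export
analytic_spine_length <- function(spec) {
  validate_phantom_spec(spec)
  ctr <- spine_centers(spec)
  z <- phantom_z_positions(spec)
  seg <- sqrt(diff(ctr[, 1L])^2 + diff(ctr[, 2L])^2 + diff(z)^2)
  sum(seg) / 10
}

#' Analytic thoracic volume of a phantom
#'
#' Ellipse-stack integral `sum_k pi a_k b_k dz_k` in liters, with the same
#' center-to-center slab widths the quantification module uses (end slices
#' take the full distance to their single neighbour), so a uniform stack of n
#' slices spaced s integrates a height of n*s.
#'
#' @param spec a valid [phantom_spec()].
#' @return thoracic volume in liters.
#' @export
analytic_thoracic_volume <- function(spec) {
  validate_phantom_spec(spec)
  z <- phantom_z_positions(spec)
  dz <- slab_widths(z, spec$slice_thickness)
  areas <- pi * spec$thorax_axes[, 1L] * spec$thorax_axes[, 2L]
  sum(areas * dz) / 1e6
}

#' Generate a synthetic chest phantom
#'
#' Renders the phantom onto its pixel grid and returns the image, the exact
#' 3-class ground-truth mask (0 background, 1 thorax-not-spine, 2 spine), and
#' the analytic truth record. Intensities are class-dependent means
#' (background 30, thorax 120, spine 200) plus additive Gaussian noise of
#' standard deviation `noise_sigma`, reproducible under `spec$seed`.
#'
#' @param spec a valid [phantom_spec()].
#' @return list with `volume` ([annotated_volume()]), `mask` ([label_mask()])
#'   and `truth` (class `phantom_truth`: `analytic_volume` in L,
#'   `analytic_length` in cm, `curve_samples` as an n_slices x 3 matrix of
#'   (x, y, z) mm, and the generating `spec`).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  n <- spec$in_plane_size
  px <- spec$pixel_spacing
  ## pixel-center physical coords, symmetric about the grid center
  coord <- (seq_len(n) - (n + 1) / 2) * px
  X <- matrix(coord, n, n, byrow = FALSE)   # rows vary: x (left-right)
  Y <- matrix(coord, n, n, byrow = TRUE)    # cols vary: y (AP, + posterior)
  z <- phantom_z_positions(spec)
  ctr <- spine_centers(spec)
  labels <- array(0L, dim = c(n, n, spec$n_slices))
  for (k in seq_len(spec$n_slices)) {
    a <- spec$thorax_axes[k, 1L]; b <- spec$thorax_axes[k, 2L]
    thorax <- (X / a)^2 + (Y / b)^2 <= 1
    spine <- (X - ctr[k, 1L])^2 + (Y - ctr[k, 2L])^2 <= spec$spine_radius^2
    if (spec$process_length > 0 && (k - 1L) %% spec$vertebra_period == 0L) {
      w <- 0.3 * spec$spine_radius
      bar <- abs(X - ctr[k, 1L]) <= w &
        Y >= ctr[k, 2L] & Y <= ctr[k, 2L] + spec$spine_radius + spec$process_length
      spine <- spine | bar
    }
    sl <- matrix(0L, n, n)
    sl[thorax] <- 1L
    sl[spine] <- 2L        # spine rendered inside thorax; final classes disjoint
    labels[, , k] <- sl
  }
  means <- c(30, 120, 200)[labels + 1L]
  img <- array(means, dim = dim(labels))
  if (spec$noise_sigma > 0) {
    img <- img + with_seed_(spec$seed,
      array(stats::rnorm(length(img), 0, spec$noise_sigma), dim = dim(img)))
  }
  vol <- annotated_volume(img, pixel_spacing = c(px, px), z_positions = z)
  mask <- label_mask(labels, volume = vol)
  truth <- structure(
    list(analytic_volume = analytic_thoracic_volume(spec),
         analytic_length = analytic_spine_length(spec),
         curve_samples = cbind(ctr, z = z),
         spec = spec),
    class = "phantom_truth")
  list(volume = vol, mask = mask, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> volume %.3f L, spinal length %.2f cm, %d slices\n",
              x$analytic_volume, x$analytic_length, nrow(x$curve_samples)))
  invisible(x)
}

## Draw one subject spec for a cohort. Adults draw study-scale chests; the
## child cohort scales thorax axes and stack height by a factor in
## [0.6, 0.75], reproducing the roughly 2.4-3 L child vs 5-10 L adult volume
## ratio. All draws come from the stream seeded by the caller.
draw_subject_spec <- function(cohort, preset, id) {
  a <- stats::runif(1, 85, 105)
  b <- stats::runif(1, 60, 75)
  n_slices <- sample(14:17, 1)
  if (cohort == "child") {
    s <- stats::runif(1, 0.6, 0.75)
    a <- a * s; b <- b * s
    n_slices <- sample(12:14, 1)
  }
  gap <- stats::runif(1, 20, 25)
  radius <- stats::runif(1, 0.18, 0.24) * b
  stack_h <- (n_slices - 1) * (gap + 4)
  curve <- list(amplitude_x = stats::runif(1, 0.05, 0.18) * a,
                amplitude_y = stats::runif(1, 0.02, 0.08) * b,
                wavelength = stack_h * stats::runif(1, 1.2, 2.2),
                phase = stats::runif(1, 0, 2 * pi))
  seed <- sample.int(.Machine$integer.max, 1)
  if (preset == "tiny") {
    px <- 4
    size <- 64L
  } else {
    px <- stats::runif(1, 0.46875, 0.625)
    ## smallest multiple of 32 whose field of view clears the chest by 10 mm
    size <- as.integer(32 * ceiling((2 * (a + 10) / px) / 32))
  }
  ## taper the chest slightly toward both stack ends
  taper <- 1 - 0.12 * abs(2 * (seq_len(n_slices) - 1) / (n_slices - 1) - 1)
  cy0 <- 0.08 * b
  ## posterior process sized to stay inside the most tapered ellipse
  allowed <- 0.78 * b * min(taper) - (cy0 + curve$amplitude_y + radius)
  process <- max(0, min(1.2 * radius, allowed))
  phantom_spec(cohort = cohort, n_slices = n_slices,
               inter_slice_gap = gap, pixel_spacing = px,
               in_plane_size = size,
               thorax_axes = cbind(a * taper, b * taper),
               spine_curve = curve,
               spine_center = c(0, cy0),
               spine_radius = radius,
               process_length = process,
               vertebra_period = 2L,
               noise_sigma = 10,
               seed = seed,
               preset = preset)
}

#' Draw a cohort of phantom subjects with a train/test split
#'
#' Emulates the study cohort: children draw smaller thoraces and shorter
#' stacks than adults. The split is stratified so both cohorts appear in both
#' partitions whenever counts allow. Phantoms themselves are generated lazily
#' with [generate_phantom()] on each subject's spec.
#'
#' @param n_child,n_adult subject counts (>= 0).
#' @param seed integer seed; the cohort is reproducible under it.
#' @param n_test number of held-out test subjects (default 0: all train).
#' @param preset `"study"` or `"tiny"` grids (see [phantom_spec()]).
#' @return data.frame with columns `subject`, `cohort`, `split`, and a
#'   list-column `spec` of [phantom_spec()] objects.
#' @export
make_cohort <- function(n_child, n_adult, seed = 1L, n_test = 0L,
                        preset = c("study", "tiny")) {
  preset <- match.arg(preset)
  if (n_child < 0 || n_adult < 0) stopf("subject counts must be >= 0")
  n <- n_child + n_adult
  if (n_test < 0 || n_test > n) stopf("'n_test' must be in [0, %d]", n)
  cohorts <- rep(c("child", "adult"), c(n_child, n_adult))
  out <- with_seed_(seed, {
    specs <- lapply(seq_len(n), function(i)
      draw_subject_spec(cohorts[i], preset, i))
    ## stratified test draw: proportional per cohort, at least one from each
    ## non-empty cohort when n_test allows
    split <- rep("train", n)
    if (n_test > 0L) {
      idx_c <- which(cohorts == "child"); idx_a <- which(cohorts == "adult")
      t_c <- round(n_test * length(idx_c) / n)
      if (length(idx_c) > 0L && length(idx_a) > 0L)
        t_c <- min(max(t_c, 1L), n_test - 1L, length(idx_c))
      t_c <- max(min(t_c, length(idx_c)), n_test - length(idx_a))
      test <- c(if (t_c > 0L) sample(idx_c, t_c),
                if (n_test - t_c > 0L) sample(idx_a, n_test - t_c))
      split[test] <- "test"
    }
    list(specs = specs, split = split)
  })
  df <- data.frame(subject = seq_len(n),
                   cohort = cohorts,
                   split = out$split,
                   stringsAsFactors = FALSE)
  df$spec <- out$specs
  df
}
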