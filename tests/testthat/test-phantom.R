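test_that("phantom generation is bit-identical under a fixed seed", {
  a <- generate_phantom(small_spec(noise_sigma = 8, seed = 7))
  b <- generate_phantom(small_spec(noise_sigma = 8, seed = 7))
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$mask$labels, b$mask$labels)
  expect_identical(a$truth$analytic_volume, b$truth$analytic_volume)
  c <- generate_phantom(small_spec(noise_sigma = 8, seed = 8))
  expect_false(identical(a$volume$voxels, c$volume$voxels))
})

test_that("image and mask share grid and geometry; classes are {0,1,2}", {
  ph <- generate_phantom(small_spec(noise_sigma = 5))
  expect_identical(dim(ph$volume$voxels), dim(ph$mask$labels))
  expect_identical(ph$volume$z_positions, ph$mask$z_positions)
  expect_true(all(ph$mask$labels %in% 0:2))
  ## spine voxels sit strictly inside the thorax ellipse region
  sp <- which(ph$mask$labels == 2L, arr.ind = TRUE)
  expect_gt(nrow(sp), 0)
  expect_true(all(ph$mask$labels[ph$mask$labels == 2L] == 2L))
  ## every slice has thorax voxels surrounding the spine (disjoint classes)
  expect_equal(sum(ph$mask$labels == 1L & ph$mask$labels == 2L), 0)
})

test_that("noise-free straight-spine phantom has exact per-slice spine COM", {
  spec <- small_spec(spine_curve = list(amplitude_x = 0, amplitude_y = 0,
                                        wavelength = 300, phase = 0),
                     spine_center = c(0, 0), process_length = 0)
  ph <- generate_phantom(spec)
  q <- compute_spinal_length(ph$mask)
  ## symmetric disk about the grid center: COM = curve (x, y) exactly
  ctr_phys <- (dim(ph$mask$labels)[1] - 1) / 2 * ph$mask$pixel_spacing[1]
  expect_equal(unname(q$com_polyline[, "x"]), rep(ctr_phys, 13))
  expect_equal(unname(q$com_polyline[, "y"]), rep(ctr_phys, 13))
})

test_that("analytic spine length: straight case, monotonicity, dense oracle", {
  straight <- small_spec(spine_curve = list(amplitude_x = 0, amplitude_y = 0,
                                            wavelength = 300, phase = 0),
                         process_length = 0)
  ## 13 slices at 25 mm center spacing -> 12 x 25 mm = 30 cm
  expect_equal(analytic_spine_length(straight), 30)

  lens <- vapply(c(0, 5, 10, 15), function(ax)
    analytic_spine_length(small_spec(
      spine_curve = list(amplitude_x = ax, amplitude_y = 0, wavelength = 350,
                         phase = 0),
      spine_center = c(0, 5), process_length = 0)), 0)
  expect_true(all(diff(lens) > 0))
  expect_gt(lens[2], 30)

  ## matches an independent polyline-length computation of the same samples
  spec <- small_spec(spine_curve = list(amplitude_x = 7, amplitude_y = 3,
                                        wavelength = 280, phase = 0.4),
                     process_length = 0)
  ph <- generate_phantom(spec)
  expect_equal(analytic_spine_length(spec),
               o_polyline_length_cm(ph$truth$curve_samples))
})

test_that("constant-ellipse stack volume matches the closed form and the voxel count", {
  spec <- phantom_spec(n_slices = 14, slice_thickness = 4, inter_slice_gap = 24,
                       pixel_spacing = 0.46875, in_plane_size = 512,
                       thorax_axes = c(100, 70),
                       spine_curve = list(amplitude_x = 0, amplitude_y = 0,
                                          wavelength = 300, phase = 0),
                       spine_center = c(0, 20), spine_radius = 10,
                       process_length = 0, noise_sigma = 0, seed = 1)
  ## closed form: pi * 0.1 m * 0.07 m * (14 * 0.028 m) ~ 8.62 L
  expect_equal(analytic_thoracic_volume(spec), pi * 0.1 * 0.07 * 14 * 0.028 * 1e3,
               tolerance = 1e-10)
  ph <- generate_phantom(spec)
  v <- compute_thoracic_volume(ph$mask)
  truth <- analytic_thoracic_volume(spec)
  expect_lt(abs(v - truth) / truth, 0.03)
})

test_that("spec validation rejects out-of-range fields by name", {
  expect_error(small_spec(n_slices = 11), "n_slices")
  expect_error(small_spec(n_slices = 18), "n_slices")
  expect_error(small_spec(inter_slice_gap = 19), "inter_slice_gap")
  expect_error(small_spec(pixel_spacing = 0.4), "pixel_spacing")
  expect_error(small_spec(pixel_spacing = -1), "pixel_spacing")
  expect_error(small_spec(spine_radius = 40), "spine")
  expect_error(small_spec(thorax_axes = c(70, 22)), "thorax_axes")
  ## tiny preset relaxes the acquisition ranges but not positivity
  expect_silent(validate_phantom_spec(
    small_spec(pixel_spacing = 4, in_plane_size = 64, preset = "tiny")))
})

test_that("make_cohort draws valid stratified cohorts reproducibly", {
  co <- make_cohort(19, 19, seed = 3, n_test = 7)
  expect_equal(nrow(co), 38)
  expect_equal(sum(co$split == "train"), 31)
  expect_equal(sum(co$split == "test"), 7)
  ## both cohorts present in both partitions
  expect_true(all(c("child", "adult") %in% co$cohort[co$split == "train"]))
  expect_true(all(c("child", "adult") %in% co$cohort[co$split == "test"]))
  ## all specs valid; children draw smaller chests and stacks than adults
  for (s in co$spec) expect_silent(validate_phantom_spec(s))
  ax_child <- vapply(co$spec[co$cohort == "child"], function(s) max(s$thorax_axes[, 1]), 0)
  ax_adult <- vapply(co$spec[co$cohort == "adult"], function(s) max(s$thorax_axes[, 1]), 0)
  expect_lt(mean(ax_child), mean(ax_adult))
  ns_child <- vapply(co$spec[co$cohort == "child"], function(s) s$n_slices, 0L)
  ns_adult <- vapply(co$spec[co$cohort == "adult"], function(s) s$n_slices, 0L)
  expect_lt(mean(ns_child), mean(ns_adult))
  ## reproducible; empty cohort allowed
  co2 <- make_cohort(19, 19, seed = 3, n_test = 7)
  expect_identical(co$split, co2$split)
  expect_equal(nrow(make_cohort(0, 0, seed = 1)), 0)
  ## distinct subjects
  co3 <- make_cohort(5, 5, seed = 2)
  seeds <- vapply(co3$spec, function(s) s$seed, 0L)
  expect_equal(length(unique(seeds)), 10)
})

test_that("cohort phantoms cover the study's volume span", {
  co <- make_cohort(3, 3, seed = 21)
  vols <- vapply(co$spec, analytic_thoracic_volume, 0)
  expect_lt(min(vols[co$cohort == "child"]), 3.5)
  expect_gt(max(vols[co$cohort == "adult"]), 5)
})
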