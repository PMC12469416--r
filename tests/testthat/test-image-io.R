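test_that("NIfTI round-trip preserves voxels and geometry to 1e-6 mm", {
  ph <- generate_phantom(small_spec(noise_sigma = 6, seed = 2))
  td <- withr::local_tempdir()
  vp <- file.path(td, "vol.nii.gz")
  mp <- file.path(td, "mask.nii.gz")
  write_volume(ph$volume, vp)
  write_mask(ph$mask, mp)
  v2 <- read_volume(vp)
  m2 <- read_mask(mp, paired_volume = v2)
  expect_equal(v2$voxels, ph$volume$voxels)
  expect_lt(max(abs(v2$z_positions - ph$volume$z_positions)), 1e-6)
  expect_lt(max(abs(v2$pixel_spacing - ph$volume$pixel_spacing)), 1e-6)
  expect_identical(m2$labels, ph$mask$labels)
})

test_that("mask reading rejects invalid class codes and geometry mismatches", {
  ph <- generate_phantom(small_spec())
  td <- withr::local_tempdir()
  bad <- ph$mask$labels
  bad[1, 1, 1] <- 3L
  img <- RNifti::asNifti(bad, datatype = "int16")
  p <- file.path(td, "bad.nii.gz")
  RNifti::writeNifti(img, p)
  expect_error(read_mask(p), "class codes")

  ## sidecar listing one fewer z-position than slices -> pairing error
  vp <- file.path(td, "vol.nii.gz")
  write_volume(ph$volume, vp)
  side <- jsonlite::read_json(file.path(td, "vol.zpos.json"),
                              simplifyVector = TRUE)
  side$z_positions_mm <- side$z_positions_mm[-1]
  jsonlite::write_json(side, file.path(td, "vol.zpos.json"), digits = NA)
  expect_error(read_volume(vp), "sidecar")

  ## mask that does not pair with its volume
  mp <- file.path(td, "m.nii.gz")
  write_mask(label_mask(ph$mask$labels[, , 1:5],
                        pixel_spacing = ph$mask$pixel_spacing,
                        z_positions = ph$mask$z_positions[1:5]), mp)
  expect_error(read_mask(mp, paired_volume = ph$volume), "pair")
})

test_that("min-max normalization maps extremes exactly and is affine-invariant", {
  v <- annotated_volume(array(c(0, 5, 10, 2, 7, 3), c(1, 2, 3)),
                        c(1, 1), c(0, 10, 20))
  n <- minmax_normalize(v)
  expect_equal(n$voxels[1, 1, 1], 0)
  expect_equal(n$voxels[1, 1, 2], 1)
  expect_equal(n$voxels[1, 2, 1], 0.5)

  ph <- generate_phantom(small_spec(noise_sigma = 9, seed = 4))
  n1 <- minmax_normalize(ph$volume)
  expect_equal(min(n1$voxels), 0)
  expect_equal(max(n1$voxels), 1)
  ## invariance under positive affine intensity rescaling
  resc <- annotated_volume(3.7 * ph$volume$voxels - 12, ph$volume$pixel_spacing,
                           ph$volume$z_positions)
  expect_equal(minmax_normalize(resc)$voxels, n1$voxels, tolerance = 1e-12)
  ## idempotence on data already spanning [0, 1]
  expect_equal(minmax_normalize(n1)$voxels, n1$voxels, tolerance = 1e-12)
  ## constant volume -> zeros with a warning
  const <- annotated_volume(array(5, c(2, 2, 2)), c(1, 1), c(0, 10))
  expect_warning(z <- minmax_normalize(const), "constant")
  expect_true(all(z$voxels == 0))
})

test_that("model-grid resampling honors shape, class, and round-trip contracts", {
  ph <- generate_phantom(small_spec(n_slices = 12, noise_sigma = 5, seed = 3))
  pair <- to_model_grid(minmax_normalize(ph$volume), ph$mask,
                        shape = c(240, 240, 16))
  expect_identical(dim(pair$image), c(1L, 240L, 240L, 16L))
  expect_identical(dim(pair$mask), c(240L, 240L, 16L))
  expect_gte(min(pair$image), 0)
  expect_lte(max(pair$image), 1)
  ## nearest neighbour cannot invent class codes
  expect_true(all(unique(as.vector(pair$mask)) %in%
                    unique(as.vector(ph$mask$labels))))
  ## inverting recovers the native 12-slice grid
  back <- resample_back(pair$mask, pair$provenance)
  expect_identical(dim(back$labels), dim(ph$mask$labels))
  ## per-class voxel fractions survive the round trip within 10%
  for (cls in 0:2) {
    f0 <- mean(ph$mask$labels == cls)
    f1 <- mean(back$labels == cls)
    expect_lt(abs(f1 - f0) / f0, 0.10)
  }
  ## identity resampling: mask bit-identical, image almost unchanged
  pair2 <- to_model_grid(minmax_normalize(ph$volume), ph$mask,
                         shape = dim(ph$mask$labels))
  expect_identical(pair2$mask, ph$mask$labels)
  nv <- minmax_normalize(ph$volume)$voxels
  expect_equal(array(pair2$image, dim(nv)), nv, tolerance = 1e-12)
})

test_that("probability maps round-trip through 4D NIfTI", {
  net <- build_unet3d(net_config(depth = 1, base_channels = 2,
                                 in_shape = c(1, 8, 8, 4), seed = 1))
  pair <- structure(list(image = array(0.3, c(1, 8, 8, 4)), mask = NULL,
                         provenance = list()), class = "model_grid_pair")
  prob <- predict_unet3d(net, pair)
  td <- withr::local_tempdir()
  p <- file.path(td, "prob.nii.gz")
  write_probability_map(prob, p)
  back <- RNifti::readNifti(p)
  expect_identical(dim(back), c(8L, 8L, 4L, 3L))
  expect_equal(aperm(array(as.numeric(back), dim(back)), c(4, 1, 2, 3)),
               prob$probs, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("rotation augmentation is a bounded, near-invertible in-plane map", {
  ## fat centered disk on the model grid
  d <- c(64, 64, 8)
  ctr <- (d[1:2] + 1) / 2
  g <- expand.grid(r = 1:d[1], c = 1:d[2])
  disk2d <- matrix((g$r - ctr[1])^2 + (g$c - ctr[2])^2 <= 20^2, d[1], d[2])
  mask <- array(rep(disk2d, d[3]), dim = d) * 1L
  img <- array(0.2 + 0.6 * (mask == 1), dim = d)
  pair <- structure(list(image = array(img, c(1, d)), mask = mask,
                         provenance = list(shape = d, model_shape = d,
                                           pixel_spacing = c(1, 1),
                                           z_positions = seq_len(d[3]))),
                    class = "model_grid_pair")
  expect_error(augment_rotation(pair, 11), "-10, 10")
  ## angle 0 is the identity
  expect_identical(augment_rotation(pair, 0), pair)
  ## +10 then -10 nearly inverts on the raster
  r2 <- augment_rotation(augment_rotation(pair, 10), -10)
  expect_gte(dsc(r2$mask == 1, pair$mask == 1), 0.95)
  ## area conservation within 5% per slice
  a0 <- sum(pair$mask[, , 1] == 1)
  a1 <- sum(augment_rotation(pair, 7.3)$mask[, , 1] == 1)
  expect_lt(abs(a1 - a0) / a0, 0.05)
  ## no fabricated classes, image stays in [0, 1]
  r3 <- augment_rotation(pair, -8.2)
  expect_true(all(r3$mask %in% c(0, 1)))
  expect_gte(min(r3$image), 0)
  expect_lte(max(r3$image), 1)
})
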