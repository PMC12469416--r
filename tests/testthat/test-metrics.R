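test_that("dsc handles identity, disjoint, counted and empty cases", {
  a <- array(FALSE, c(4, 4, 2)); a[1:2, 1:2, 1] <- TRUE
  b <- array(FALSE, c(4, 4, 2)); b[3:4, 3:4, 2] <- TRUE
  expect_equal(dsc(a, a), 1)
  expect_equal(dsc(a, b), 0)
  ## |P| = 4, |G| = 6, overlap 3 -> 0.6
  p <- array(FALSE, c(5, 2, 1)); p[1:4, 1, 1] <- TRUE
  g <- array(FALSE, c(5, 2, 1)); g[2:5, 1, 1] <- TRUE; g[1:2, 2, 1] <- TRUE
  expect_equal(sum(p), 4); expect_equal(sum(g), 6); expect_equal(sum(p & g), 3)
  expect_equal(dsc(p, g), 0.6)
  ## both empty -> 1 by convention (all-background slice is a success)
  e <- array(FALSE, c(3, 3, 1))
  expect_equal(dsc(e, e), 1)
  expect_error(dsc(a, array(FALSE, c(3, 3, 1))), "shape")
})

test_that("precision/recall match counted fixtures and report NA when undefined", {
  ## TP = 3, FP = 1, FN = 2
  p <- array(FALSE, c(6, 1, 1)); p[1:4, 1, 1] <- TRUE
  g <- array(FALSE, c(6, 1, 1)); g[c(1:3, 5:6), 1, 1] <- TRUE
  pr <- precision_recall(p, g)
  expect_equal(unname(pr["precision"]), 0.75)
  expect_equal(unname(pr["recall"]), 0.6)
  expect_equal(unname(precision_recall(g, g)), c(1, 1))
  ## strict over-segmentation: recall 1, precision < 1
  sup <- g; sup[4, 1, 1] <- TRUE
  pr2 <- precision_recall(sup, g)
  expect_equal(unname(pr2["recall"]), 1)
  expect_lt(pr2["precision"], 1)
  ## empty prediction -> precision undefined, not zero
  e <- array(FALSE, c(6, 1, 1))
  expect_true(is.na(precision_recall(e, g)["precision"]))
  expect_true(is.na(precision_recall(g, e)["recall"]))
})

test_that("hausdorff matches hand values and errors on empty masks", {
  geom <- list(pixel_spacing = c(1, 1), z_positions = c(0, 5, 10))
  a <- array(FALSE, c(8, 8, 3)); a[2, 2, 1] <- TRUE
  b <- array(FALSE, c(8, 8, 3)); b[5, 6, 1] <- TRUE
  ## single voxels offset by (3 mm, 4 mm, 0) -> 5 mm
  expect_equal(unname(hausdorff(a, b, geom)["hd"]), 5)
  expect_equal(unname(hausdorff(a, a, geom)), c(0, 0))
  expect_error(hausdorff(a, array(FALSE, c(8, 8, 3)), geom), "empty")
})

test_that("hausdorff agrees exactly with the all-pairs oracle on random masks", {
  set.seed(91)
  for (rep in 1:200) {
    d <- c(sample(3:8, 1), sample(3:8, 1), sample(2:5, 1))
    geom <- list(pixel_spacing = sort(stats::runif(2, 0.4, 2.5)),
                 z_positions = cumsum(stats::runif(d[3], 3, 30)))
    p <- random_small_mask(d, p = stats::runif(1, 0.05, 0.5))
    g <- random_small_mask(d, p = stats::runif(1, 0.05, 0.5))
    got <- hausdorff(p, g, geom)
    want <- o_hausdorff(p, g, geom)
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(dsc(p, g), o_dsc(p, g), tolerance = 1e-15)
    expect_equal(unname(precision_recall(p, g)), o_precision_recall(p, g))
  }
})

test_that("metric symmetries, Dice-F1 identity and spacing-awareness hold", {
  set.seed(17)
  for (rep in 1:25) {
    d <- c(6, 6, 4)
    geom <- list(pixel_spacing = c(0.7, 1.3), z_positions = c(0, 8, 20, 26))
    p <- random_small_mask(d, 0.3); g <- random_small_mask(d, 0.3)
    ## symmetry
    expect_equal(dsc(p, g), dsc(g, p))
    expect_equal(unname(hausdorff(p, g, geom)["hd"]),
                 unname(hausdorff(g, p, geom)["hd"]))
    expect_equal(unname(precision_recall(p, g)["precision"]),
                 unname(precision_recall(g, p)["recall"]))
    ## Dice-F1 identity
    pr <- precision_recall(p, g)
    if (!anyNA(pr) && sum(pr) > 0)
      expect_equal(dsc(p, g), 2 * pr[1] * pr[2] / (pr[1] + pr[2]),
                   tolerance = 1e-12, ignore_attr = TRUE)
    ## doubling spacings doubles HD, leaves overlap metrics unchanged
    geom2 <- list(pixel_spacing = 2 * geom$pixel_spacing,
                  z_positions = 2 * geom$z_positions)
    expect_equal(unname(hausdorff(p, g, geom2)),
                 2 * unname(hausdorff(p, g, geom)), tolerance = 1e-12)
    ## hd95 <= hd always
    h <- hausdorff(p, g, geom)
    expect_lte(h["hd95"], h["hd"])
  }
})

test_that("overlay map partitions voxels into confusion categories", {
  p <- array(FALSE, c(6, 1, 1)); p[1:4, 1, 1] <- TRUE
  g <- array(FALSE, c(6, 1, 1)); g[c(1:3, 5:6), 1, 1] <- TRUE
  ov <- overlay_map(p, g)
  expect_equal(sum(ov == 1), 3)  # TP
  expect_equal(sum(ov == 2), 1)  # FP
  expect_equal(sum(ov == 3), 2)  # FN
  expect_equal(sum(ov == 1) + sum(ov == 2), sum(p))
  expect_true(all(overlay_map(g, g) %in% c(0, 1)))
})

test_that("evaluate_subject scores thorax as chest-wall union and spine separately", {
  ph <- generate_phantom(small_spec(noise_sigma = 0))
  gt <- ph$mask
  rows <- evaluate_subject(gt, gt)
  expect_equal(rows$dsc, c(1, 1))
  expect_equal(rows$hd, c(0, 0))
  ## dilated prediction: recall 1, precision < 1 (over-segmentation regime)
  dil <- gt$labels
  grown <- binary_dilate1(gt$labels >= 1)
  dil[grown & gt$labels == 0L] <- 1L
  pred <- label_mask(dil, pixel_spacing = gt$pixel_spacing,
                     z_positions = gt$z_positions)
  r2 <- evaluate_subject(pred, gt)
  th <- r2[r2$class == "thorax", ]
  expect_equal(th$recall, 1)
  expect_lt(th$precision, 1)
  ## ranges on a random prediction
  noisy <- gt$labels
  set.seed(5)
  flip <- sample(length(noisy), 500)
  noisy[flip] <- sample(0:2, 500, replace = TRUE)
  r3 <- evaluate_subject(label_mask(noisy, pixel_spacing = gt$pixel_spacing,
                                    z_positions = gt$z_positions), gt)
  expect_true(all(r3$dsc >= 0 & r3$dsc <= 1))
  expect_true(all(r3$hd >= 0, na.rm = TRUE))
  expect_true(all(r3$hd95 <= r3$hd, na.rm = TRUE))
})
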