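## Shared fixtures and independent oracles for the test suite.

## A small, fully valid study-geometry phantom spec; overrides via ...
small_spec <- function(..., n_slices = 13, noise_sigma = 0, seed = 1) {
  defaults <- list(
    n_slices = n_slices, slice_thickness = 4, inter_slice_gap = 21,
    pixel_spacing = 0.5, in_plane_size = 128,
    thorax_axes = c(28, 22),
    spine_curve = list(amplitude_x = 4, amplitude_y = 2, wavelength = 300,
                       phase = 0),
    spine_center = c(0, 5), spine_radius = 5, process_length = 5,
    vertebra_period = 2, noise_sigma = noise_sigma, seed = seed)
  do.call(phantom_spec, utils::modifyList(defaults, list(...)))
}

## Random small binary mask with at least one foreground voxel.
random_small_mask <- function(d, p = 0.2) {
  m <- array(stats::runif(prod(d)) < p, dim = d)
  if (!any(m)) m[sample(length(m), 1)] <- TRUE
  m
}

## One-step 6-neighbour binary dilation (fixture construction).
binary_dilate1 <- function(bin) {
  d <- dim(bin)
  out <- bin
  shift <- function(axis, dir) {
    res <- array(FALSE, d)
    n <- d[axis]
    if (n == 1) return(res)
    src <- if (dir > 0) 2:n else 1:(n - 1)
    dst <- if (dir > 0) 1:(n - 1) else 2:n
    ix <- lapply(d, seq_len)
    ixs <- ix; ixs[[axis]] <- src
    ixd <- ix; ixd[[axis]] <- dst
    res[ixd[[1]], ixd[[2]], ixd[[3]]] <- bin[ixs[[1]], ixs[[2]], ixs[[3]]]
    res
  }
  for (axis in 1:3) for (dir in c(-1, 1)) out <- out | shift(axis, dir)
  out
}

## ---- Independent brute-force oracles (straight loops, no shared code) -----

o_dsc <- function(p, g) {
  if (sum(p) + sum(g) == 0) return(1)
  2 * sum(p & g) / (sum(p) + sum(g))
}

o_precision_recall <- function(p, g) {
  tp <- sum(p & g)
  c(if (sum(p) > 0) tp / sum(p) else NA_real_,
    if (sum(g) > 0) tp / sum(g) else NA_real_)
}

## Boundary via explicit neighbour loop: foreground voxel with any of its 6
## face neighbours background or out of bounds.
o_boundary <- function(bin) {
  d <- dim(bin)
  fg <- which(bin, arr.ind = TRUE)
  keep <- logical(nrow(fg))
  for (r in seq_len(nrow(fg))) {
    i <- fg[r, 1]; j <- fg[r, 2]; k <- fg[r, 3]
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    for (q in seq_len(6)) {
      p <- nb[q, ]
      if (p[1] < 1 || p[1] > d[1] || p[2] < 1 || p[2] > d[2] ||
          p[3] < 1 || p[3] > d[3] || !bin[p[1], p[2], p[3]]) {
        keep[r] <- TRUE
        break
      }
    }
  }
  fg[keep, , drop = FALSE]
}

## All-pairs Hausdorff on physical boundary coordinates.
o_hausdorff <- function(p, g, geom) {
  coords <- function(idx)
    cbind((idx[, 1] - 1) * geom$pixel_spacing[1],
          (idx[, 2] - 1) * geom$pixel_spacing[2],
          geom$z_positions[idx[, 3]])
  P <- coords(o_boundary(p)); G <- coords(o_boundary(g))
  dmat <- matrix(0, nrow(P), nrow(G))
  for (a in seq_len(nrow(P)))
    for (b in seq_len(nrow(G)))
      dmat[a, b] <- sqrt(sum((P[a, ] - G[b, ])^2))
  d_pg <- apply(dmat, 1, min)
  d_gp <- apply(dmat, 2, min)
  c(hd = max(max(d_pg), max(d_gp)),
    hd95 = as.numeric(stats::quantile(c(d_pg, d_gp), 0.95, type = 7)))
}

## Dense numerical arc length of the spine curve restricted to slice samples.
o_polyline_length_cm <- function(points) {
  total <- 0
  for (r in 2:nrow(points))
    total <- total + sqrt(sum((points[r, ] - points[r - 1, ])^2))
  total / 10
}
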