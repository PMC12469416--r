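## Neural-network primitives for the volumetric encoder-decoder.
##
## Feature maps are stored as (N_voxels x channels) matrices plus a spatial
## dim attribute c(H, W, D); voxel order is R's column-major array order, so
## matrix(array, N, C) and array(matrix, c(H, W, D, C)) convert losslessly.
## 3x3x3 convolutions are im2col + dense GEMM (zero padding 1, stride 1);
## transpose convolutions use kernel = stride so each output voxel receives
## exactly one contribution and both passes reduce to per-offset GEMMs. All
## operations carry hand-derived backward passes, verified against finite
## differences in the test suite.

fmap <- function(mat, dim) {
  structure(list(mat = mat, dim = as.integer(dim)), class = "fmap")
}

## ---- 3x3x3 convolution ----------------------------------------------------

## Neighbor row-index table for a spatial grid: column o gives, for every
## voxel, the row of its o-th 3x3x3 neighbor (out-of-bounds clamped to row 1,
## with the affected voxels listed in `pad` for explicit zeroing). Offsets
## enumerate di fastest over {-1,0,1}^3, so the mirrored offset of column o
## is column 28-o. Cached per grid since every conv layer reuses it.
.conv_idx_cache <- new.env(parent = emptyenv())

conv_neighbor_index <- function(d) {
  key <- paste(d, collapse = "x")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  H <- d[1]; W <- d[2]; D <- d[3]
  N <- H * W * D
  iv <- rep.int(seq_len(H), W * D)
  jv <- rep.int(rep(seq_len(W), each = H), D)
  kv <- rep(seq_len(D), each = H * W)
  idx <- matrix(1L, N, 27L)
  pad <- vector("list", 27L)
  o <- 0L
  for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
    o <- o + 1L
    ii <- iv + di; jj <- jv + dj; kk <- kv + dk
    ok <- ii >= 1L & ii <= H & jj >= 1L & jj <= W & kk >= 1L & kk <= D
    lin <- (kk - 1L) * (H * W) + (jj - 1L) * H + ii
    idx[ok, o] <- lin[ok]
    pad[[o]] <- which(!ok)
  }
  out <- list(idx = idx, pad = pad)
  .conv_idx_cache[[key]] <- out
  out
}

## (N x 27C) patch matrix; column o + (c-1)*27 holds input channel c at
## neighbor offset o. One big row-gather, then the padded positions zeroed.
im2col3 <- function(mat, d) {
  nb <- conv_neighbor_index(d)
  C <- ncol(mat)
  cols <- mat[as.vector(nb$idx), , drop = FALSE]
  dim(cols) <- c(nrow(mat), 27L * C)
  cols_base <- (seq_len(C) - 1L) * 27L
  for (o in 1:27)
    if (length(nb$pad[[o]])) cols[nb$pad[[o]], cols_base + o] <- 0
  cols
}

## Adjoint of im2col3: scatter patch-gradients back to voxel-gradients via
## the mirrored-offset gather.
col2im3 <- function(gcols, d, C) {
  nb <- conv_neighbor_index(d)
  gx <- matrix(0, nrow(gcols), C)
  cols_base <- (seq_len(C) - 1L) * 27L
  for (o in 1:27) {
    om <- 28L - o
    sub <- gcols[nb$idx[, om], cols_base + o, drop = FALSE]
    if (length(nb$pad[[om]])) sub[nb$pad[[om]], ] <- 0
    gx <- gx + sub
  }
  gx
}

conv3_fw <- function(x, W, b) {
  cols <- im2col3(x$mat, x$dim)
  y <- cols %*% W
  for (c in seq_along(b)) y[, c] <- y[, c] + b[c]
  list(out = fmap(y, x$dim), cols = cols)
}

conv3_bw <- function(cache_cols, x, W, gy) {
  C <- ncol(x$mat)
  list(gx = fmap(col2im3(gy %*% t(W), x$dim, C), x$dim),
       gW = crossprod(cache_cols, gy),
       gb = colSums(gy))
}

## ---- ReLU -----------------------------------------------------------------

relu_fw <- function(x) {
  y <- x$mat
  y[y < 0] <- 0
  fmap(y, x$dim)
}

relu_bw <- function(y, gy) {
  g <- gy
  g[y$mat <= 0] <- 0
  g
}

## ---- Max pooling ----------------------------------------------------------

pool_offsets <- function(f) {
  as.matrix(expand.grid(i = seq_len(f[1]), j = seq_len(f[2]), k = seq_len(f[3])))
}

maxpool_fw <- function(x, f) {
  d <- x$dim
  C <- ncol(x$mat)
  dn <- d %/% f
  x4 <- array(x$mat, c(d, C))
  offs <- pool_offsets(f)
  y <- NULL; amax <- NULL
  for (o in seq_len(nrow(offs))) {
    sub <- x4[seq(offs[o, 1], d[1], f[1]), seq(offs[o, 2], d[2], f[2]),
              seq(offs[o, 3], d[3], f[3]), , drop = FALSE]
    subm <- matrix(sub, prod(dn), C)
    if (is.null(y)) {
      y <- subm
      amax <- matrix(1L, prod(dn), C)
    } else {
      m <- subm > y
      y[m] <- subm[m]
      amax[m] <- o
    }
  }
  list(out = fmap(y, dn), amax = amax)
}

maxpool_bw <- function(gy, amax, in_dim, f) {
  C <- ncol(gy)
  dn <- in_dim %/% f
  gx4 <- array(0, c(in_dim, C))
  offs <- pool_offsets(f)
  for (o in seq_len(nrow(offs))) {
    gsub <- matrix(0, prod(dn), C)
    m <- amax == o
    gsub[m] <- gy[m]
    gx4[seq(offs[o, 1], in_dim[1], f[1]), seq(offs[o, 2], in_dim[2], f[2]),
        seq(offs[o, 3], in_dim[3], f[3]), ] <- array(gsub, c(dn, C))
  }
  fmap(matrix(gx4, prod(in_dim), C), in_dim)
}

## ---- Transpose convolution (kernel = stride) ------------------------------

upconv_fw <- function(x, Wlist, b, f) {
  d <- x$dim
  dn <- d * f
  Co <- length(b)
  y4 <- array(0, c(dn, Co))
  offs <- pool_offsets(f)
  for (o in seq_len(nrow(offs))) {
    sub <- x$mat %*% Wlist[[o]]
    y4[seq(offs[o, 1], dn[1], f[1]), seq(offs[o, 2], dn[2], f[2]),
       seq(offs[o, 3], dn[3], f[3]), ] <- array(sub, c(d, Co))
  }
  y <- matrix(y4, prod(dn), Co)
  for (c in seq_len(Co)) y[, c] <- y[, c] + b[c]
  fmap(y, dn)
}

upconv_bw <- function(x, Wlist, f, gy, out_dim) {
  d <- x$dim
  Co <- ncol(Wlist[[1]])
  gy4 <- array(gy, c(out_dim, Co))
  offs <- pool_offsets(f)
  gx <- matrix(0, nrow(x$mat), ncol(x$mat))
  gW <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    sub <- gy4[seq(offs[o, 1], out_dim[1], f[1]), seq(offs[o, 2], out_dim[2], f[2]),
               seq(offs[o, 3], out_dim[3], f[3]), , drop = FALSE]
    subm <- matrix(sub, nrow(x$mat), Co)
    gx <- gx + subm %*% t(Wlist[[o]])
    gW[[o]] <- crossprod(x$mat, subm)
  }
  list(gx = fmap(gx, d), gW = gW, gb = colSums(gy))
}

## ---- Softmax + loss -------------------------------------------------------

softmax_rows <- function(logits) {
  m <- logits[, 1]
  for (c in 2:ncol(logits)) m <- pmax(m, logits[, c])
  P <- exp(logits - m)
  P / rowSums(P)
}

## Combined objective for 3-class voxel classification: voxelwise
## cross-entropy plus soft Dice (1 - mean per-class Dice of probabilities
## against one-hot truth). `class_weights` reweights the cross-entropy per
## true class (inverse-frequency weighting counters the ~0.5% spine
## prevalence, whose gradient otherwise vanishes through the saturated
## softmax). Returns loss components and d(loss)/d(logits).
softmax_loss_grad <- function(logits, labels, loss = "combined",
                              dice_eps = 1, class_weights = NULL) {
  N <- nrow(logits)
  K <- ncol(logits)
  P <- softmax_rows(logits)
  G <- matrix(0, N, K)
  G[cbind(seq_len(N), labels + 1L)] <- 1
  w <- if (is.null(class_weights)) rep(1, K) else class_weights
  wv <- w[labels + 1L]
  sw <- sum(wv)
  ce <- -sum(wv * log(pmax(P[cbind(seq_len(N), labels + 1L)], 1e-12))) / sw
  num <- 2 * colSums(P * G) + dice_eps
  den <- colSums(P) + colSums(G) + dice_eps
  dice <- 1 - mean(num / den)
  gl <- matrix(0, N, K)
  if (loss %in% c("cross_entropy", "combined"))
    gl <- gl + wv * (P - G) / sw
  if (loss %in% c("soft_dice", "combined")) {
    ## dL/dP_nc = -(1/K) * (2 G_nc / den_c - num_c / den_c^2),
    ## then through the softmax Jacobian
    gP <- -(sweep(2 * G, 2, den, "/") -
              matrix(num / den^2, N, K, byrow = TRUE)) / K
    gl <- gl + P * (gP - rowSums(gP * P))
  }
  loss_val <- switch(loss,
                     cross_entropy = ce,
                     soft_dice = dice,
                     combined = ce + dice)
  list(loss = loss_val, ce = ce, dice = dice, grad = gl, probs = P)
}
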