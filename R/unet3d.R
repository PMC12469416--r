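## 3-class volumetric encoder-decoder ("3D U-Net"): `depth` encoder blocks of
## two 3x3x3 convolutions + ReLU followed by max pooling, a two-convolution
## bottleneck, a mirrored decoder of transpose convolutions with skip
## concatenations, and a final 1x1x1 convolution to 3 channels with a voxelwise
## softmax. In-plane axes pool at every block; the depth axis pools only while
## it remains even, so a (240, 240, 16) input pools (2,2,2) three times.

#' Configure the segmentation network
#'
#' Loss, optimizer and schedule defaults (combined cross-entropy + soft Dice,
#' Adam, lr 1e-3, batch 2) are standard choices for class-imbalanced 3-class
#' volumetric segmentation and are all overridable here.
#'
#' @param depth number of encoder/decoder blocks (default 3).
#' @param base_channels channels of the first block; doubled per level.
#' @param in_shape input tensor shape `(1, H, W, D)`.
#' @param n_classes number of output classes (fixed at 3).
#' @param loss `"combined"`, `"cross_entropy"` or `"soft_dice"`.
#' @param class_weights `"balanced"` (inverse class frequency per volume,
#'   capped at 50; counters the sub-percent spine prevalence), `"none"`, or
#'   a length-3 numeric vector of fixed weights for the cross-entropy term.
#' @param lr initial Adam learning rate.
#' @param clip_norm global L2 gradient-norm ceiling per optimizer step
#'   (`Inf` disables); bounds the loss spikes that heavily weighted minority
#'   classes otherwise produce.
#' @param lr_decay multiplicative step decay applied once at 85% of the
#'   epoch schedule (set 1 to disable); consolidates the late phase of
#'   training without freezing classes whose learning starts late.
#' @param epochs maximum training epochs.
#' @param batch_size gradient-accumulation batch size.
#' @param augment logical; rotate each training volume by a fresh uniform
#'   angle in [-10, 10] degrees every epoch.
#' @param seed integer seed governing initialization, shuffling and
#'   augmentation angles; training is deterministic under it.
#' @return An object of class `net_config`.
#' @export
net_config <- function(depth = 3L, base_channels = 16L,
                       in_shape = c(1L, 240L, 240L, 16L),
                       n_classes = 3L, loss = c("combined", "cross_entropy",
                                                "soft_dice"),
                       class_weights = "balanced",
                       lr = 1e-3, clip_norm = 5, lr_decay = 0.3,
                       epochs = 100L, batch_size = 2L,
                       augment = TRUE, seed = 1L) {
  loss <- match.arg(loss)
  if (is.character(class_weights) && !class_weights %in% c("balanced", "none"))
    stopf("'class_weights' must be \"balanced\", \"none\" or a length-3 numeric")
  if (is.numeric(class_weights) && length(class_weights) != 3L)
    stopf("numeric 'class_weights' must have length 3")
  depth <- as.integer(depth)
  in_shape <- as.integer(in_shape)
  if (depth < 1L) stopf("'depth' must be >= 1")
  if (length(in_shape) != 4L || in_shape[1] != 1L)
    stopf("'in_shape' must be (1, H, W, D)")
  if (n_classes != 3L) stopf("'n_classes' is fixed at 3 (background/thorax/spine)")
  cfg <- structure(
    list(depth = depth, base_channels = as.integer(base_channels),
         in_shape = in_shape, n_classes = 3L, loss = loss,
         class_weights = class_weights,
         lr = lr, clip_norm = clip_norm, lr_decay = lr_decay,
         epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), augment = isTRUE(augment),
         seed = as.integer(seed)),
    class = "net_config")
  cfg$pool_factors <- plan_pooling(cfg)   # validates divisibility
  cfg
}

#' Tiny network preset for CPU tests
#'
#' 64x64x16 grid with 8 base channels; same depth-3 architecture.
#' @param ... overrides passed to [net_config()].
#' @return a `net_config`.
#' @export
net_config_tiny <- function(...) {
  args <- list(...)
  defaults <- list(base_channels = 8L, in_shape = c(1L, 64L, 64L, 16L),
                   epochs = 32L)
  do.call(net_config, utils::modifyList(defaults, args))
}

## Per-level pooling factors; errors name the offending axis.
plan_pooling <- function(cfg) {
  H <- cfg$in_shape[2]; W <- cfg$in_shape[3]; D <- cfg$in_shape[4]
  factors <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    fd <- if (D %% 2L == 0L && D >= 2L) 2L else 1L
    if (H %% 2L != 0L)
      stopf("height %d is not divisible by 2 at pooling level %d", H, i)
    if (W %% 2L != 0L)
      stopf("width %d is not divisible by 2 at pooling level %d", W, i)
    factors[[i]] <- c(2L, 2L, fd)
    H <- H %/% 2L; W <- W %/% 2L; D <- D %/% fd
  }
  factors
}

init_conv <- function(cin, cout) {
  list(W = matrix(stats::rnorm(27 * cin * cout, 0, sqrt(2 / (27 * cin))),
                  27 * cin, cout),
       b = numeric(cout))
}

init_upconv <- function(cin, cout, f) {
  n <- prod(f)
  list(W = lapply(seq_len(n), function(o)
         matrix(stats::rnorm(cin * cout, 0, sqrt(2 / (n * cin))), cin, cout)),
       b = numeric(cout))
}

#' Build an untrained network
#'
#' He-initialized under `cfg$seed`.
#'
#' @param cfg a [net_config()].
#' @return An object of class `unet3d` holding the parameters and config.
#' @export
build_unet3d <- function(cfg) {
  if (!inherits(cfg, "net_config")) stopf("'cfg' must be a net_config")
  ch <- cfg$base_channels * 2L^(seq_len(cfg$depth) - 1L)
  params <- with_seed_(cfg$seed, {
    p <- list()
    cin <- 1L
    for (i in seq_len(cfg$depth)) {
      p[[paste0("enc", i, ".conv1")]] <- init_conv(cin, ch[i])
      p[[paste0("enc", i, ".conv2")]] <- init_conv(ch[i], ch[i])
      cin <- ch[i]
    }
    cb <- 2L * ch[cfg$depth]
    p[["bott.conv1"]] <- init_conv(cin, cb)
    p[["bott.conv2"]] <- init_conv(cb, cb)
    cin <- cb
    for (i in rev(seq_len(cfg$depth))) {
      p[[paste0("dec", i, ".up")]] <- init_upconv(cin, ch[i], cfg$pool_factors[[i]])
      p[[paste0("dec", i, ".conv1")]] <- init_conv(2L * ch[i], ch[i])
      p[[paste0("dec", i, ".conv2")]] <- init_conv(ch[i], ch[i])
      cin <- ch[i]
    }
    p[["final"]] <- list(W = matrix(stats::rnorm(ch[1] * 3L, 0, sqrt(2 / ch[1])),
                                    ch[1], 3L),
                         b = numeric(3L))
    p
  })
  structure(list(params = params, cfg = cfg, trained = FALSE),
            class = "unet3d")
}

#' @export
print.unet3d <- function(x, ...) {
  n_par <- n_parameters(x)
  cat(sprintf("<unet3d> depth %d, base %d channels, input (%s), %s\n",
              x$cfg$depth, x$cfg$base_channels,
              paste(x$cfg$in_shape, collapse = ", "),
              if (x$trained) "trained" else "untrained"))
  cat(sprintf("  parameters: %d\n", as.integer(n_par)))
  invisible(x)
}

#' Number of learnable parameters
#' @param net a [build_unet3d()] network.
#' @return integer parameter count.
#' @export
n_parameters <- function(net) {
  as.integer(sum(rapply(net$params, length, how = "unlist")))
}

## Forward pass. x: (N x 1) fmap on the configured grid. Returns logits fmap
## and (if keep_cache) everything the backward pass needs.
unet_forward <- function(net, x, keep_cache = FALSE) {
  cfg <- net$cfg; p <- net$params
  cache <- list()
  skips <- list()
  f <- x
  for (i in seq_len(cfg$depth)) {
    nm1 <- paste0("enc", i, ".conv1"); nm2 <- paste0("enc", i, ".conv2")
    c1 <- conv3_fw(f, p[[nm1]]$W, p[[nm1]]$b); a1 <- relu_fw(c1$out)
    c2 <- conv3_fw(a1, p[[nm2]]$W, p[[nm2]]$b); a2 <- relu_fw(c2$out)
    pl <- maxpool_fw(a2, cfg$pool_factors[[i]])
    skips[[i]] <- a2
    if (keep_cache)
      cache[[paste0("enc", i)]] <- list(x = f, cols1 = c1$cols, a1 = a1,
                                        cols2 = c2$cols, a2 = a2,
                                        amax = pl$amax)
    f <- pl$out
  }
  c1 <- conv3_fw(f, p[["bott.conv1"]]$W, p[["bott.conv1"]]$b); a1 <- relu_fw(c1$out)
  c2 <- conv3_fw(a1, p[["bott.conv2"]]$W, p[["bott.conv2"]]$b); a2 <- relu_fw(c2$out)
  if (keep_cache)
    cache[["bott"]] <- list(x = f, cols1 = c1$cols, a1 = a1,
                            cols2 = c2$cols, a2 = a2)
  f <- a2
  for (i in rev(seq_len(cfg$depth))) {
    nmu <- paste0("dec", i, ".up")
    nm1 <- paste0("dec", i, ".conv1"); nm2 <- paste0("dec", i, ".conv2")
    up <- upconv_fw(f, p[[nmu]]$W, p[[nmu]]$b, cfg$pool_factors[[i]])
    cat_in <- fmap(cbind(skips[[i]]$mat, up$mat), up$dim)
    c1 <- conv3_fw(cat_in, p[[nm1]]$W, p[[nm1]]$b); a1 <- relu_fw(c1$out)
    c2 <- conv3_fw(a1, p[[nm2]]$W, p[[nm2]]$b); a2 <- relu_fw(c2$out)
    if (keep_cache)
      cache[[paste0("dec", i)]] <- list(x = f, up = up, cat_in = cat_in,
                                        cols1 = c1$cols, a1 = a1,
                                        cols2 = c2$cols, a2 = a2)
    f <- a2
  }
  logits <- fmap(f$mat %*% p[["final"]]$W +
                   matrix(p[["final"]]$b, nrow(f$mat), 3L, byrow = TRUE),
                 f$dim)
  list(logits = logits, feat = f, cache = if (keep_cache) cache)
}

## Backward pass: returns gradient list with the same names/shapes as params.
unet_backward <- function(net, fwd, glogits) {
  cfg <- net$cfg; p <- net$params
  cache <- fwd$cache
  g <- list()
  g[["final"]] <- list(W = crossprod(fwd$feat$mat, glogits),
                       b = colSums(glogits))
  gf <- glogits %*% t(p[["final"]]$W)
  for (i in seq_len(cfg$depth)) {
    cc <- cache[[paste0("dec", i)]]
    nmu <- paste0("dec", i, ".up")
    nm1 <- paste0("dec", i, ".conv1"); nm2 <- paste0("dec", i, ".conv2")
    gf <- relu_bw(cc$a2, gf)
    b2 <- conv3_bw(cc$cols2, cc$a1, p[[nm2]]$W, gf)
    g[[nm2]] <- list(W = b2$gW, b = b2$gb)
    gf <- relu_bw(cc$a1, b2$gx$mat)
    b1 <- conv3_bw(cc$cols1, cc$cat_in, p[[nm1]]$W, gf)
    g[[nm1]] <- list(W = b1$gW, b = b1$gb)
    nskip <- ncol(cache[[paste0("enc", i)]]$a2$mat)
    gskip <- b1$gx$mat[, seq_len(nskip), drop = FALSE]
    gup <- b1$gx$mat[, -seq_len(nskip), drop = FALSE]
    bu <- upconv_bw(cc$x, p[[nmu]]$W, cfg$pool_factors[[i]], gup, cc$up$dim)
    g[[nmu]] <- list(W = bu$gW, b = bu$gb)
    cache[[paste0("enc", i)]]$gskip <- gskip
    gf <- bu$gx$mat
  }
  cb <- cache[["bott"]]
  gf <- relu_bw(cb$a2, gf)
  b2 <- conv3_bw(cb$cols2, cb$a1, p[["bott.conv2"]]$W, gf)
  g[["bott.conv2"]] <- list(W = b2$gW, b = b2$gb)
  gf <- relu_bw(cb$a1, b2$gx$mat)
  b1 <- conv3_bw(cb$cols1, cb$x, p[["bott.conv1"]]$W, gf)
  g[["bott.conv1"]] <- list(W = b1$gW, b = b1$gb)
  gf <- b1$gx$mat
  for (i in rev(seq_len(cfg$depth))) {
    ce <- cache[[paste0("enc", i)]]
    nm1 <- paste0("enc", i, ".conv1"); nm2 <- paste0("enc", i, ".conv2")
    gpool <- maxpool_bw(gf, ce$amax, ce$a2$dim, cfg$pool_factors[[i]])
    ga2 <- gpool$mat + ce$gskip
    ga2 <- relu_bw(ce$a2, ga2)
    b2 <- conv3_bw(ce$cols2, ce$a1, p[[nm2]]$W, ga2)
    g[[nm2]] <- list(W = b2$gW, b = b2$gb)
    ga1 <- relu_bw(ce$a1, b2$gx$mat)
    b1 <- conv3_bw(ce$cols1, ce$x, p[[nm1]]$W, ga1)
    g[[nm1]] <- list(W = b1$gW, b = b1$gb)
    gf <- b1$gx$mat
  }
  g
}

pair_to_fmap <- function(pair, cfg) {
  d <- dim(pair$image)[-1]
  if (!identical(as.integer(d), cfg$in_shape[2:4]))
    stopf("input grid (%s) does not match the configured shape (%s)",
          paste(d, collapse = ", "), paste(cfg$in_shape[2:4], collapse = ", "))
  fmap(matrix(as.numeric(pair$image), prod(d), 1L), d)
}

## ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like)
    else x * 0
  }
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  out <- Map(upd, params, grads, state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = state$t))
}

acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  Map(function(x, y) if (is.list(x)) acc_grads(x, y) else x + y, a, b)
}

scale_grads <- function(g, s) {
  lapply(g, function(x) if (is.list(x)) scale_grads(x, s) else x * s)
}

## ---- Training and prediction ----------------------------------------------

#' Train the segmentation network
#'
#' Adam with gradient accumulation over `cfg$batch_size` volumes, optional
#' per-epoch rotation augmentation, and a per-epoch validation Dice when a
#' validation set is supplied. Fully deterministic under `cfg$seed` on a
#' fixed platform.
#'
#' @param net a [build_unet3d()] network.
#' @param train_set list of `model_grid_pair`s with masks.
#' @param val_set optional list of `model_grid_pair`s for per-epoch Dice.
#' @param verbose print per-epoch loss.
#' @return the trained `unet3d`, with a `history` data.frame (epoch, mean
#'   loss, and per-class validation DSC when `val_set` is given).
#' @export
train_unet3d <- function(net, train_set, val_set = NULL, verbose = FALSE) {
  if (!inherits(net, "unet3d")) stopf("'net' must be a unet3d")
  cfg <- net$cfg
  if (length(train_set) == 0L) stopf("empty training set")
  for (pr in train_set) {
    if (is.null(pr$mask)) stopf("every training pair needs a mask")
    if (!all(pr$mask %in% 0:2)) stopf("training mask has class codes outside {0, 1, 2}")
  }
  with_seed_(cfg$seed + 1L, {
    state <- adam_init(net$params)
    hist <- vector("list", cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      lr_now <- cfg$lr * ifelse(ep > 0.85 * cfg$epochs, cfg$lr_decay, 1)
      ord <- sample(length(train_set))
      losses <- numeric(0)
      gacc <- NULL
      nacc <- 0L
      for (j in seq_along(ord)) {
        pair <- train_set[[ord[j]]]
        if (cfg$augment) {
          ang <- stats::runif(1, -10, 10)
          pair <- augment_rotation(pair, ang)
        }
        x <- pair_to_fmap(pair, cfg)
        lab <- as.integer(pair$mask)
        cw <- if (is.numeric(cfg$class_weights)) {
          cfg$class_weights
        } else if (identical(cfg$class_weights, "balanced")) {
          counts <- tabulate(lab + 1L, nbins = 3L)
          pmin(length(lab) / (3 * pmax(counts, 1L)), 50)
        }
        fwd <- unet_forward(net, x, keep_cache = TRUE)
        lg <- softmax_loss_grad(fwd$logits$mat, lab,
                                loss = cfg$loss, class_weights = cw)
        losses <- c(losses, lg$loss)
        gacc <- acc_grads(gacc, unet_backward(net, fwd, lg$grad)[names(net$params)])
        nacc <- nacc + 1L
        if (nacc == cfg$batch_size || j == length(ord)) {
          gstep <- scale_grads(gacc, 1 / nacc)
          gn <- sqrt(sum(rapply(gstep, function(x) sum(x * x), how = "unlist")))
          if (is.finite(cfg$clip_norm) && gn > cfg$clip_norm)
            gstep <- scale_grads(gstep, cfg$clip_norm / gn)
          st <- adam_step(net$params, gstep, state, lr_now)
          net$params <- st$params
          state <- st$state
          gacc <- NULL
          nacc <- 0L
        }
      }
      row <- data.frame(epoch = ep, loss = mean(losses))
      if (!is.null(val_set)) {
        vd <- vapply(val_set, function(vp) {
          pred <- predict_unet3d(net, vp)
          c(dsc(pred$labels >= 1, vp$mask >= 1),
            dsc(pred$labels == 2, vp$mask == 2))
        }, numeric(2))
        row$val_dsc_thorax <- mean(vd[1, ])
        row$val_dsc_spine <- mean(vd[2, ])
      }
      hist[[ep]] <- row
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f%s", ep, row$loss,
                        if (!is.null(val_set))
                          sprintf("  val DSC thorax %.3f spine %.3f",
                                  row$val_dsc_thorax, row$val_dsc_spine)
                        else ""))
    }
    net$history <- do.call(rbind, hist)
  })
  net$trained <- TRUE
  net
}

#' Predict per-voxel class probabilities
#'
#' Runs the forward pass and returns the softmax probability map together
#' with hard labels. Voxels are assigned the class of highest probability;
#' exact ties resolve to the lowest class code (background-favoring,
#' deterministic).
#'
#' @param net a `unet3d`.
#' @param pair a `model_grid_pair` on the configured grid.
#' @return An object of class `probability_map`: `probs` is a
#'   `(3, H, W, D)` array on the channel simplex, `labels` an `(H, W, D)`
#'   integer array, `provenance` copied from the input pair.
#' @export
predict_unet3d <- function(net, pair) {
  if (!inherits(net, "unet3d")) stopf("'net' must be a unet3d")
  x <- pair_to_fmap(pair, net$cfg)
  fwd <- unet_forward(net, x, keep_cache = FALSE)
  P <- softmax_rows(fwd$logits$mat)
  d <- x$dim
  labels <- array(max.col(P, ties.method = "first") - 1L, dim = d)
  probs <- aperm(array(P, c(d, 3L)), c(4, 1, 2, 3))
  structure(list(probs = probs, labels = labels,
                 provenance = pair$provenance),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  d <- dim(x$probs)
  cat(sprintf("<probability_map> %d classes on %d x %d x %d grid\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Save / load a network checkpoint
#'
#' Plain-text JSON checkpoint with the config embedded.
#' @param net a `unet3d`.
#' @param path output path.
#' @return `path` invisibly; `load_checkpoint` returns the `unet3d`.
#' @export
save_checkpoint <- function(net, path) {
  cfg <- unclass(net$cfg)
  cfg$pool_factors <- NULL
  ser <- list(cfg = cfg, trained = net$trained,
              flat_params = as.numeric(rapply(net$params, identity,
                                              how = "unlist")))
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg_args <- as.list(ser$cfg)
  net <- build_unet3d(do.call(net_config, cfg_args))
  flat <- as.numeric(ser$flat_params)
  pos <- 0L
  refill <- function(x) {
    if (is.list(x)) return(lapply(x, refill))
    n <- length(x)
    val <- flat[pos + seq_len(n)]
    pos <<- pos + n
    if (is.matrix(x)) matrix(val, nrow(x), ncol(x)) else val
  }
  net$params <- refill(net$params)
  if (pos != length(flat))
    stopf("checkpoint parameter count (%d) does not match the architecture (%d)",
          length(flat), pos)
  net$trained <- isTRUE(ser$trained)
  net
}
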