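#' Segmentation configuration
#'
#' One configuration per target class; the mitochondrion and granule models
#' are trained independently and share no state. The architecture is a small
#' volumetric encoder-decoder with skip connections (a 3D U-Net): `depth`
#' pooling levels, `base_channels` features at the top level doubling per
#' level, one 3x3x3 convolution + ReLU per level, nearest-neighbour
#' upsampling, and a final 1x1x1 convolution to a per-voxel foreground
#' probability.
#'
#' Class imbalance is handled by foreground-biased patch sampling (half of
#' the training patches are centred on an annotated foreground voxel) rather
#' than loss weighting; the loss is per-voxel binary cross-entropy over
#' non-ignore voxels only.
#'
#' @param target_class `"mitochondrion"` or `"granule"`.
#' @param depth number of pooling levels (patch sides must be divisible by
#'   `2^depth`).
#' @param base_channels feature channels at the top level.
#' @param patch_size training/inference patch side(s), scalar or (z,y,x).
#' @param epochs training epochs; each epoch draws `steps_per_epoch`
#'   optimization steps.
#' @param steps_per_epoch optimization steps per epoch.
#' @param learning_rate Adam learning rate.
#' @param batch_size patches averaged per optimization step.
#' @param binarize_threshold probability threshold for final masks.
#' @param pseudo_fg_conf confidence above which a predicted voxel becomes a
#'   pseudo-foreground label.
#' @param pseudo_bg_conf confidence below which a predicted voxel becomes a
#'   pseudo-background label.
#' @param seed seed controlling initialization and patch sampling.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(target_class = c("mitochondrion", "granule"),
                       depth = 3L, base_channels = 8L, patch_size = 32L,
                       epochs = 12L, steps_per_epoch = 25L,
                       learning_rate = 3e-3, batch_size = 2L,
                       binarize_threshold = 0.5,
                       pseudo_fg_conf = 0.95, pseudo_bg_conf = 0.05,
                       seed = 1L) {
  target_class <- match.arg(target_class)
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1")
  if (length(patch_size) == 1L) patch_size <- rep(patch_size, 3L)
  patch_size <- as.integer(patch_size)
  if (any(patch_size %% 2L^depth != 0L))
    stop("patch_size must be divisible by 2^depth on every axis")
  if (!(binarize_threshold > 0 && binarize_threshold < 1))
    stop("binarize_threshold must be in (0, 1)")
  if (!(pseudo_bg_conf < binarize_threshold &&
        binarize_threshold < pseudo_fg_conf))
    stop("need pseudo_bg_conf < binarize_threshold < pseudo_fg_conf")
  structure(list(
    target_class = target_class, depth = depth,
    base_channels = as.integer(base_channels), patch_size = patch_size,
    epochs = as.integer(epochs), steps_per_epoch = as.integer(steps_per_epoch),
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    binarize_threshold = binarize_threshold,
    pseudo_fg_conf = pseudo_fg_conf, pseudo_bg_conf = pseudo_bg_conf,
    seed = as.integer(seed)), class = "seg_config")
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

#' Build an untrained segmentation model
#'
#' Parameter initialization is a pure function of `config$seed`.
#'
#' @param config a [seg_config()].
#' @return An object of class `unet3d`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "seg_config"))
  set.seed(config$seed)
  depth <- config$depth
  ch <- config$base_channels * 2L^(seq_len(depth) - 1L)
  enc <- vector("list", depth)
  cin <- 1L
  for (l in seq_len(depth)) {
    enc[[l]] <- list(w = he_init(c(3, 3, 3, cin, ch[l]), 27 * cin),
                     b = numeric(ch[l]))
    cin <- ch[l]
  }
  bott <- list(w = he_init(c(3, 3, 3, ch[depth], ch[depth]), 27 * ch[depth]),
               b = numeric(ch[depth]))
  dec <- vector("list", depth)
  prev <- ch[depth]
  for (l in rev(seq_len(depth))) {
    cin_l <- prev + ch[l]
    dec[[l]] <- list(w = he_init(c(3, 3, 3, cin_l, ch[l]), 27 * cin_l),
                     b = numeric(ch[l]))
    prev <- ch[l]
  }
  out <- list(w = stats::rnorm(ch[1], 0, sqrt(1 / ch[1])), b = 0)
  structure(list(config = config, ch = ch,
                 enc = enc, bott = bott, dec = dec, out = out,
                 trained = FALSE, loss_log = numeric(0)),
            class = "unet3d")
}

relu <- function(z) { z[z < 0] <- 0; z }

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- c(a, b)
  dim(out) <- c(da[1:3], da[4] + db[4])
  out
}

# forward pass; x is a 3D array (one channel). Returns logits and, when
# cache = TRUE, every intermediate needed by unet_backward().
unet_forward <- function(model, x, cache = FALSE) {
  depth <- model$config$depth
  a <- x
  dim(a) <- c(dim(x), 1L)
  e <- vector("list", depth)
  pidx <- vector("list", depth)
  edim <- vector("list", depth)
  ain <- vector("list", depth)  # inputs to encoder convs
  for (l in seq_len(depth)) {
    ain[[l]] <- a
    z <- conv3_fw(a, model$enc[[l]]$w, model$enc[[l]]$b)
    e[[l]] <- relu(z)
    edim[[l]] <- dim(e[[l]])
    p <- maxpool2_fw(e[[l]])
    a <- p$y
    pidx[[l]] <- p$idx
  }
  bin <- a
  bz <- conv3_fw(a, model$bott$w, model$bott$b)
  r <- relu(bz)
  dcat <- vector("list", depth)
  dout <- vector("list", depth)
  for (l in rev(seq_len(depth))) {
    u <- upsample2_fw(r)
    cc <- cat_channels(u, e[[l]])
    dcat[[l]] <- cc
    z <- conv3_fw(cc, model$dec[[l]]$w, model$dec[[l]]$b)
    r <- relu(z)
    dout[[l]] <- r
  }
  dr <- dim(r)
  n <- prod(dr[1:3])
  feat <- matrix(r, n, dr[4])
  logits <- as.vector(feat %*% model$out$w) + model$out$b
  dim(logits) <- dr[1:3]
  if (!cache) return(logits)
  list(logits = logits, ain = ain, e = e, pidx = pidx, edim = edim,
       bin = bin, bott_y = relu(bz), dcat = dcat, dout = dout, feat = feat)
}

# backward pass: glogits is dL/dlogits (same dim as logits).
# Returns a list of gradients mirroring the parameter structure.
unet_backward <- function(model, cachef, glogits) {
  depth <- model$config$depth
  gr <- list(enc = vector("list", depth), bott = NULL,
             dec = vector("list", depth), out = NULL)
  feat <- cachef$feat
  gl <- as.vector(glogits)
  gw_out <- as.vector(crossprod(feat, gl))
  gb_out <- sum(gl)
  gr$out <- list(w = gw_out, b = gb_out)
  gfeat <- gl %o% model$out$w
  g_r <- array(gfeat, dim(cachef$dout[[1]]))

  # decoder backward (levels 1..depth correspond to forward depth..1 order)
  g_skip <- vector("list", depth)
  for (l in seq_len(depth)) {
    rr <- cachef$dout[[l]]
    gz <- g_r * (rr > 0)
    bw <- conv3_bw(cachef$dcat[[l]], model$dec[[l]]$w, gz)
    gr$dec[[l]] <- list(w = bw$gw, b = bw$gb)
    gcat <- bw$gx
    dcc <- dim(gcat)
    uch <- dcc[4] - dim(cachef$e[[l]])[4]
    gu <- gcat[, , , seq_len(uch), drop = FALSE]
    g_skip[[l]] <- gcat[, , , uch + seq_len(dcc[4] - uch), drop = FALSE]
    g_r <- upsample2_bw(gu)
  }

  # bottleneck
  by <- cachef$bott_y
  gz <- g_r * (by > 0)
  bw <- conv3_bw(cachef$bin, model$bott$w, gz)
  gr$bott <- list(w = bw$gw, b = bw$gb)
  g_a <- bw$gx

  # encoder backward
  for (l in rev(seq_len(depth))) {
    ge <- maxpool2_bw(g_a, cachef$pidx[[l]], as.integer(cachef$edim[[l]])) +
      g_skip[[l]]
    gz <- ge * (cachef$e[[l]] > 0)
    bw <- conv3_bw(cachef$ain[[l]], model$enc[[l]]$w, gz)
    gr$enc[[l]] <- list(w = bw$gw, b = bw$gb)
    g_a <- bw$gx
  }
  gr
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# masked binary cross-entropy with logits; mask values 0/1/255 (255 = ignore)
masked_bce <- function(logits, mask) {
  valid <- mask != 255L
  n <- sum(valid)
  if (n == 0) return(list(loss = NA_real_, glogits = array(0, dim(logits))))
  x <- logits[valid]
  t <- as.numeric(mask[valid])
  loss <- mean(pmax(x, 0) - x * t + log1p(exp(-abs(x))))
  g <- array(0, dim(logits))
  g[valid] <- (sigmoid(x) - t) / n
  list(loss = loss, glogits = g)
}

# flatten/apply helpers for Adam over the nested parameter list
param_names <- function(model) {
  depth <- model$config$depth
  c(paste0("enc", seq_len(depth)), "bott", paste0("dec", seq_len(depth)),
    "out")
}

get_layer <- function(model, nm) {
  if (nm == "bott") model$bott
  else if (nm == "out") model$out
  else if (startsWith(nm, "enc")) model$enc[[as.integer(substring(nm, 4))]]
  else model$dec[[as.integer(substring(nm, 4))]]
}

set_layer <- function(model, nm, layer) {
  if (nm == "bott") model$bott <- layer
  else if (nm == "out") model$out <- layer
  else if (startsWith(nm, "enc"))
    model$enc[[as.integer(substring(nm, 4))]] <- layer
  else model$dec[[as.integer(substring(nm, 4))]] <- layer
  model
}

adam_update <- function(model, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in param_names(model)) {
    layer <- get_layer(model, nm)
    g <- if (nm == "bott") grads$bott
         else if (nm == "out") grads$out
         else if (startsWith(nm, "enc")) grads$enc[[as.integer(substring(nm, 4))]]
         else grads$dec[[as.integer(substring(nm, 4))]]
    for (p in c("w", "b")) {
      key <- paste0(nm, ".", p)
      if (is.null(state[[key]]))
        state[[key]] <- list(m = 0 * layer[[p]], v = 0 * layer[[p]])
      st <- state[[key]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[p]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[p]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layer[[p]] <- layer[[p]] - lr * mhat / (sqrt(vhat) + eps)
      state[[key]] <- st
    }
    model <- set_layer(model, nm, layer)
  }
  list(model = model, state = state)
}

# elementwise sum of two gradient structures (for batch accumulation)
sum_grads <- function(a, b) {
  if (is.null(a)) return(b)
  pair <- function(x, y) list(w = x$w + y$w, b = x$b + y$b)
  list(enc = Map(pair, a$enc, b$enc), bott = pair(a$bott, b$bott),
       dec = Map(pair, a$dec, b$dec), out = pair(a$out, b$out))
}

scale_grads <- function(g, s) {
  sc <- function(x) list(w = x$w * s, b = x$b * s)
  list(enc = lapply(g$enc, sc), bott = sc(g$bott),
       dec = lapply(g$dec, sc), out = sc(g$out))
}
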