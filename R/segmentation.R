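#' Voxel training mask from a sparse slice annotation
#'
#' Annotated slices are copied as 0/1 labels; every other voxel is set to
#' the ignore value 255, over which no loss is computed.
#'
#' @param ann a [annotation_for_class()] result (binary planes for one
#'   class).
#' @param volume_shape integer triple (nz, ny, nx).
#' @return An object of class `training_mask`: list with `mask` (integer 3D
#'   array over \{0, 1, 255\}) and `provenance` (`"human"` or `"pseudo"`).
#' @export
make_training_mask <- function(ann, volume_shape) {
  stopifnot(inherits(ann, "sparse_slice_annotation"))
  volume_shape <- as.integer(volume_shape)
  if (any(ann$annotated_z < 1L) || any(ann$annotated_z > volume_shape[1]))
    stop("annotation z indices outside the volume")
  mask <- array(255L, volume_shape)
  for (z in ann$annotated_z) {
    p <- ann$planes[[as.character(z)]]
    if (!identical(dim(p), volume_shape[2:3]))
      stop("annotation plane shape does not match the volume")
    mask[z, , ] <- as.integer(p)
  }
  structure(list(mask = mask, provenance = ann$provenance),
            class = "training_mask")
}

as_mask_array <- function(m) {
  if (inherits(m, "training_mask")) m$mask else m
}

as_voxel_array <- function(v) {
  if (inherits(v, "tomogram")) v$voxels else v
}

standardize_volume <- function(v) {
  s <- stats::sd(as.vector(v))
  if (!is.finite(s) || s == 0) s <- 1
  (v - mean(v)) / s
}

#' Train a segmentation model on sparsely annotated volumes
#'
#' Optimizes per-voxel binary cross-entropy over non-ignore voxels of
#' sampled patches. Patches always intersect an annotated slice; half are
#' centred on an annotated foreground voxel (foreground-biased sampling).
#' Each input volume is standardized (zero mean, unit variance) before
#' patch extraction; prediction applies the same standardization.
#'
#' @param tomograms list of [tomogram()]s or 3D arrays, each at least
#'   `patch_size` on every axis.
#' @param masks list of [make_training_mask()] results (or 0/1/255 arrays),
#'   paired with `tomograms`.
#' @param config a [seg_config()].
#' @param model optional prebuilt [build_model()] output; when NULL a fresh
#'   model is built from `config`.
#' @return A trained `unet3d` model (with `loss_log`).
#' @export
seg_train <- function(tomograms, masks, config, model = NULL) {
  stopifnot(inherits(config, "seg_config"))
  if (length(tomograms) != length(masks) || length(tomograms) < 1L)
    stop("need >= 1 (volume, mask) pair, with equal list lengths")
  vols <- lapply(tomograms, as_voxel_array)
  msks <- lapply(masks, as_mask_array)
  ps <- config$patch_size
  for (i in seq_along(vols)) {
    if (!identical(dim(vols[[i]]), dim(msks[[i]])))
      stop("volume/mask shape mismatch at pair ", i)
    if (any(dim(vols[[i]]) < ps))
      stop("volume ", i, " is smaller than patch_size on some axis")
  }
  n_fg <- sum(vapply(msks, function(m) sum(m == 1L), 0))
  n_bg <- sum(vapply(msks, function(m) sum(m == 0L), 0))
  if (n_fg == 0)
    stop(errorCondition("degenerate supervision: no foreground voxel in any mask",
                        class = c("mitogranule_supervision_error", "error",
                                  "condition")))
  if (n_bg == 0)
    stop(errorCondition("degenerate supervision: no background voxel in any mask",
                        class = c("mitogranule_supervision_error", "error",
                                  "condition")))

  vols <- lapply(vols, standardize_volume)
  # drop pairs that carry no supervision at all: they cannot contribute loss
  keep <- vapply(msks, function(m) any(m != 255L), TRUE)
  vols <- vols[keep]; msks <- msks[keep]

  ann_z <- lapply(msks, function(m)
    which(apply(m != 255L, 1, any)))
  fg_idx <- lapply(msks, function(m) which(m == 1L))

  if (is.null(model)) model <- build_model(config)
  set.seed(config$seed + 1L)
  state <- list()
  losses <- numeric(0)
  n_steps <- config$epochs * config$steps_per_epoch
  t_adam <- 0
  for (step in seq_len(n_steps)) {
    acc <- NULL
    loss_b <- 0
    for (bi in seq_len(config$batch_size)) {
      vi <- sample.int(length(vols), 1L)
      dms <- dim(vols[[vi]])
      if (length(fg_idx[[vi]]) > 0 && stats::runif(1) < 0.5) {
        pick <- fg_idx[[vi]][sample.int(length(fg_idx[[vi]]), 1L)]
        ctr <- arrayInd(pick, dms)[1, ]
        start <- pmin(pmax(ctr - ps %/% 2L, 1L), dms - ps + 1L)
      } else {
        z <- ann_z[[vi]][sample.int(length(ann_z[[vi]]), 1L)]
        zlo <- max(1L, z - ps[1] + 1L)
        zhi <- min(dms[1] - ps[1] + 1L, z)
        start <- c(zlo + sample.int(zhi - zlo + 1L, 1L) - 1L,
                   sample.int(dms[2] - ps[2] + 1L, 1L),
                   sample.int(dms[3] - ps[3] + 1L, 1L))
      }
      sl <- lapply(1:3, function(k) start[k]:(start[k] + ps[k] - 1L))
      xp <- vols[[vi]][sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
      mp <- msks[[vi]][sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
      if (!any(mp != 255L)) next
      fwd <- unet_forward(model, xp, cache = TRUE)
      lb <- masked_bce(fwd$logits, mp)
      g <- unet_backward(model, fwd, lb$glogits)
      acc <- sum_grads(acc, g)
      loss_b <- loss_b + lb$loss
    }
    if (is.null(acc)) next
    acc <- scale_grads(acc, 1 / config$batch_size)
    t_adam <- t_adam + 1
    upd <- adam_update(model, acc, state, config$learning_rate, t_adam)
    model <- upd$model
    state <- upd$state
    losses <- c(losses, loss_b / config$batch_size)
  }
  model$trained <- TRUE
  model$loss_log <- losses
  model
}

#' @export
print.unet3d <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(param_names(x), function(nm) {
    l <- get_layer(x, nm); length(l$w) + length(l$b)
  }, 0))
  cat(sprintf("<unet3d> target %s, depth %d, base channels %d, %d params%s\n",
              cfg$target_class, cfg$depth, cfg$base_channels, np,
              if (x$trained) sprintf(", trained (final loss %.4f)",
                                     utils::tail(x$loss_log, 1)) else
                ", untrained"))
  invisible(x)
}

#' Tiled volumetric inference
#'
#' Runs the model over overlapping patches and averages probabilities in
#' overlap zones. Deterministic given the model and input.
#'
#' @param object a trained `unet3d`.
#' @param newdata a [tomogram()] or 3D array at the model's training scale;
#'   must be at least `patch_size` on every axis.
#' @param overlap fractional patch overlap in \[0, 0.9\].
#' @param ... unused.
#' @return An object of class `probability_map`: list with `values` (3D
#'   array in \[0,1\]) and `target_class`.
#' @export
predict.unet3d <- function(object, newdata, overlap = 0.25, ...) {
  v <- standardize_volume(as_voxel_array(newdata))
  ps <- object$config$patch_size
  d <- dim(v)
  if (any(d < ps))
    stop("volume is smaller than patch_size on some axis; pad the input")
  starts <- lapply(1:3, function(k) {
    stride <- max(1L, as.integer(floor(ps[k] * (1 - overlap))))
    unique(c(seq(1L, d[k] - ps[k] + 1L, by = stride), d[k] - ps[k] + 1L))
  })
  acc <- array(0, d)
  cnt <- array(0, d)
  for (sz in starts[[1]]) for (sy in starts[[2]]) for (sx in starts[[3]]) {
    zz <- sz:(sz + ps[1] - 1L); yy <- sy:(sy + ps[2] - 1L)
    xx <- sx:(sx + ps[3] - 1L)
    lg <- unet_forward(object, v[zz, yy, xx, drop = FALSE])
    acc[zz, yy, xx] <- acc[zz, yy, xx] + sigmoid(lg)
    cnt[zz, yy, xx] <- cnt[zz, yy, xx] + 1
  }
  structure(list(values = acc / cnt,
                 target_class = object$config$target_class),
            class = "probability_map")
}

# Chebyshev (26-neighbourhood) dilation of a logical array by k steps,
# separable along the three axes
dilate_chebyshev <- function(a, k) {
  axis_max <- function(x, axis) {
    d <- dim(x)
    out <- x
    idx_lo <- lapply(d, seq_len)
    idx_hi <- idx_lo
    idx_lo[[axis]] <- seq_len(d[axis] - 1L)
    idx_hi[[axis]] <- 1L + seq_len(d[axis] - 1L)
    out[idx_lo[[1]], idx_lo[[2]], idx_lo[[3]]] <-
      out[idx_lo[[1]], idx_lo[[2]], idx_lo[[3]]] |
      x[idx_hi[[1]], idx_hi[[2]], idx_hi[[3]]]
    out[idx_hi[[1]], idx_hi[[2]], idx_hi[[3]]] <-
      out[idx_hi[[1]], idx_hi[[2]], idx_hi[[3]]] |
      x[idx_lo[[1]], idx_lo[[2]], idx_lo[[3]]]
    out
  }
  for (i in seq_len(k)) for (ax in 1:3) a <- axis_max(a, ax)
  a
}

#' Confidence-based pseudo-labels from a probability map
#'
#' In `mode = "voxel"`, voxels with probability >= `pseudo_fg_conf` become
#' foreground labels, <= `pseudo_bg_conf` background labels, and everything
#' else is ignored; optionally, background labels within
#' `boundary_guard_vox` voxels (Chebyshev distance) of likely foreground
#' are also ignored.
#'
#' In `mode = "slice"`, a z slice is accepted when at least `slice_conf` of
#' its voxels are confident; accepted slices are then labeled **in full**
#' by the binarize threshold (mirroring human-annotated slices), and all
#' other slices are ignored. The slice mode avoids a failure mode of
#' voxel-level confidence on small objects: confident voxels cover only
#' object cores, so a model retrained on them learns systematically eroded
#' objects.
#'
#' @param map a [predict.unet3d()] probability map.
#' @param config the [seg_config()] holding the confidence thresholds.
#' @param mode `"voxel"` (default) or `"slice"`.
#' @param slice_conf minimum confident-voxel fraction for slice mode.
#' @param boundary_guard_vox voxel-mode option: width of an ignored guard
#'   band around likely foreground (0, the default, disables).
#' @return A `training_mask` with provenance `"pseudo"`.
#' @export
generate_pseudo_labels <- function(map, config, mode = c("voxel", "slice"),
                                   slice_conf = 0.9,
                                   boundary_guard_vox = 0L) {
  stopifnot(inherits(map, "probability_map"), inherits(config, "seg_config"))
  mode <- match.arg(mode)
  if (!(config$pseudo_bg_conf < config$pseudo_fg_conf))
    stop("pseudo_bg_conf must be below pseudo_fg_conf")
  p <- map$values
  mask <- array(255L, dim(p))
  mask[p >= config$pseudo_fg_conf] <- 1L
  mask[p <= config$pseudo_bg_conf] <- 0L
  if (mode == "voxel" && boundary_guard_vox > 0) {
    near_fg <- dilate_chebyshev(p >= config$binarize_threshold,
                                as.integer(boundary_guard_vox))
    mask[mask == 0L & near_fg] <- 255L
  }
  if (mode == "slice") {
    conf_frac <- apply(mask != 255L, 1, mean)
    accepted <- conf_frac >= slice_conf
    full <- array(as.integer(p >= config$binarize_threshold), dim(p))
    mask[accepted, , ] <- full[accepted, , ]
    mask[!accepted, , ] <- 255L
  }
  structure(list(mask = mask, provenance = "pseudo"),
            class = "training_mask")
}

#' Stage-2 retraining on human plus pseudo labels
#'
#' Trains a fresh model (new initialization from the same config seed) on
#' the expanded training set: every human-annotated pair plus every
#' pseudo-labeled pair. With zero pseudo masks this reduces exactly to
#' stage-1 training.
#'
#' @param config a [seg_config()].
#' @param tomograms list of volumes.
#' @param human_masks list parallel to `tomograms`; elements may be NULL for
#'   volumes without human annotation.
#' @param pseudo_masks list parallel to `tomograms`; elements may be NULL.
#' @return A trained `unet3d`.
#' @export
train_stage2 <- function(config, tomograms, human_masks,
                         pseudo_masks = vector("list", length(tomograms))) {
  stopifnot(length(tomograms) == length(human_masks),
            length(tomograms) == length(pseudo_masks))
  vols <- list(); msks <- list()
  for (i in seq_along(tomograms)) {
    if (!is.null(human_masks[[i]])) {
      vols[[length(vols) + 1L]] <- tomograms[[i]]
      msks[[length(msks) + 1L]] <- human_masks[[i]]
    }
  }
  for (i in seq_along(tomograms)) {
    if (!is.null(pseudo_masks[[i]])) {
      vols[[length(vols) + 1L]] <- tomograms[[i]]
      msks[[length(msks) + 1L]] <- pseudo_masks[[i]]
    }
  }
  seg_train(vols, msks, config)
}

#' Calibrate the binarization threshold on annotated slices
#'
#' Grid-searches the probability threshold that maximizes Dice between a
#' model's probability maps and the human-annotated (non-ignore) slices of
#' the training masks, pooled over volumes. This uses only the annotation
#' a real study has — no ground truth — and compensates for the
#' systematic under-confidence a model distilled from noisy labels shows
#' at object boundaries.
#'
#' @param maps list of `probability_map`s for the annotated volumes.
#' @param masks list of [make_training_mask()] results paired with `maps`.
#' @param grid candidate thresholds.
#' @return The threshold with the highest pooled Dice.
#' @export
calibrate_threshold <- function(maps, masks,
                                grid = seq(0.15, 0.85, by = 0.05)) {
  stopifnot(length(maps) == length(masks), length(maps) >= 1L)
  scores <- vapply(grid, function(th) {
    num <- 0; den <- 0
    for (k in seq_along(maps)) {
      mask <- as_mask_array(masks[[k]])
      p <- if (inherits(maps[[k]], "probability_map")) maps[[k]]$values
           else maps[[k]]
      zs <- which(apply(mask != 255L, 1, any))
      for (z in zs) {
        a <- p[z, , ] >= th
        b <- mask[z, , ] == 1L
        num <- num + 2 * sum(a & b)
        den <- den + sum(a) + sum(b)
      }
    }
    if (den == 0) 0 else num / den
  }, 0)
  grid[which.max(scores)]
}

#' Binarize a probability map
#'
#' Uses the `>=` convention at the threshold; raising the threshold never
#' adds foreground voxels.
#'
#' @param map a `probability_map` (or numeric array of probabilities).
#' @param threshold in (0, 1).
#' @return logical 3D array.
#' @export
binarize <- function(map, threshold = 0.5) {
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  p <- if (inherits(map, "probability_map")) map$values else map
  p >= threshold
}

#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty.
#'
#' @param a,b binary masks (logical or 0/1 arrays) of identical shape.
#' @return scalar in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  a <- a != 0; b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
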