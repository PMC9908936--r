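tiny_cfg <- function(cl = "granule", ...) {
  args <- list(target_class = cl, depth = 2L, base_channels = 4L,
               patch_size = 16L, epochs = 2L, steps_per_epoch = 10L,
               batch_size = 1L, seed = 7L)
  ov <- list(...)
  for (nm in names(ov)) args[[nm]] <- ov[[nm]]
  do.call(seg_config, args)
}

test_that("model building is a pure function of the seed", {
  m1 <- build_model(tiny_cfg())
  m2 <- build_model(tiny_cfg())
  expect_identical(m1$enc, m2$enc)
  expect_identical(m1$dec, m2$dec)
  m3 <- build_model(tiny_cfg(seed = 8))
  expect_false(identical(m1$enc[[1]]$w, m3$enc[[1]]$w))

  expect_error(seg_config(patch_size = 18, depth = 2), "divisible")
  expect_error(seg_config(binarize_threshold = 1.2), "in \\(0, 1\\)")
  expect_error(seg_config(pseudo_fg_conf = 0.4), "pseudo_bg_conf <")
})

test_that("an untrained model emits per-voxel probabilities in (0, 1) with
           the input shape", {
  m <- build_model(tiny_cfg())
  set.seed(1)
  v <- array(rnorm(16 * 32 * 16), c(16, 32, 16))
  pm <- predict(m, v)
  expect_equal(dim(pm$values), dim(v))
  expect_true(all(pm$values > 0 & pm$values < 1))
  expect_equal(pm$target_class, "granule")
})

test_that("training masks copy annotated slices and ignore the rest", {
  sim <- simulate_tomogram(small_params(seed = 23))
  sp <- sparsify_labels(sim$labels, 0.04, seed = 2, prefer_class = 2L)
  ann <- annotation_for_class(sp, "mitochondrion")
  tm <- make_training_mask(ann, dim(sim$labels$labels))
  d <- dim(sim$labels$labels)
  expect_equal(sum(tm$mask != 255L), length(ann$annotated_z) * d[2] * d[3])
  for (z in ann$annotated_z)
    expect_identical(tm$mask[z, , ],
                     array(as.integer(ann$planes[[as.character(z)]]),
                           d[2:3]))
  # fully annotated volume: no ignore voxels
  full <- annotation_for_class(sparsify_labels(sim$labels, 1, seed = 1),
                               "granule")
  expect_equal(sum(make_training_mask(full, d)$mask == 255L), 0)

  bad <- ann
  bad$planes[[1]] <- bad$planes[[1]][1:10, 1:10]
  expect_error(make_training_mask(bad, d), "plane shape")
  bad2 <- ann
  bad2$annotated_z[1] <- d[1] + 5L
  expect_error(make_training_mask(bad2, d), "outside")
})

test_that("training reduces the loss and needs non-degenerate supervision", {
  sim <- simulate_tomogram(small_params(seed = 29, noise_sd = 0.05,
                                        shape = c(40L, 80L, 80L),
                                        mito_radius_nm = c(16, 19),
                                        mito_length_nm = c(40, 55)))
  ann <- annotation_for_class(
    sparsify_labels(sim$labels, 0.05, seed = 3, prefer_class = 2L),
    "mitochondrion")
  tm <- make_training_mask(ann, dim(sim$labels$labels))
  cfg <- tiny_cfg("mitochondrion", epochs = 4L, steps_per_epoch = 15L)
  m <- seg_train(list(sim$tomogram), list(tm), cfg)
  expect_true(m$trained)
  expect_lt(mean(tail(m$loss_log, 5)), mean(head(m$loss_log, 5)))

  # same inputs, same seed: reproducible
  m2 <- seg_train(list(sim$tomogram), list(tm), cfg)
  expect_identical(m$enc, m2$enc)

  all_bg <- tm; all_bg$mask[all_bg$mask == 1L] <- 0L
  expect_error(seg_train(list(sim$tomogram), list(all_bg), cfg),
               class = "mitogranule_supervision_error")
  all_ig <- tm; all_ig$mask[] <- 255L
  expect_error(seg_train(list(sim$tomogram), list(all_ig), cfg),
               class = "mitogranule_supervision_error")
})

test_that("a volume with an all-ignore mask contributes nothing", {
  sim1 <- simulate_tomogram(small_params(seed = 31, shape = c(40L, 80L, 80L),
                                         mito_radius_nm = c(16, 19),
                                         mito_length_nm = c(40, 55)))
  sim2 <- simulate_tomogram(small_params(seed = 32, shape = c(40L, 80L, 80L),
                                         mito_radius_nm = c(16, 19),
                                         mito_length_nm = c(40, 55)))
  ann <- annotation_for_class(
    sparsify_labels(sim1$labels, 0.05, seed = 3, prefer_class = 2L),
    "mitochondrion")
  tm <- make_training_mask(ann, dim(sim1$labels$labels))
  ig <- list(mask = array(255L, dim(sim2$labels$labels)),
             provenance = "human")
  class(ig) <- "training_mask"
  cfg <- tiny_cfg("mitochondrion")
  with_ignored <- seg_train(list(sim1$tomogram, sim2$tomogram),
                            list(tm, ig), cfg)
  without <- seg_train(list(sim1$tomogram), list(tm), cfg)
  expect_identical(with_ignored$enc, without$enc)
  expect_identical(with_ignored$dec, without$dec)
})

test_that("pseudo-labels keep only confident voxels", {
  cfg <- tiny_cfg()
  flat <- structure(list(values = array(0.5, c(8, 8, 8)),
                         target_class = "granule"),
                    class = "probability_map")
  pm <- generate_pseudo_labels(flat, cfg)
  expect_true(all(pm$mask == 255L))
  expect_equal(pm$provenance, "pseudo")

  sure <- flat; sure$values[] <- 0.99
  expect_true(all(generate_pseudo_labels(sure, cfg)$mask == 1L))

  set.seed(9)
  mixed <- flat; mixed$values[] <- runif(512)
  got <- generate_pseudo_labels(mixed, cfg, boundary_guard_vox = 0)$mask
  expect_equal(sum(got == 1L), sum(mixed$values >= 0.95))
  expect_equal(sum(got == 0L), sum(mixed$values <= 0.05))

  # the boundary guard turns background labels near likely foreground
  # into ignore, and only those
  blob <- flat; blob$values[] <- 0.01
  blob$values[4:5, 4:5, 4:5] <- 0.99
  gm <- generate_pseudo_labels(blob, cfg, boundary_guard_vox = 1)$mask
  expect_true(all(gm[4:5, 4:5, 4:5] == 1L))
  expect_true(all(gm[3:6, 3:6, 3:6][gm[3:6, 3:6, 3:6] != 1L] == 255L))
  expect_true(all(gm[1, , ] == 0L))

  # slice mode: a slice is accepted only when >= 90% of it is confident,
  # and accepted slices are labeled in full by the binarize threshold
  half <- flat
  half$values[1:4, , ] <- 0.99          # confident slices
  half$values[1, 1, 1] <- 0.6           # one unconfident voxel, still >= 0.5
  half$values[5:8, , ] <- 0.5           # unconfident slices
  sl <- generate_pseudo_labels(half, cfg, mode = "slice")
  expect_true(all(sl$mask[1:4, , ] == 1L))  # includes the 0.6 voxel
  expect_true(all(sl$mask[5:8, , ] == 255L))
})

test_that("tiled prediction is deterministic and consistent across
           overlaps", {
  m <- build_model(tiny_cfg())
  set.seed(13)
  v <- array(rnorm(24 * 40 * 40), c(24, 40, 40))
  p1 <- predict(m, v)
  p2 <- predict(m, v)
  expect_identical(p1$values, p2$values)
  expect_true(all(p1$values >= 0 & p1$values <= 1))

  # a patch-sized volume is a single tile: prediction equals the direct
  # network output
  vp <- array(rnorm(16^3), c(16, 16, 16))
  one <- predict(m, vp, overlap = 0)
  direct <- 1 / (1 + exp(-mitogranule:::unet_forward(
    m, mitogranule:::standardize_volume(vp))))
  expect_equal(one$values, direct, tolerance = 1e-12)

  # the corner region covered by exactly one identical tile in both
  # tilings agrees exactly
  p0 <- predict(m, v, overlap = 0)
  p5 <- predict(m, v, overlap = 0.5)
  expect_equal(p0$values[1:8, 1:8, 1:8], p5$values[1:8, 1:8, 1:8],
               tolerance = 1e-12)

  expect_error(predict(m, array(0, c(8, 20, 20))), "smaller than patch")
})

test_that("binarization uses >= and is monotone in the threshold", {
  vals <- structure(list(values = array(0.5, c(4, 4, 4)),
                         target_class = "granule"),
                    class = "probability_map")
  expect_true(all(binarize(vals, 0.5)))

  set.seed(17)
  pm <- structure(list(values = array(runif(4^3, 0, 0.95), c(4, 4, 4)),
                       target_class = "granule"),
                  class = "probability_map")
  expect_gte(sum(binarize(pm, 0.3)), sum(binarize(pm, 0.7)))
  expect_equal(sum(binarize(pm, 0.99)), 0)
  expect_error(binarize(pm, 0), "\\(0, 1\\)")
})

test_that("dice matches hand arithmetic and edge conventions", {
  a <- array(FALSE, c(4, 4, 4)); b <- a
  expect_equal(dice(a, b), 1)         # both empty
  a[1:2, 1, 1] <- TRUE
  expect_equal(dice(a, a), 1)
  b[3:4, 4, 4] <- TRUE
  expect_equal(dice(a, b), 0)         # disjoint
  # |a| = 50 subset of |b| = 100 -> 2*50/150
  a2 <- array(FALSE, c(10, 10, 10)); b2 <- a2
  a2[1:50] <- TRUE; b2[1:100] <- TRUE
  expect_equal(dice(a2, b2), 2 * 50 / 150, tolerance = 1e-12)
  expect_error(dice(a, array(FALSE, c(2, 2, 2))), "shapes differ")
})

test_that("stage-2 with no pseudo masks reduces exactly to stage 1", {
  sim <- simulate_tomogram(small_params(seed = 37, shape = c(40L, 80L, 80L),
                                        mito_radius_nm = c(16, 19),
                                        mito_length_nm = c(40, 55)))
  ann <- annotation_for_class(
    sparsify_labels(sim$labels, 0.05, seed = 3, prefer_class = 2L),
    "mitochondrion")
  tm <- make_training_mask(ann, dim(sim$labels$labels))
  cfg <- tiny_cfg("mitochondrion")
  s1 <- seg_train(list(sim$tomogram), list(tm), cfg)
  s2 <- train_stage2(cfg, list(sim$tomogram), list(tm))
  expect_identical(s1$enc, s2$enc)
  expect_identical(s1$out, s2$out)
})

test_that("contradictory pseudo-labels poison stage-2 training", {
  sim1 <- simulate_tomogram(small_params(seed = 41, noise_sd = 0.05,
                                         shape = c(40L, 80L, 80L),
                                         mito_radius_nm = c(16, 19),
                                         mito_length_nm = c(40, 55)))
  sim2 <- simulate_tomogram(small_params(seed = 42, noise_sd = 0.05,
                                         shape = c(40L, 80L, 80L),
                                         mito_radius_nm = c(16, 19),
                                         mito_length_nm = c(40, 55)))
  ann <- annotation_for_class(
    sparsify_labels(sim1$labels, 0.05, seed = 3, prefer_class = 2L),
    "mitochondrion")
  tm <- make_training_mask(ann, dim(sim1$labels$labels))
  cfg <- tiny_cfg("mitochondrion", epochs = 4L, steps_per_epoch = 15L)

  gt2 <- class_mask(sim2$labels, "mitochondrion")
  good <- structure(list(mask = array(as.integer(gt2), dim(gt2)),
                         provenance = "pseudo"), class = "training_mask")
  bad <- structure(list(mask = array(as.integer(!gt2), dim(gt2)),
                        provenance = "pseudo"), class = "training_mask")

  held <- simulate_tomogram(small_params(seed = 43, noise_sd = 0.05,
                                         shape = c(40L, 80L, 80L),
                                         mito_radius_nm = c(16, 19),
                                         mito_length_nm = c(40, 55)))
  gt_h <- class_mask(held$labels, "mitochondrion")
  dice_of <- function(pseudo) {
    m <- train_stage2(cfg, list(sim1$tomogram, sim2$tomogram),
                      list(tm, NULL), list(NULL, pseudo))
    dice(binarize(predict(m, held$tomogram), 0.5), gt_h)
  }
  expect_gt(dice_of(good), dice_of(bad))
})
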