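test_that("an empty scene is pure noise with all-background labels", {
  p <- small_params(seed = 3, n_mitochondria = 0L, noise_sd = 0.2)
  sim <- simulate_tomogram(p)
  expect_true(all(sim$labels$labels == 0L))
  expect_equal(sd(as.vector(sim$tomogram$voxels)), 0.2, tolerance = 0.05)
  expect_equal(nrow(sim$truth$granules), 0)
})

test_that("identical seeds give bit-identical scenes, new seeds differ", {
  p <- small_params(seed = 5)
  s1 <- simulate_tomogram(p)
  s2 <- simulate_tomogram(p)
  expect_identical(s1$tomogram$voxels, s2$tomogram$voxels)
  expect_identical(s1$labels$labels, s2$labels$labels)
  expect_identical(s1$truth, s2$truth)

  s3 <- simulate_tomogram(small_params(seed = 6))
  expect_false(identical(s1$tomogram$voxels, s3$tomogram$voxels))
})

test_that("noise and blur corrupt the tomogram but never the labels", {
  clean <- simulate_tomogram(small_params(seed = 8, noise_sd = 0,
                                          z_blur_sigma_vox = 0))
  noisy <- simulate_tomogram(small_params(seed = 8, noise_sd = 0.3,
                                          z_blur_sigma_vox = 2))
  expect_identical(clean$labels$labels, noisy$labels$labels)
  expect_false(identical(clean$tomogram$voxels, noisy$tomogram$voxels))
})

test_that("granule counts follow the Poisson rate over matrix volume", {
  # 50 seeds; oracle: Poisson mean = rate x summed interior volume, with
  # counts measured from the generated label volumes by connected
  # components
  rate <- 8e-5
  total_count <- 0
  total_lambda <- 0
  for (s in 1:50) {
    p <- small_params(seed = 1000 + s, n_mitochondria = 1L,
                      granule_rate_per_nm3 = rate,
                      granule_log_median_nm3 = 600,
                      granule_log_sigma = 0.3,
                      shape = c(40L, 80L, 80L),
                      mito_radius_nm = c(22, 26), mito_length_nm = c(45, 60))
    sim <- simulate_tomogram(p)
    cc <- connected_components(class_mask(sim$labels, "granule"), 26,
                               p$voxel_size_A, class = "granule")
    total_count <- total_count + nrow(cc)
    total_lambda <- total_lambda + rate *
      sum(sim$truth$mitochondria$interior_volume_nm3)
  }
  se <- sqrt(total_lambda)
  expect_lt(abs(total_count - total_lambda), 3 * se)
})

test_that("every granule voxel is embedded inside a mitochondrion", {
  shift <- function(a, dz, dy, dx) {
    d <- dim(a)
    out <- array(FALSE, d)
    zs <- max(1, 1 + dz):min(d[1], d[1] + dz)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    xs <- max(1, 1 + dx):min(d[3], d[3] + dx)
    out[zs, ys, xs] <- a[zs - dz, ys - dy, xs - dx]
    out
  }
  for (s in 1:20) {
    sim <- simulate_tomogram(small_params(seed = 2000 + s,
                                          granule_rate_per_nm3 = 2e-4))
    lab <- sim$labels$labels
    gr <- lab == 2L
    if (!any(gr)) next
    bg <- lab == 0L
    # dilate granules by one voxel (26-neighbourhood): must not reach
    # background, i.e. granules are always wrapped in mitochondrion
    touches_bg <- FALSE
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      if (any(shift(gr, dz, dy, dx) & bg)) { touches_bg <- TRUE; break }
    }
    expect_false(touches_bg)
    expect_true(all(lab %in% c(0L, 1L, 2L)))
  }
})

test_that("generated granule volumes recover the configured lognormal
           median", {
  vols <- numeric(0)
  s <- 0
  while (length(vols) < 500 && s < 80) {
    s <- s + 1
    sim <- simulate_tomogram(small_params(
      seed = 3000 + s, granule_rate_per_nm3 = 3e-4,
      granule_log_median_nm3 = 600, granule_log_sigma = 0.5))
    vols <- c(vols, sim$truth$granules$volume_nm3)
  }
  expect_gte(length(vols), 500)
  expect_lt(abs(median(vols) - 600) / 600, 0.10)
})

test_that("packing failure raises an explicit error for impossible scenes", {
  expect_error(simulation_params(shape = c(10L, 10L, 10L),
                                 mito_radius_nm = c(35, 45)),
               "too small")
  p <- small_params(n_mitochondria = 12L)  # cannot pack 12 fat tubes
  expect_error(simulate_tomogram(p), class = "mitogranule_packing_error")
})

test_that("cohorts derive stable child seeds and unique conditions", {
  specs <- list(
    condition_spec("control", 2, params = list(granule_log_median_nm3 = 800)),
    condition_spec("disease", 2, params = list(granule_log_median_nm3 = 1600)))
  base <- small_params()
  ch <- simulate_cohort(specs, seed = 9, base_params = base)
  expect_equal(length(ch$entries), 4)
  expect_equal(as.vector(table(ch$manifest$condition)), c(2, 2))

  ch2 <- simulate_cohort(specs, seed = 9, base_params = base)
  expect_identical(ch$manifest, ch2$manifest)
  expect_identical(ch$entries[[3]]$sim$tomogram$voxels,
                   ch2$entries[[3]]$sim$tomogram$voxels)

  # adding tomograms never changes content for shared (condition, index)
  specs3 <- list(condition_spec("control", 3,
                                params = list(granule_log_median_nm3 = 800)),
                 specs[[2]])
  ch3 <- simulate_cohort(specs3, seed = 9, base_params = base)
  expect_identical(ch3$entries[[1]]$sim$tomogram$voxels,
                   ch$entries[[1]]$sim$tomogram$voxels)

  expect_error(simulate_cohort(list(condition_spec("a"),
                                    condition_spec("a")), 1, base),
               "duplicate")
})

test_that("a disease cohort with doubled median yields larger granules", {
  base <- small_params(granule_rate_per_nm3 = 2e-4,
                       granule_log_median_nm3 = 600,
                       granule_log_sigma = 0.4)
  specs <- list(
    condition_spec("control", 10),
    condition_spec("disease", 10, params = list(granule_log_median_nm3 = 1200)))
  ch <- simulate_cohort(specs, seed = 4, base_params = base)
  vols <- split(
    unlist(lapply(ch$entries, function(e) e$sim$truth$granules$volume_nm3)),
    rep(ch$manifest$condition,
        vapply(ch$entries, function(e) nrow(e$sim$truth$granules), 0L)))
  expect_gt(median(vols$disease), median(vols$control))
})

test_that("slice sparsification selects the advertised number of slices", {
  sim <- simulate_tomogram(small_params(seed = 12))

  full <- sparsify_labels(sim$labels, 1.0, seed = 1)
  expect_equal(length(full$annotated_z), dim(sim$labels$labels)[1])
  expect_identical(densify_annotation(full), sim$labels$labels)

  lab100 <- label_volume(array(0L, c(100, 4, 4)), 13.88)
  sp <- sparsify_labels(lab100, 0.02, seed = 2)
  expect_equal(length(sp$annotated_z), 2)

  sp1 <- sparsify_labels(sim$labels, 0.1, seed = 3)
  sp2 <- sparsify_labels(sim$labels, 0.1, seed = 3)
  expect_identical(sp1$annotated_z, sp2$annotated_z)

  # informative mode picks slices that actually contain granules
  spg <- sparsify_labels(sim$labels, 0.05, seed = 4, prefer_class = 2L)
  hit <- vapply(spg$planes, function(p) any(p == 2L), TRUE)
  gz <- which(apply(sim$labels$labels == 2L, 1, any))
  expect_equal(sum(hit), min(length(spg$annotated_z), length(gz)))

  expect_error(sparsify_labels(sim$labels, 0), "\\(0, 1\\]")
  expect_error(sparsify_labels(label_volume(array(integer(0), c(0, 0, 0)),
                                            10), 0.5), "empty")
})
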