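test_that("corner-touching voxels split by connectivity", {
  m <- array(0L, c(2, 2, 2))
  m[1, 1, 1] <- 1L
  m[2, 2, 2] <- 1L
  cc26 <- connected_components(m, 26, voxel_size_A = 10)
  cc6 <- connected_components(m, 6, voxel_size_A = 10)
  expect_equal(nrow(cc26), 1)
  expect_equal(nrow(cc6), 2)
  expect_equal(connected_components(array(0L, c(3, 3, 3)), 26, 10),
               connected_components(array(0L, c(3, 3, 3)), 26, 10))
  expect_equal(nrow(connected_components(array(0L, c(3, 3, 3)), 26, 10)), 0)
  expect_error(connected_components(array(2L, c(2, 2, 2)), 26, 10),
               "binary")
  expect_error(connected_components(m, 10, 10), "6, 18, or 26")
})

test_that("labeling matches the brute-force flood fill on random volumes", {
  set.seed(61)
  for (i in 1:12) {
    d <- sample(5:9, 3, replace = TRUE)
    m <- array(rbinom(prod(d), 1, 0.35), d)
    for (conn in c(6L, 18L, 26L)) {
      got <- attr(connected_components(m, conn, 10), "label_array")
      want <- flood_fill_cc(m, conn)
      expect_identical(cc_partition(got), cc_partition(want))
    }
  }
})

test_that("component bookkeeping: conservation, centroids, volumes", {
  set.seed(62)
  m <- array(rbinom(6 * 7 * 8, 1, 0.3), c(6, 7, 8))
  cc <- connected_components(m, 26, voxel_size_A = 10)
  expect_equal(sum(cc$voxel_count), sum(m))
  expect_equal(cc$volume_nm3, cc$voxel_count * 1.0)  # 10 A voxel = 1 nm^3

  m2 <- array(0L, c(5, 5, 5))
  m2[2:3, 4, 5] <- 1L
  cc2 <- connected_components(m2, 26, voxel_size_A = 10)
  expect_equal(cc2$centroid_z, 1.5)   # 0-based mean of z = 2,3
  expect_equal(cc2$centroid_y, 3)
  expect_equal(cc2$centroid_x, 4)
  expect_equal(c(cc2$bbox_z0, cc2$bbox_z1), c(1L, 2L))
})

test_that("voxel volume converts Angstrom and binning to nm^3", {
  expect_equal(voxel_volume_nm3(10, 1), 1.0)
  expect_equal(voxel_volume_nm3(3.47, 4), 1.388^3, tolerance = 1e-4)
  expect_equal(voxel_volume_nm3(5, 4) / voxel_volume_nm3(5, 2), 8)
  expect_error(voxel_volume_nm3(-1), "positive")
})

test_that("volume-range filtering is a monotone order-preserving predicate", {
  comps <- data.frame(id = 1:3, class = "granule", voxel_count = c(1, 10, 100),
                      volume_nm3 = c(10, 100, 1000))
  expect_equal(filter_components_by_volume(comps, c(0, Inf))$id, 1:3)
  expect_equal(filter_components_by_volume(comps, c(50, 500))$id, 2L)

  set.seed(63)
  for (i in 1:10) {
    v <- data.frame(id = 1:20, volume_nm3 = rlnorm(20, 4, 1))
    lo <- runif(1, 0, 50); hi <- 2 * lo + runif(1, 10, 400)
    n1 <- nrow(filter_components_by_volume(v, c(lo, hi)))
    n2 <- nrow(filter_components_by_volume(v, c(lo * 2, hi)))
    expect_lte(n2, n1)
  }
  expect_error(filter_components_by_volume(comps, c(5, 2)), "min < max")
})

test_that("granule assignment honours the centroid and overlap rules", {
  # mitochondrion occupies x in 1..4 of a 7x7x9 box
  mito_mask <- array(0L, c(7, 7, 9))
  mito_mask[, , 1:4] <- 1L

  # granule A fully inside; granule B straddles: 6/13 of its voxels are
  # inside (< 50%), but its inside voxels sit deep (x = 2) while the
  # outside ones sit just past the boundary (x = 5), so the centroid voxel
  # lands inside: mean x (1-based) = (4*2 + 3 + 4 + 7*5)/13 = 3.85 -> 4
  gran_mask <- array(0L, c(7, 7, 9))
  gran_mask[6, 6, 2:3] <- 1L                        # A: 2 voxels, inside
  b_vox <- rbind(c(3, 3, 2), c(3, 4, 2), c(4, 3, 2), c(4, 4, 2),  # deep in
                 c(3, 3, 3), c(3, 3, 4),                          # bridge in
                 c(3, 3, 5), c(3, 4, 5), c(4, 3, 5), c(4, 4, 5),  # outside
                 c(2, 3, 5), c(5, 3, 5), c(3, 2, 5))
  gran_mask[b_vox] <- 1L

  mito <- connected_components(mito_mask, 26, 10, class = "mitochondrion")
  gran <- connected_components(gran_mask, 26, 10, class = "granule")
  expect_equal(nrow(gran), 2)

  ass_c <- assign_granules(gran, mito, config = quant_config())
  ass_o <- assign_granules(gran, mito,
                           config = quant_config(
                             containment_rule = "overlap_fraction",
                             min_overlap_fraction = 0.5))
  a_id <- gran$id[gran$voxel_count == 2]
  b_id <- gran$id[gran$voxel_count == 13]
  # A: fully inside under both rules, containment fraction 1
  expect_equal(ass_c$parent_mito_id[ass_c$granule_id == a_id], mito$id)
  expect_equal(ass_c$containment_fraction[ass_c$granule_id == a_id], 1)
  expect_equal(ass_o$parent_mito_id[ass_o$granule_id == a_id], mito$id)
  # B: 6/13 inside -> discarded under the overlap rule
  expect_true(is.na(ass_o$parent_mito_id[ass_o$granule_id == b_id]))
  # but its centroid voxel is inside -> retained under the centroid rule
  cx <- round(gran$centroid_x[gran$id == b_id]) + 1
  expect_lte(cx, 4)
  expect_equal(ass_c$parent_mito_id[ass_c$granule_id == b_id], mito$id)

  # a granule entirely outside any mitochondrion is unassigned
  lone <- array(0L, c(7, 7, 9)); lone[2, 2, 8] <- 1L
  gl <- connected_components(lone, 26, 10, class = "granule")
  expect_true(is.na(assign_granules(gl, mito)$parent_mito_id))

  expect_error(
    assign_granules(gl, mito,
                    mito_label_volume = array(0L, c(2, 2, 2))),
    "different shapes")
})

test_that("per-mitochondrion summaries compute densities and zero counts", {
  mito <- data.frame(id = c(1L, 2L), class = "mitochondrion",
                     voxel_count = c(1000L, 500L),
                     volume_nm3 = c(1000, 500))
  gran <- data.frame(id = 1:3, class = "granule", voxel_count = 5L,
                     volume_nm3 = c(10, 20, 30))
  ass <- data.frame(granule_id = 1:3, parent_mito_id = c(1L, 1L, 1L),
                    containment_fraction = 1)
  s <- summarize_mitochondria(mito, ass, gran)
  expect_equal(s$granule_count, c(3L, 0L))
  expect_equal(s$granule_density_per_nm3, c(0.003, 0))
  expect_equal(sort(s$granule_volumes_nm3[[1]]), c(10, 20, 30))
  expect_equal(length(s$granule_volumes_nm3[[2]]), 0)

  bad <- ass; bad$parent_mito_id[1] <- 99L
  expect_error(summarize_mitochondria(mito, bad, gran), "dangling")
})

test_that("ground-truth labels push through quantify to exact bookkeeping", {
  sim <- simulate_tomogram(small_params(seed = 17))
  mm <- class_mask(sim$labels, "mitochondrion")
  gm <- class_mask(sim$labels, "granule")
  cfg <- quant_config(mito_volume_range_nm3 = c(1, Inf),
                      granule_volume_range_nm3 = c(0.1, Inf))
  q <- quantify_tomogram(mm, gm, meta = list(voxel_size_A = 13.88),
                         config = cfg)
  expect_equal(nrow(q$granules), nrow(sim$truth$granules))
  expect_equal(sort(q$summaries$granule_count),
               sort(sim$truth$mitochondria$granule_count))
  expect_equal(sort(q$granules$volume_nm3),
               sort(sim$truth$granules$volume_nm3))

  # empty masks -> empty outputs
  q0 <- quantify_tomogram(array(0L, c(4, 4, 4)), array(0L, c(4, 4, 4)),
                          meta = list(voxel_size_A = 10))
  expect_equal(nrow(q0$summaries), 0)
  expect_equal(nrow(q0$granules), 0)

  # invariance to axis permutation of the scene (component ids relabel)
  flip <- function(a) a[rev(seq_len(dim(a)[1])), , ]
  q2 <- quantify_tomogram(flip(mm), flip(gm),
                          meta = list(voxel_size_A = 13.88), config = cfg)
  expect_equal(sort(q2$summaries$granule_count),
               sort(q$summaries$granule_count))
  expect_equal(sort(q2$granules$volume_nm3), sort(q$granules$volume_nm3))

  # shrinking a range never increases downstream counts
  cfg2 <- quant_config(mito_volume_range_nm3 = c(1, Inf),
                       granule_volume_range_nm3 = c(500, Inf))
  q3 <- quantify_tomogram(mm, gm, meta = list(voxel_size_A = 13.88),
                          config = cfg2)
  expect_lte(nrow(q3$granules), nrow(q$granules))
  expect_lte(sum(q3$summaries$granule_count), sum(q$summaries$granule_count))
})

test_that("measurement tables emit granule volumes and mito densities", {
  sim <- simulate_tomogram(small_params(seed = 19))
  q <- quantify_tomogram(class_mask(sim$labels, "mitochondrion"),
                         class_mask(sim$labels, "granule"),
                         meta = list(voxel_size_A = 13.88,
                                     tomogram_id = "t1"),
                         config = quant_config(
                           mito_volume_range_nm3 = c(1, Inf),
                           granule_volume_range_nm3 = c(0.1, Inf)))
  tab <- measurements_table(q, "control")
  expect_setequal(unique(tab$measure),
                  c("granule_volume_nm3", "granule_density_per_nm3"))
  expect_equal(sum(tab$measure == "granule_volume_nm3"), nrow(q$granules))
  expect_equal(sum(tab$measure == "granule_density_per_nm3"),
               nrow(q$summaries))
  expect_true(all(tab$condition == "control"))
})
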