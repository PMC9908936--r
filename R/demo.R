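#' Bundled demonstration cohort and configurations
#'
#' A desk-scale three-condition experiment that exercises every stage of the
#' pipeline: `control` and `rescue` share the granule-volume law while
#' `disease` doubles its median, mirroring the enlarged-granule phenotype
#' and its rescue. Volumes are generated at the post-bin-4 working scale
#' (13.88 A/voxel) with mild noise and z blurring so that the two-stage
#' segmentation is learnable from 2% slice annotation on a single CPU.
#'
#' @param seed master seed; per-tomogram child seeds are derived by stable
#'   hashing of (seed, condition, index).
#' @param n_per_condition tomograms per condition. The default 5 is sized
#'   for power: at roughly 7 granules per tomogram and the effect
#'   attenuation segmentation introduces, detecting the doubled median at
#'   an adjusted 0.01 level needs on the order of 30 granules per group.
#'   The segmentation stages (training, pseudo-labeling) always operate on
#'   the first three control and disease tomograms only; later tomograms
#'   are prediction-only analysis volumes.
#' @return A list with `base_params` ([simulation_params()]), `specs`
#'   (list of [condition_spec()]), `seg_configs` (per-class
#'   [seg_config()]s), `quant` ([quant_config()]), `family` (declared
#'   comparison pairs), `annotation_fraction`, and `train_ids`.
#' @export
demo_cohort <- function(seed = 1L, n_per_condition = 5L) {
  base <- simulation_params(
    shape = c(64L, 128L, 128L), voxel_size_A = 13.88, n_mitochondria = 2L,
    mito_radius_nm = c(26, 30), mito_length_nm = c(70, 90),
    granule_rate_per_nm3 = 7e-5, granule_log_median_nm3 = 2500,
    granule_log_sigma = 0.4, noise_sd = 0.05, z_blur_sigma_vox = 0.5,
    seed = seed)
  specs <- list(
    condition_spec("control", n_per_condition),
    condition_spec("disease", n_per_condition,
                   params = list(granule_log_median_nm3 = 5000)),
    condition_spec("rescue", n_per_condition))
  seg_configs <- list(
    mitochondrion = seg_config("mitochondrion", depth = 2L,
                               base_channels = 8L, patch_size = 16L,
                               epochs = 12L, steps_per_epoch = 25L,
                               batch_size = 2L, seed = seed + 101L),
    granule = seg_config("granule", depth = 2L, base_channels = 8L,
                         patch_size = 20L, epochs = 24L,
                         steps_per_epoch = 25L, batch_size = 2L,
                         seed = seed + 202L))
  # stage 2 trains on a far larger (pseudo-labeled) set than stage 1, so it
  # gets a larger batch (and, for the granule class, a larger step size)
  stage2 <- list(mitochondrion = list(epochs = 12L, batch_size = 4L,
                                      learning_rate = 3e-3),
                 granule = list(epochs = 24L, batch_size = 4L,
                                learning_rate = 5e-3))
  # expected-volume windows bracket the configured granule law (about
  # +/- 3 sdlog around the condition medians) and the organelle scale
  list(base_params = base, specs = specs, seg_configs = seg_configs,
       stage2 = stage2,
       quant = quant_config(mito_volume_range_nm3 = c(5e4, Inf),
                            granule_volume_range_nm3 = c(500, 5e4)),
       family = list(c("control", "disease"), c("control", "rescue")),
       annotation_fraction = 0.02,
       train_ids = c("control_01", "control_02", "disease_01", "disease_02"),
       heldout_ids = c("control_03", "disease_03"),
       seg_ids = c(paste0("control_0", 1:3), paste0("disease_0", 1:3)),
       seed = as.integer(seed))
}

#' Run the demonstration two-stage analysis in memory
#'
#' Generates the [demo_cohort()], trains the stage-1 models on the sparsely
#' annotated training tomograms, pseudo-labels the control/disease volumes
#' (slice mode), retrains (stage 2, with the larger batch/epoch budget its
#' expanded training set warrants), calibrates each model's binarization
#' threshold on the human-annotated slices, predicts every tomogram,
#' quantifies, and runs the group comparisons. Returns everything the
#' acceptance checks need: held-out Dice per stage and class, the
#' measurement table, and the comparison results.
#'
#' @param demo a [demo_cohort()] list.
#' @param progress print stage timings.
#' @return A list with `dice_stage1`, `dice_stage2` (named held-out Dice,
#'   each stage at its calibrated threshold), `thresholds`,
#'   `measurements`, `results`, `models`, and the cohort `truth`.
#' @export
run_demo_analysis <- function(demo = demo_cohort(), progress = FALSE) {
  say <- function(...) if (progress) message(sprintf(...))
  cohort <- simulate_cohort(demo$specs, seed = demo$seed,
                            base_params = demo$base_params)
  sims <- lapply(cohort$entries, function(e) e$sim)
  names(sims) <- cohort$manifest$tomogram_id
  conds <- stats::setNames(cohort$manifest$condition,
                           cohort$manifest$tomogram_id)
  seg_ids <- demo$seg_ids   # the 2x3 learning cohort; the rest is
  train_ids <- demo$train_ids  # predicted only
  heldout <- demo$heldout_ids

  models <- list()
  d1 <- c(); d2 <- c()
  th <- list()
  maps <- stats::setNames(vector("list", length(sims)), names(sims))
  for (cl in c("mitochondrion", "granule")) {
    cfg <- demo$seg_configs[[cl]]
    anns <- lapply(train_ids, function(id) annotation_for_class(
      sparsify_labels(sims[[id]]$labels, demo$annotation_fraction,
                      seed = stable_seed(demo$seed, id, "annotate"),
                      prefer_class = 2L), cl))
    hmask <- Map(function(a, id) make_training_mask(a,
                                                    dim(sims[[id]]$labels$labels)),
                 anns, train_ids)
    t0 <- proc.time()
    m1 <- seg_train(lapply(train_ids, function(id) sims[[id]]$tomogram),
                    hmask, cfg)
    say("%s stage-1 training: %.0f s", cl, (proc.time() - t0)[3])

    t0 <- proc.time()
    maps1 <- lapply(seg_ids, function(id) predict(m1, sims[[id]]$tomogram))
    names(maps1) <- seg_ids
    th1 <- calibrate_threshold(maps1[train_ids], hmask)
    for (id in heldout)
      d1[paste(cl, id, sep = ".")] <- dice(
        binarize(maps1[[id]], th1), class_mask(sims[[id]]$labels, cl))
    pmask <- lapply(seg_ids, function(id)
      generate_pseudo_labels(maps1[[id]], cfg, mode = "slice"))
    hm_all <- stats::setNames(vector("list", length(seg_ids)), seg_ids)
    for (k in seq_along(train_ids)) hm_all[[train_ids[k]]] <- hmask[[k]]
    cfg2 <- cfg
    for (nm in names(demo$stage2[[cl]]))
      cfg2[[nm]] <- demo$stage2[[cl]][[nm]]
    m2 <- train_stage2(cfg2, lapply(seg_ids, function(id) sims[[id]]$tomogram),
                       hm_all, pmask)
    say("%s pseudo-labeling + stage-2: %.0f s", cl, (proc.time() - t0)[3])

    t0 <- proc.time()
    mp <- lapply(names(sims), function(id) predict(m2, sims[[id]]$tomogram))
    names(mp) <- names(sims)
    th2 <- calibrate_threshold(mp[train_ids], hmask)
    for (id in heldout)
      d2[paste(cl, id, sep = ".")] <- dice(
        binarize(mp[[id]], th2), class_mask(sims[[id]]$labels, cl))
    say("%s final prediction + calibration: %.0f s (thresholds %.2f / %.2f)",
        cl, (proc.time() - t0)[3], th1, th2)
    for (id in names(sims)) maps[[id]][[cl]] <- mp[[id]]
    th[[cl]] <- list(stage1 = th1, stage2 = th2)
    models[[cl]] <- m2
  }

  meas <- do.call(rbind, lapply(names(sims), function(id) {
    q <- quantify_tomogram(
      binarize(maps[[id]]$mitochondrion, th$mitochondrion$stage2),
      binarize(maps[[id]]$granule, th$granule$stage2),
      meta = list(voxel_size_A = demo$base_params$voxel_size_A,
                  tomogram_id = id),
      config = demo$quant)
    measurements_table(q, conds[[id]], id)
  }))
  results <- run_group_comparisons(meas, family = demo$family)

  list(dice_stage1 = d1, dice_stage2 = d2, thresholds = th,
       measurements = meas, results = results, models = models,
       truth = lapply(sims, function(s) s$truth))
}
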