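#' Read and write cohort manifests
#'
#' A manifest is a plain-text tab-separated table associating each tomogram
#' with its condition and on-disk volumes: columns `tomogram_id`,
#' `condition`, `tomogram_path`, optional `labels_path`, optional `seed`.
#'
#' @param path manifest TSV path.
#' @return Data frame.
#' @export
read_manifest <- function(path) {
  mf <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("tomogram_id", "condition", "tomogram_path")
  if (!all(need %in% names(mf)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(mf$tomogram_id))
    stop("duplicate tomogram_id in manifest")
  mf
}

#' @param manifest manifest data frame.
#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Writes each tomogram and its ground-truth labels as MRC2014 plus a
#' manifest TSV, the on-disk form consumed by [run_pipeline()] and the
#' command-line interface.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$entries, function(e) {
    tp <- file.path(dir, paste0(e$tomogram_id, "_tomo.mrc"))
    lp <- file.path(dir, paste0(e$tomogram_id, "_labels.mrc"))
    write_mrc(e$sim$tomogram, tp)
    write_mrc(e$sim$labels, lp)
    data.frame(tomogram_id = e$tomogram_id, condition = e$condition,
               tomogram_path = tp, labels_path = lp,
               seed = e$sim$params$seed)
  })
  mf <- do.call(rbind, rows)
  write_manifest(mf, file.path(dir, "manifest.tsv"))
  invisible(mf)
}

pkg_version <- function() {
  as.character(utils::packageVersion("mitogranule"))
}

write_provenance <- function(out_dir, stage, config, inputs, outputs,
                             seed = NULL) {
  pdir <- file.path(out_dir, "provenance")
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  rec <- list(
    stage = stage,
    config = config,
    seed = seed,
    input_checksums = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    output_checksums = as.list(tools::md5sum(outputs[file.exists(outputs)])),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    tool_version = pkg_version())
  jsonlite::write_json(rec, file.path(pdir, paste0(stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(rec)
}

# a stage may be skipped iff its provenance exists, its recorded outputs
# still exist with matching checksums, and its recorded inputs are unchanged
stage_current <- function(out_dir, stage, inputs) {
  pfile <- file.path(out_dir, "provenance", paste0(stage, ".json"))
  if (!file.exists(pfile)) return(FALSE)
  rec <- tryCatch(jsonlite::read_json(pfile), error = function(e) NULL)
  if (is.null(rec)) return(FALSE)
  outs <- names(rec$output_checksums)
  if (length(outs) == 0 || !all(file.exists(outs))) return(FALSE)
  now_out <- tools::md5sum(outs)
  if (!identical(unname(now_out), unlist(rec$output_checksums,
                                         use.names = FALSE))) return(FALSE)
  ins <- names(rec$input_checksums)
  if (!all(file.exists(ins))) return(FALSE)
  now_in <- tools::md5sum(ins)
  identical(unname(now_in),
            unlist(rec$input_checksums, use.names = FALSE))
}

#' Run the end-to-end analysis
#'
#' Executes the full chain on a synthetic cohort or an on-disk manifest:
#' optional preprocessing, stage-1 training per class on sparsely annotated
#' slices, pseudo-labeling, stage-2 retraining, tiled prediction,
#' binarization, quantification, and the group statistics. Every stage
#' writes a provenance record (resolved config, seeds, input/output
#' checksums); a stage whose outputs are present and whose recorded
#' checksums still match is skipped on re-run, so deleting an intermediate
#' resumes from the last valid stage.
#'
#' With `use_ground_truth = TRUE` the segmentation stages are bypassed and
#' the ground-truth labels are quantified directly (the generator-as-oracle
#' shortcut).
#'
#' @param cohort a [simulate_cohort()] result, or a manifest data frame /
#'   TSV path whose rows point at MRC volumes (with `labels_path` when
#'   training or ground truth is needed).
#' @param out_dir results directory.
#' @param seg_configs named list of [seg_config()]s for `mitochondrion` and
#'   `granule` (ignored when `use_ground_truth`).
#' @param quant a [quant_config()].
#' @param annotation_fraction fraction of z slices "manually" annotated on
#'   training tomograms.
#' @param annotation_prefer_class class id preferred when picking annotated
#'   slices (default 2: slices where granules are visible, emulating an
#'   annotator who labels informative slices); NULL for uniform slices.
#' @param train_ids tomogram ids used for training; default: the first
#'   tomogram of every condition.
#' @param family,control,adjustment passed to [run_group_comparisons()].
#' @param preprocess optional [preprocess_config()]; NULL skips
#'   preprocessing (synthetic volumes are already at the working scale).
#' @param use_ground_truth bypass segmentation and quantify the labels.
#' @param seed master seed; child seeds per (tomogram, stage) are derived by
#'   stable hashing.
#' @return A list with the measurements table, the `group_comparison_set`,
#'   and the paths written.
#' @export
run_pipeline <- function(cohort, out_dir,
                         seg_configs = list(
                           mitochondrion = seg_config("mitochondrion"),
                           granule = seg_config("granule")),
                         quant = quant_config(),
                         annotation_fraction = 0.02,
                         annotation_prefer_class = 2L,
                         train_ids = NULL,
                         family = NULL, control = NULL,
                         adjustment = "bonferroni",
                         preprocess = NULL,
                         use_ground_truth = FALSE,
                         seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # ---- load inputs ---------------------------------------------------
  if (inherits(cohort, "simulated_cohort")) {
    vdir <- file.path(out_dir, "volumes")
    if (!stage_current(out_dir, "ingest",
                       character(0)) || !dir.exists(vdir)) {
      mf <- write_cohort(cohort, vdir)
      write_provenance(out_dir, "ingest", list(source = "simulated_cohort"),
                       character(0),
                       c(mf$tomogram_path, mf$labels_path,
                         file.path(vdir, "manifest.tsv")), seed)
    }
    mf <- read_manifest(file.path(vdir, "manifest.tsv"))
  } else if (is.character(cohort)) {
    mf <- read_manifest(cohort)
  } else {
    mf <- cohort
  }
  tomos <- lapply(mf$tomogram_path, read_mrc)
  labs <- if (!is.null(mf$labels_path))
    lapply(mf$labels_path, read_mrc, as = "labels") else NULL
  names(tomos) <- mf$tomogram_id
  if (!is.null(labs)) names(labs) <- mf$tomogram_id

  # ---- optional preprocessing ---------------------------------------
  if (!is.null(preprocess)) {
    tomos <- lapply(tomos, preprocess_tomogram, config = preprocess)
    write_provenance(out_dir, "preprocess", unclass(preprocess),
                     mf$tomogram_path, character(0), seed)
  }

  # ---- masks: segmentation or ground truth --------------------------
  classes <- c("mitochondrion", "granule")
  mdir <- file.path(out_dir, "masks")
  dir.create(mdir, showWarnings = FALSE)
  mask_path <- function(id, cl) file.path(mdir, paste0(id, "_", cl, ".mrc"))
  mask_files <- as.vector(outer(mf$tomogram_id, classes, mask_path))

  if (use_ground_truth) {
    if (is.null(labs)) stop("ground-truth shortcut requires labels_path")
    if (!stage_current(out_dir, "segmentation", mf$labels_path)) {
      for (id in mf$tomogram_id) for (cl in classes) {
        m <- class_mask(labs[[id]], cl)
        write_mrc(array(as.integer(m), dim(m)), mask_path(id, cl),
                  voxel_size_A = labs[[id]]$voxel_size_A)
      }
      write_provenance(out_dir, "segmentation",
                       list(mode = "ground_truth"),
                       mf$labels_path, mask_files, seed)
    }
  } else if (!stage_current(out_dir, "segmentation", mf$tomogram_path)) {
    if (is.null(labs)) stop("training requires labels_path in the manifest")
    if (is.null(train_ids))
      train_ids <- mf$tomogram_id[!duplicated(mf$condition)]
    models <- list()
    for (cl in classes) {
      cfg <- seg_configs[[cl]]
      cfg$seed <- stable_seed(seed, cl, "train")
      anns <- lapply(train_ids, function(id)
        annotation_for_class(
          sparsify_labels(labs[[id]], annotation_fraction,
                          seed = stable_seed(seed, id, "annotate"),
                          prefer_class = annotation_prefer_class), cl))
      hmask <- Map(function(a, id)
        make_training_mask(a, dim(labs[[id]]$labels)), anns, train_ids)
      tv <- tomos[train_ids]
      m1 <- seg_train(tv, hmask, cfg)
      # pseudo-label every tomogram (slice mode: full machine-labeled
      # slices, no core-erosion bias), retrain from scratch
      pmask_all <- lapply(mf$tomogram_id, function(id)
        generate_pseudo_labels(predict(m1, tomos[[id]]), cfg,
                               mode = "slice"))
      hm_all <- stats::setNames(vector("list", nrow(mf)), mf$tomogram_id)
      for (k in seq_along(train_ids)) hm_all[[train_ids[k]]] <- hmask[[k]]
      m2 <- train_stage2(cfg, tomos, hm_all, pmask_all)
      models[[cl]] <- m2
      for (id in mf$tomogram_id) {
        pm <- predict(m2, tomos[[id]])
        m <- binarize(pm, cfg$binarize_threshold)
        write_mrc(array(as.integer(m), dim(m)), mask_path(id, cl),
                  voxel_size_A = tomos[[id]]$voxel_size_A)
      }
    }
    write_provenance(out_dir, "segmentation",
                     list(mode = "two_stage",
                          annotation_fraction = annotation_fraction,
                          train_ids = train_ids,
                          configs = lapply(seg_configs, unclass)),
                     c(mf$tomogram_path, mf$labels_path), mask_files, seed)
  }

  # ---- quantify ------------------------------------------------------
  meas_file <- file.path(out_dir, "measurements.csv")
  if (!stage_current(out_dir, "quantify", mask_files)) {
    meas <- do.call(rbind, lapply(seq_len(nrow(mf)), function(i) {
      id <- mf$tomogram_id[i]
      mm <- read_mrc(mask_path(id, "mitochondrion"))
      gm <- read_mrc(mask_path(id, "granule"))
      q <- quantify_tomogram(mm$voxels != 0, gm$voxels != 0,
                             meta = list(voxel_size_A = mm$voxel_size_A,
                                         binning = 1L, tomogram_id = id),
                             config = quant)
      measurements_table(q, mf$condition[i], id)
    }))
    utils::write.csv(meas, meas_file, row.names = FALSE)
    write_provenance(out_dir, "quantify", unclass(quant), mask_files,
                     meas_file, seed)
  }
  meas <- utils::read.csv(meas_file, stringsAsFactors = FALSE)

  # ---- statistics ----------------------------------------------------
  stats_file <- file.path(out_dir, "stats.csv")
  results <- run_group_comparisons(meas, family = family, control = control,
                                   adjustment = adjustment,
                                   on_degenerate = "mark")
  utils::write.csv(comparison_table(results), stats_file, row.names = FALSE)
  jsonlite::write_json(
    lapply(results, function(x) {
      if (inherits(x, "group_comparison_degenerate"))
        list(measure = x$measure, degenerate = x$reason)
      else list(
        measure = x$measure, H = x$H, df = x$df, p_omnibus = x$p_omnibus,
        pairwise = x$pairwise, groups = x$group_summary,
        adjustment = x$adjustment)
    }),
    file.path(out_dir, "stats.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA, dataframe = "rows")
  write_provenance(out_dir, "stats",
                   list(family = family, control = control,
                        adjustment = adjustment),
                   meas_file, stats_file, seed)

  list(measurements = meas, results = results, out_dir = out_dir,
       measurements_file = meas_file, stats_file = stats_file)
}
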