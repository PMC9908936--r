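#' Quantification configuration
#'
#' Controls connected-component labeling and the post-segmentation filters:
#' retained volume ranges per class, and the granule-in-mitochondrion
#' retention rule. Ranges bracket roughly 10-120 nm granule diameters by
#' default and are always configurable, never hard-coded downstream.
#'
#' @param connectivity 6, 18, or 26 (3D neighbourhood).
#' @param mito_volume_range_nm3 (min, max) retained mitochondrion volume.
#' @param granule_volume_range_nm3 (min, max) retained granule volume.
#' @param containment_rule `"centroid"` (granule centroid voxel inside a
#'   mitochondrion; robust to one-voxel boundary bleed) or
#'   `"overlap_fraction"`.
#' @param min_overlap_fraction minimum granule-voxel fraction inside the
#'   parent for the overlap rule, in (0, 1].
#' @return An object of class `quant_config`.
#' @export
quant_config <- function(connectivity = 26L,
                         mito_volume_range_nm3 = c(1e5, Inf),
                         granule_volume_range_nm3 = c(1e3, 1e6),
                         containment_rule = c("centroid", "overlap_fraction"),
                         min_overlap_fraction = 0.5) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18, or 26")
  containment_rule <- match.arg(containment_rule)
  for (r in list(mito_volume_range_nm3, granule_volume_range_nm3))
    if (length(r) != 2L || !(r[1] < r[2]))
      stop("volume ranges must be (min, max) with min < max")
  if (!(min_overlap_fraction > 0 && min_overlap_fraction <= 1))
    stop("min_overlap_fraction must be in (0, 1]")
  structure(list(connectivity = connectivity,
                 mito_volume_range_nm3 = mito_volume_range_nm3,
                 granule_volume_range_nm3 = granule_volume_range_nm3,
                 containment_rule = containment_rule,
                 min_overlap_fraction = min_overlap_fraction),
            class = "quant_config")
}

#' Physical voxel volume
#'
#' @param voxel_size_A voxel edge at the current working scale, Angstrom.
#' @param binning_applied_here any further integer binning applied after
#'   that scale.
#' @return voxel volume in nm^3:
#'   `(voxel_size_A * binning_applied_here / 10)^3`.
#' @export
voxel_volume_nm3 <- function(voxel_size_A, binning_applied_here = 1L) {
  if (voxel_size_A <= 0 || binning_applied_here <= 0)
    stop("inputs must be positive")
  (voxel_size_A * binning_applied_here / 10)^3
}

#' 3D connected components
#'
#' Labels maximal connected foreground sets under the chosen neighbourhood.
#' Components are numbered deterministically in the scan order (z fastest,
#' then y, then x) of their minimum-index voxel. Centroids and bounding
#' boxes are reported as 0-based (z, y, x) voxel coordinates.
#'
#' @param mask binary 3D array (logical or 0/1).
#' @param connectivity 6, 18, or 26.
#' @param voxel_size_A voxel edge in Angstrom (for physical volumes).
#' @param binning any further binning applied at measurement time.
#' @param class component class recorded in the output
#'   (`"mitochondrion"` or `"granule"`).
#' @return A data frame of component records (id, class, voxel_count,
#'   volume_nm3, centroid_z/y/x, bbox columns) with the labeled array in
#'   `attr(, "label_array")`.
#' @export
connected_components <- function(mask, connectivity = 26L, voxel_size_A = 10,
                                 binning = 1L,
                                 class = c("mitochondrion", "granule")) {
  class <- match.arg(class)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18, or 26")
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array")
  vals <- unique(as.vector(mask))
  if (is.logical(mask)) {
    m <- array(as.integer(mask), dim(mask))
  } else {
    if (!all(vals %in% c(0, 1)))
      stop("mask must be binary (0/1 or logical)")
    m <- array(as.integer(mask), dim(mask))
  }
  lab <- cc_label3d(m, connectivity)
  vv <- voxel_volume_nm3(voxel_size_A, binning)
  idx <- which(lab > 0L)
  if (length(idx) == 0L) {
    out <- data.frame(id = integer(), class = character(),
                      voxel_count = integer(), volume_nm3 = numeric(),
                      centroid_z = numeric(), centroid_y = numeric(),
                      centroid_x = numeric(), bbox_z0 = integer(),
                      bbox_z1 = integer(), bbox_y0 = integer(),
                      bbox_y1 = integer(), bbox_x0 = integer(),
                      bbox_x1 = integer())
    attr(out, "label_array") <- lab
    attr(out, "voxel_volume_nm3") <- vv
    return(out)
  }
  lv <- lab[idx]
  coords <- arrayInd(idx, dim(lab))
  sp <- split(seq_along(lv), lv)
  ids <- as.integer(names(sp))
  rec <- lapply(seq_along(sp), function(k) {
    rows <- sp[[k]]
    cz <- coords[rows, 1]; cy <- coords[rows, 2]; cx <- coords[rows, 3]
    data.frame(id = ids[k], class = class, voxel_count = length(rows),
               volume_nm3 = length(rows) * vv,
               centroid_z = mean(cz) - 1, centroid_y = mean(cy) - 1,
               centroid_x = mean(cx) - 1,
               bbox_z0 = min(cz) - 1L, bbox_z1 = max(cz) - 1L,
               bbox_y0 = min(cy) - 1L, bbox_y1 = max(cy) - 1L,
               bbox_x0 = min(cx) - 1L, bbox_x1 = max(cx) - 1L)
  })
  out <- do.call(rbind, rec)
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "label_array") <- lab
  attr(out, "voxel_volume_nm3") <- vv
  out
}

#' Filter components by physical volume
#'
#' Retains components whose `volume_nm3` lies in `[min, max]`; order is
#' preserved, and the labeled array attribute is updated so dropped
#' components are zeroed.
#'
#' @param components a [connected_components()] data frame.
#' @param range_nm3 (min, max) in nm^3.
#' @return Filtered component data frame.
#' @export
filter_components_by_volume <- function(components, range_nm3) {
  if (length(range_nm3) != 2L || !(range_nm3[1] < range_nm3[2]))
    stop("range_nm3 must be (min, max) with min < max")
  keep <- components$volume_nm3 >= range_nm3[1] &
    components$volume_nm3 <= range_nm3[2]
  out <- components[keep, , drop = FALSE]
  rownames(out) <- NULL
  lab <- attr(components, "label_array")
  if (!is.null(lab)) {
    lab[!(lab %in% out$id)] <- 0L
    attr(out, "label_array") <- lab
  }
  attr(out, "voxel_volume_nm3") <- attr(components, "voxel_volume_nm3")
  out
}

#' Assign granules to their host mitochondria
#'
#' Centroid rule: the parent is the mitochondrion component whose mask
#' contains the granule's centroid voxel (rounded to the nearest voxel);
#' unassigned otherwise. Overlap rule: the parent is the mitochondrion with
#' the largest voxel overlap, assigned iff
#' `overlap / granule_size >= min_overlap_fraction`. Unassigned granules
#' are discarded from downstream statistics.
#'
#' @param granule_comps [connected_components()] output for granules (its
#'   `label_array` attribute is required).
#' @param mito_comps [connected_components()] output for mitochondria.
#' @param mito_label_volume labeled mitochondrion array; defaults to
#'   `attr(mito_comps, "label_array")`.
#' @param config a [quant_config()].
#' @return Data frame (granule_id, parent_mito_id, containment_fraction);
#'   `parent_mito_id` is NA for unassigned granules.
#' @export
assign_granules <- function(granule_comps, mito_comps,
                            mito_label_volume = attr(mito_comps,
                                                     "label_array"),
                            config = quant_config()) {
  glab <- attr(granule_comps, "label_array")
  if (is.null(glab) || is.null(mito_label_volume))
    stop("labeled arrays are required for assignment")
  if (!identical(dim(glab), dim(mito_label_volume)))
    stop("granule and mitochondrion volumes have different shapes")
  n <- nrow(granule_comps)
  parent <- rep(NA_integer_, n)
  frac <- numeric(n)
  if (n == 0)
    return(data.frame(granule_id = integer(), parent_mito_id = integer(),
                      containment_fraction = numeric()))
  gidx_all <- which(glab > 0L)
  sp <- split(gidx_all, glab[gidx_all])
  for (k in seq_len(n)) {
    gid <- granule_comps$id[k]
    vox <- sp[[as.character(gid)]]
    ml <- mito_label_volume[vox]
    tab <- table(ml[ml > 0L])
    best <- if (length(tab)) as.integer(names(tab)[which.max(tab)]) else
      NA_integer_
    best_frac <- if (length(tab)) max(tab) / length(vox) else 0
    if (config$containment_rule == "centroid") {
      cz <- as.integer(round(granule_comps$centroid_z[k])) + 1L
      cy <- as.integer(round(granule_comps$centroid_y[k])) + 1L
      cx <- as.integer(round(granule_comps$centroid_x[k])) + 1L
      hit <- mito_label_volume[cz, cy, cx]
      if (hit > 0L) {
        parent[k] <- as.integer(hit)
        frac[k] <- if (!is.na(best) && best == hit)
          best_frac else sum(ml == hit) / length(vox)
      } else frac[k] <- best_frac
    } else {
      if (!is.na(best) && best_frac >= config$min_overlap_fraction) {
        parent[k] <- best
        frac[k] <- best_frac
      } else frac[k] <- best_frac
    }
  }
  data.frame(granule_id = granule_comps$id, parent_mito_id = parent,
             containment_fraction = frac)
}

#' Per-mitochondrion summaries
#'
#' Every retained mitochondrion appears, including those with zero assigned
#' granules. Density is granules per nm^3 of mitochondrial volume.
#'
#' @param mito_comps retained mitochondrion components.
#' @param assignments [assign_granules()] output.
#' @param granule_comps retained granule components.
#' @return Data frame (mito_id, volume_nm3, granule_count,
#'   granule_density_per_nm3) with assigned granule volumes in the
#'   list-column `granule_volumes_nm3`.
#' @export
summarize_mitochondria <- function(mito_comps, assignments, granule_comps) {
  ass <- assignments[!is.na(assignments$parent_mito_id), , drop = FALSE]
  if (nrow(ass)) {
    if (!all(ass$parent_mito_id %in% mito_comps$id))
      stop("dangling assignment: parent mitochondrion not in components")
    if (!all(ass$granule_id %in% granule_comps$id))
      stop("dangling assignment: granule not in components")
  }
  gv <- stats::setNames(granule_comps$volume_nm3, granule_comps$id)
  out <- data.frame(
    mito_id = mito_comps$id,
    volume_nm3 = mito_comps$volume_nm3,
    granule_count = vapply(mito_comps$id, function(id)
      sum(ass$parent_mito_id == id), 0L))
  out$granule_density_per_nm3 <- out$granule_count / out$volume_nm3
  out$granule_volumes_nm3 <- I(lapply(mito_comps$id, function(id)
    unname(gv[as.character(ass$granule_id[ass$parent_mito_id == id])])))
  out
}

#' Quantify one tomogram from binary masks
#'
#' Composition of the measurement chain: connected components per class,
#' volume-range filtering, granule-in-mitochondrion retention, and
#' per-mitochondrion summaries, with physical scaling from the volume
#' metadata.
#'
#' @param mito_mask,granule_mask binary 3D arrays of identical shape.
#' @param meta list with `voxel_size_A` (required), `binning` (default 1),
#'   `tomogram_id` (optional).
#' @param config a [quant_config()].
#' @return An object of class `tomogram_quant`: `mitochondria` and
#'   `granules` (retained components), `assignments`, `summaries`, plus the
#'   config and meta used.
#' @export
quantify_tomogram <- function(mito_mask, granule_mask, meta,
                              config = quant_config()) {
  if (!identical(dim(mito_mask), dim(granule_mask)))
    stop("mask shapes differ")
  if (is.null(meta$voxel_size_A)) stop("meta$voxel_size_A is required")
  binning <- if (is.null(meta$binning)) 1L else meta$binning
  mito <- connected_components(mito_mask, config$connectivity,
                               meta$voxel_size_A, binning, "mitochondrion")
  gran <- connected_components(granule_mask, config$connectivity,
                               meta$voxel_size_A, binning, "granule")
  mito <- filter_components_by_volume(mito, config$mito_volume_range_nm3)
  gran <- filter_components_by_volume(gran, config$granule_volume_range_nm3)
  ass <- assign_granules(gran, mito, config = config)
  keep <- !is.na(ass$parent_mito_id)
  gran_kept <- gran[gran$id %in% ass$granule_id[keep], , drop = FALSE]
  summ <- summarize_mitochondria(mito, ass, gran)
  structure(list(mitochondria = mito, granules = gran_kept,
                 assignments = ass, summaries = summ,
                 config = config, meta = meta),
            class = "tomogram_quant")
}

#' Long-format measurement rows for the statistics stage
#'
#' Emits one row per assigned granule (`granule_volume_nm3`) and one row per
#' retained mitochondrion (`granule_density_per_nm3`), the two units of
#' observation used for the group comparisons.
#'
#' @param quant a [quantify_tomogram()] result.
#' @param condition condition label.
#' @param tomogram_id tomogram identifier.
#' @return Data frame (condition, tomogram_id, unit_id, measure, value).
#' @export
measurements_table <- function(quant, condition,
                               tomogram_id = quant$meta$tomogram_id) {
  stopifnot(inherits(quant, "tomogram_quant"))
  rows <- list()
  g <- quant$granules
  ass <- quant$assignments
  assigned <- ass$granule_id[!is.na(ass$parent_mito_id)]
  g <- g[g$id %in% assigned, , drop = FALSE]
  if (nrow(g))
    rows[[1]] <- data.frame(
      condition = condition, tomogram_id = tomogram_id,
      unit_id = paste0("granule_", g$id),
      measure = "granule_volume_nm3", value = g$volume_nm3)
  s <- quant$summaries
  if (nrow(s))
    rows[[length(rows) + 1L]] <- data.frame(
      condition = condition, tomogram_id = tomogram_id,
      unit_id = paste0("mito_", s$mito_id),
      measure = "granule_density_per_nm3",
      value = s$granule_density_per_nm3)
  if (!length(rows))
    return(data.frame(condition = character(), tomogram_id = character(),
                      unit_id = character(), measure = character(),
                      value = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
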