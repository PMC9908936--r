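#' Simulation parameters for synthetic tomograms
#'
#' Describes a neurite-like scene: tubular double-membrane mitochondria
#' (capsules: cylinders with hemispherical caps) with internal cristae
#' lamellae and dense matrix granules, rendered density-positive (denser =
#' brighter), then degraded by anisotropic z blurring (a cheap stand-in for
#' missing-wedge resolution loss) and additive Gaussian noise.
#'
#' Default scale is the post-bin-4 working scale of a 3.47 A/pixel
#' acquisition (13.88 A/voxel); generation at the raw scale is available by
#' setting `voxel_size_A = 3.47` and scaling the shape up.
#'
#' Granule volumes are drawn from a lognormal law (long-tailed, strictly
#' positive; the median is `granule_log_median_nm3`) and each granule is
#' rendered as the `round(V / voxel_volume)` voxels nearest its centre, so
#' the voxelized volume matches the drawn volume within one voxel-volume.
#' Granule counts per mitochondrion follow a Poisson process with rate
#' `granule_rate_per_nm3` over the matrix (interior) volume, making expected
#' counts proportional to mitochondrial volume.
#'
#' @param shape integer triple (nz, ny, nx) voxels.
#' @param voxel_size_A Angstrom per voxel edge (isotropic).
#' @param n_mitochondria number of mitochondria to pack (>= 0).
#' @param mito_radius_nm range (min, max) of tube radius, nm.
#' @param mito_length_nm range (min, max) of tube axis length, nm.
#' @param membrane_thickness_nm thickness of each membrane of the
#'   double-membrane pair, nm.
#' @param membrane_gap_nm gap between outer and inner membrane, nm.
#' @param crista_density cristae lamellae per 100 nm of mitochondrion length.
#' @param granule_rate_per_nm3 expected granules per nm^3 of matrix volume.
#' @param granule_log_median_nm3 median of the lognormal granule-volume law,
#'   nm^3.
#' @param granule_log_sigma sdlog of the lognormal granule-volume law.
#' @param noise_sd additive Gaussian noise, relative to membrane contrast
#'   (membranes render at 1.0 above background).
#' @param z_blur_sigma_vox Gaussian blur sigma along z, voxels.
#' @param density_sign +1 when denser material has higher voxel values.
#' @param seed RNG seed; identical seeds give bit-identical scenes.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(shape = c(64L, 192L, 192L),
                              voxel_size_A = 13.88,
                              n_mitochondria = 2L,
                              mito_radius_nm = c(35, 45),
                              mito_length_nm = c(110, 160),
                              membrane_thickness_nm = 5,
                              membrane_gap_nm = 7,
                              crista_density = 2,
                              granule_rate_per_nm3 = 2e-5,
                              granule_log_median_nm3 = 5000,
                              granule_log_sigma = 0.5,
                              noise_sd = 0.2,
                              z_blur_sigma_vox = 1,
                              density_sign = 1L,
                              seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 8L))
    stop("shape must be three integers (nz, ny, nx), each >= 8")
  geo <- c(voxel_size_A, mito_radius_nm, mito_length_nm,
           membrane_thickness_nm, membrane_gap_nm, crista_density)
  if (any(!is.finite(geo)) || any(geo <= 0))
    stop("all geometric parameters must be strictly positive")
  if (n_mitochondria < 0) stop("n_mitochondria must be >= 0")
  if (granule_rate_per_nm3 < 0 || granule_log_median_nm3 <= 0 ||
      granule_log_sigma <= 0)
    stop("granule law parameters must be positive")
  if (noise_sd < 0 || z_blur_sigma_vox < 0)
    stop("noise_sd and z_blur_sigma_vox must be >= 0")
  if (!density_sign %in% c(-1L, 1L)) stop("density_sign must be +1 or -1")
  vox_nm <- voxel_size_A / 10
  if (n_mitochondria > 0 &&
      any(shape * vox_nm < 2 * (mito_radius_nm[1] + 2 * vox_nm)))
    stop("shape too small to fit one mitochondrion of the minimum radius")
  structure(list(
    shape = shape, voxel_size_A = voxel_size_A,
    n_mitochondria = as.integer(n_mitochondria),
    mito_radius_nm = mito_radius_nm, mito_length_nm = mito_length_nm,
    membrane_thickness_nm = membrane_thickness_nm,
    membrane_gap_nm = membrane_gap_nm, crista_density = crista_density,
    granule_rate_per_nm3 = granule_rate_per_nm3,
    granule_log_median_nm3 = granule_log_median_nm3,
    granule_log_sigma = granule_log_sigma,
    noise_sd = noise_sd, z_blur_sigma_vox = z_blur_sigma_vox,
    density_sign = as.integer(density_sign), seed = as.integer(seed)),
    class = "simulation_params")
}

# rendered densities relative to membrane contrast
.densities <- list(membrane = 1.0, crista = 1.0, matrix = 0.18,
                   granule = 1.3)

# distance from one point to a segment, both in voxel coordinates
seg_seg_dist <- function(p0, p1, q0, q1) {
  # minimum distance between two segments (Lumelsky's method, simplified)
  u <- p1 - p0; v <- q1 - q0; w <- p0 - q0
  a <- sum(u * u); b <- sum(u * v); cc <- sum(v * v)
  dd <- sum(u * w); e <- sum(v * w)
  den <- a * cc - b * b
  sc <- if (den > 1e-9) max(0, min(1, (b * e - cc * dd) / den)) else 0
  tc <- if (cc > 1e-9) max(0, min(1, (b * sc + e) / cc)) else 0
  # refine sc for the clamped tc
  sc <- if (a > 1e-9) max(0, min(1, (b * tc - dd) / a)) else 0
  tc <- if (cc > 1e-9) max(0, min(1, (b * sc + e) / cc)) else 0
  sqrt(sum((p0 + sc * u - (q0 + tc * v))^2))
}

# gaussian blur along z via FFT (periodic boundaries)
blur_z <- function(vol, sigma_vox) {
  if (sigma_vox <= 0) return(vol)
  d <- dim(vol)
  n <- d[1]
  k <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / n
  tz <- exp(-2 * pi^2 * sigma_vox^2 * k^2)
  ft <- stats::fft(vol) * array(tz, d)
  out <- Re(stats::fft(ft, inverse = TRUE)) / length(vol)
  dim(out) <- d
  out
}

#' Simulate one tomogram with voxel-accurate ground truth
#'
#' Packs `n_mitochondria` non-overlapping capsules into the volume, renders
#' double-membrane shells, cristae lamellae, matrix, and Poisson-placed
#' lognormal granules, then produces the noisy, z-blurred tomogram. Noise and
#' blur touch the tomogram only, never the labels.
#'
#' @param params a [simulation_params()].
#' @return An object of class `simulated_tomogram`: a list with elements
#'   `tomogram` ([tomogram()]), `labels` ([label_volume()]), and `truth`
#'   (per-mitochondrion and per-granule bookkeeping data frames).
#' @export
simulate_tomogram <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  d <- params$shape
  vox_nm <- params$voxel_size_A / 10
  vv <- vox_nm^3
  labels <- array(0L, d)
  density <- array(0, d)

  t_vox <- params$membrane_thickness_nm / vox_nm
  gap_vox <- params$membrane_gap_nm / vox_nm

  # pack capsules; if a partial arrangement blocks the remainder, the whole
  # scene is re-drawn (bounded), keeping placement deterministic under seed
  mitos <- list()
  for (scene in 1:25) {
    mitos <- list()
    scene_ok <- TRUE
    for (i in seq_len(params$n_mitochondria)) {
      placed <- FALSE
      for (attempt in 1:400) {
      R_nm <- stats::runif(1, params$mito_radius_nm[1], params$mito_radius_nm[2])
      L_nm <- stats::runif(1, params$mito_length_nm[1], params$mito_length_nm[2])
      R <- R_nm / vox_nm
      L <- L_nm / vox_nm
      az <- stats::runif(1, 0, 2 * pi)
      uz <- stats::runif(1, -0.15, 0.15)
      u <- c(uz, sqrt(1 - uz^2) * sin(az), sqrt(1 - uz^2) * cos(az))
      # feasible box for the centre so the whole capsule stays in bounds
      margin <- R + 1.5 + abs(u) * L / 2
      if (any(d - margin <= 1 + margin)) next
      ctr <- stats::runif(3, 1 + margin, d - margin)
      p0 <- ctr - u * L / 2
      p1 <- ctr + u * L / 2
      ok <- TRUE
      for (m in mitos)
        if (seg_seg_dist(p0, p1, m$p0, m$p1) < R + m$R + 2) { ok <- FALSE; break }
      if (!ok) next
        mitos[[i]] <- list(p0 = p0, p1 = p1, R = R, L = L,
                           R_nm = R_nm, L_nm = L_nm, u = u)
        placed <- TRUE
        break
      }
      if (!placed) { scene_ok <- FALSE; break }
    }
    if (scene_ok) break
    if (scene == 25)
      stop(errorCondition(
        sprintf("could not pack %d mitochondria into shape (%s)",
                params$n_mitochondria, paste(d, collapse = "x")),
        class = c("mitogranule_packing_error", "error", "condition")))
  }

  truth_m <- vector("list", length(mitos))
  truth_g <- list()
  gran_centers <- matrix(0, nrow = 0, ncol = 3)
  gran_radii <- numeric(0)
  g_id <- 0L

  for (i in seq_along(mitos)) {
    m <- mitos[[i]]
    lo <- pmax(1L, floor(pmin(m$p0, m$p1) - m$R - 1))
    hi <- pmin(d, ceiling(pmax(m$p0, m$p1) + m$R + 1))
    zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
    nb <- c(length(zi), length(yi), length(xi))
    Z <- array(zi, nb)
    Y <- array(rep(yi, each = nb[1]), nb)
    X <- array(rep(xi, each = nb[1] * nb[2]), nb)
    vz <- Z - m$p0[1]; vy <- Y - m$p0[2]; vx <- X - m$p0[3]
    vu <- vz * m$u[1] + vy * m$u[2] + vx * m$u[3]
    v2 <- vz^2 + vy^2 + vx^2
    tc <- pmin(pmax(vu, 0), m$L)
    dist <- sqrt(pmax(v2 - 2 * tc * vu + tc^2, 0))

    R_in_outer <- m$R - gap_vox
    interior_r <- R_in_outer - t_vox
    organelle <- dist <= m$R
    matrixm <- dist <= interior_r
    membrane <- (dist <= m$R & dist > m$R - t_vox) |
      (dist <= R_in_outer & dist > interior_r)

    sub_lab <- labels[zi, yi, xi]
    sub_lab[organelle] <- 1L
    labels[zi, yi, xi] <- sub_lab

    sub_den <- density[zi, yi, xi]
    sub_den[matrixm] <- .densities$matrix
    # cristae: lamellae perpendicular to the axis, within the matrix
    spacing <- 100 / params$crista_density / vox_nm
    phase <- stats::runif(1, 0, spacing)
    pk <- if (phase <= m$L) seq(phase, m$L, by = spacing) else numeric(0)
    pk <- pk[pk > m$R & pk < m$L - m$R]  # keep out of the caps
    for (p in pk) {
      lam <- abs(vu - p) <= t_vox / 2 & matrixm
      sub_den[lam] <- .densities$crista
    }
    sub_den[membrane] <- .densities$membrane
    density[zi, yi, xi] <- sub_den

    interior_vox <- sum(matrixm)
    interior_nm3 <- interior_vox * vv

    # granules: Poisson over matrix volume, lognormal volumes; each granule
    # is rendered as the n nearest still-available matrix voxels around its
    # centre, so containment and the drawn volume are exact by construction
    n_g <- stats::rpois(1, params$granule_rate_per_nm3 * interior_nm3)
    dropped <- 0L
    mat_idx <- which(matrixm)           # bbox-linear indices of matrix voxels
    avail <- rep(TRUE, length(mat_idx)) # not yet claimed by a granule
    mz <- Z[mat_idx]; my <- Y[mat_idx]; mx <- X[mat_idx]
    mdist <- dist[mat_idx]
    for (g in seq_len(n_g)) {
      V <- stats::rlnorm(1, log(params$granule_log_median_nm3),
                         params$granule_log_sigma)
      tries_v <- 0
      while (V > interior_nm3 && tries_v < 100) {
        V <- stats::rlnorm(1, log(params$granule_log_median_nm3),
                           params$granule_log_sigma)
        tries_v <- tries_v + 1
      }
      n_vox_g <- max(1L, as.integer(round(V / vv)))
      r_g <- (3 * n_vox_g / (4 * pi))^(1 / 3)
      elig <- which(avail & mdist <= interior_r - (r_g + 1.5))
      if (length(elig) == 0)  # small organelle: allow wall-flattened granules
        elig <- which(avail & mdist <= interior_r - 0.5 * r_g)
      placed_g <- FALSE
      for (att in 1:50) {
        if (length(elig) == 0 || sum(avail) < n_vox_g) break
        pick <- elig[sample.int(length(elig), 1L)]
        ctr <- c(mz[pick], my[pick], mx[pick]) + stats::runif(3, -0.5, 0.5)
        if (nrow(gran_centers) > 0) {
          dd <- sqrt(colSums((t(gran_centers) - ctr)^2))
          if (any(dd < gran_radii + r_g + 2.5)) next
        }
        d2 <- (mz - ctr[1])^2 + (my - ctr[2])^2 + (mx - ctr[3])^2
        d2[!avail] <- Inf
        ord <- order(d2, seq_along(d2))[seq_len(n_vox_g)]
        coords <- cbind(mz[ord], my[ord], mx[ord])
        labels[coords] <- 2L
        density[coords] <- .densities$granule
        avail[ord] <- FALSE
        gran_centers <- rbind(gran_centers, ctr)
        gran_radii <- c(gran_radii, r_g)
        g_id <- g_id + 1L
        truth_g[[g_id]] <- data.frame(
          granule_id = g_id, mito_id = i, n_vox = n_vox_g,
          volume_nm3 = n_vox_g * vv, volume_nm3_analytic = V,
          center_z = ctr[1] - 1, center_y = ctr[2] - 1, center_x = ctr[3] - 1)
        placed_g <- TRUE
        break
      }
      if (!placed_g) dropped <- dropped + 1L
    }
    truth_m[[i]] <- data.frame(
      mito_id = i, radius_nm = m$R_nm, length_nm = m$L_nm,
      interior_voxels = interior_vox, interior_volume_nm3 = interior_nm3,
      granule_count = sum(vapply(truth_g, function(x) x$mito_id == i, TRUE)),
      granules_dropped = dropped)
  }

  vol <- blur_z(density, params$z_blur_sigma_vox)
  if (params$noise_sd > 0)
    vol <- vol + array(stats::rnorm(length(vol), 0, params$noise_sd), d)
  if (params$density_sign < 0) vol <- -vol

  truth <- list(
    mitochondria = if (length(truth_m)) do.call(rbind, truth_m) else
      data.frame(mito_id = integer(), radius_nm = numeric(),
                 length_nm = numeric(), interior_voxels = integer(),
                 interior_volume_nm3 = numeric(), granule_count = integer(),
                 granules_dropped = integer()),
    granules = if (length(truth_g)) do.call(rbind, truth_g) else
      data.frame(granule_id = integer(), mito_id = integer(),
                 n_vox = integer(), volume_nm3 = numeric(),
                 volume_nm3_analytic = numeric(), center_z = numeric(),
                 center_y = numeric(), center_x = numeric()))

  structure(list(
    tomogram = tomogram(vol, params$voxel_size_A,
                        density_sign = params$density_sign),
    labels = label_volume(labels, params$voxel_size_A),
    truth = truth, params = params),
    class = "simulated_tomogram")
}

#' Condition specification for a synthetic cohort
#'
#' @param name condition label (e.g. "control", "disease", "rescue").
#' @param n_tomograms number of tomograms for this condition.
#' @param params named list of [simulation_params()] overrides (typically
#'   `granule_log_median_nm3` and `granule_rate_per_nm3`).
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(name, n_tomograms = 1L, params = list()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  n_tomograms <- as.integer(n_tomograms)
  if (is.na(n_tomograms) || n_tomograms < 1L)
    stop("n_tomograms must be a positive integer")
  structure(list(name = name, n_tomograms = n_tomograms, params = params),
            class = "condition_spec")
}

#' Simulate a multi-condition cohort
#'
#' Each tomogram gets a deterministic child seed derived from
#' `(seed, condition, index)`, so adding tomograms or conditions never
#' changes the content generated for existing (condition, index) pairs.
#'
#' @param specs list of [condition_spec()]; condition names must be unique.
#' @param seed master seed.
#' @param base_params [simulation_params()] defaults that each spec's
#'   overrides modify.
#' @return An object of class `simulated_cohort`: list with `entries` (each a
#'   list of `condition`, `tomogram_id`, `sim` = [simulate_tomogram()]
#'   output) and a `manifest` data frame.
#' @export
simulate_cohort <- function(specs, seed = 1L,
                            base_params = simulation_params()) {
  if (inherits(specs, "condition_spec")) specs <- list(specs)
  if (length(specs) < 1L) stop("at least one condition_spec is required")
  nms <- vapply(specs, function(s) s$name, "")
  if (anyDuplicated(nms))
    stop("duplicate condition names: ", paste(nms[duplicated(nms)],
                                              collapse = ", "))
  entries <- list()
  rows <- list()
  for (s in specs) {
    p <- base_params
    for (f in names(s$params)) p[[f]] <- s$params[[f]]
    for (j in seq_len(s$n_tomograms)) {
      p$seed <- stable_seed(seed, s$name, j)
      pp <- do.call(simulation_params, unclass(p))
      sim <- simulate_tomogram(pp)
      id <- sprintf("%s_%02d", s$name, j)
      entries[[length(entries) + 1L]] <-
        list(condition = s$name, tomogram_id = id, sim = sim)
      rows[[length(rows) + 1L]] <-
        data.frame(tomogram_id = id, condition = s$name, seed = pp$seed)
    }
  }
  structure(list(entries = entries, manifest = do.call(rbind, rows)),
            class = "simulated_cohort")
}

#' Sparse per-slice annotation of a label volume
#'
#' Emulates the manual-annotation regime: only a small fraction of z slices
#' carry labels. Selects `max(1, round(fraction * nz))` distinct z indices
#' uniformly without replacement and keeps those slices' full 2D labels.
#'
#' @param labels a [label_volume()].
#' @param fraction fraction of z slices to annotate, in (0, 1].
#' @param seed RNG seed for slice selection.
#' @param prefer_class optional class id (e.g. 2 for granules). When set,
#'   slices containing that class are sampled first (topped up with other
#'   slices if there are too few), emulating an annotator who picks slices
#'   where the rare structures are actually visible rather than blind
#'   uniform slices. Default NULL: uniform without replacement.
#' @return An object of class `sparse_annotation`: `annotated_z` (1-based z
#'   indices), `planes` (named list of 2D integer class matrices), `shape`.
#' @export
sparsify_labels <- function(labels, fraction = 0.02, seed = 1L,
                            prefer_class = NULL) {
  stopifnot(inherits(labels, "label_volume"))
  if (length(labels$labels) == 0L) stop("empty label volume")
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  nz <- dim(labels$labels)[1]
  k <- max(1L, as.integer(round(fraction * nz)))
  set.seed(seed)
  if (is.null(prefer_class)) {
    idx <- sort(sample.int(nz, k))
  } else {
    hit <- which(apply(labels$labels == prefer_class, 1, any))
    take <- min(k, length(hit))
    idx <- if (take > 0) hit[sample.int(length(hit), take)] else integer(0)
    if (take < k) {
      rest <- setdiff(seq_len(nz), idx)
      idx <- c(idx, rest[sample.int(length(rest), k - take)])
    }
    idx <- sort(idx)
  }
  planes <- lapply(idx, function(z) labels$labels[z, , ])
  names(planes) <- as.character(idx)
  structure(list(annotated_z = idx, planes = planes,
                 shape = dim(labels$labels), provenance = "human"),
            class = "sparse_annotation")
}

#' Per-class binary view of a sparse annotation
#'
#' @param ann a [sparsify_labels()] result.
#' @param target_class `"mitochondrion"` or `"granule"`.
#' @return An object of class `sparse_slice_annotation` with binary planes
#'   for the target class.
#' @export
annotation_for_class <- function(ann,
                                 target_class = c("mitochondrion",
                                                  "granule")) {
  stopifnot(inherits(ann, "sparse_annotation"))
  target_class <- match.arg(target_class)
  planes <- lapply(ann$planes, function(p) {
    if (target_class == "mitochondrion") (p == 1L | p == 2L) * 1L
    else (p == 2L) * 1L
  })
  structure(list(annotated_z = ann$annotated_z, planes = planes,
                 shape = ann$shape, target_class = target_class,
                 provenance = ann$provenance),
            class = "sparse_slice_annotation")
}

#' Densify a full sparse annotation back to a label array
#'
#' Only meaningful when every slice is annotated (fraction = 1); absent
#' slices densify to NA.
#'
#' @param ann a [sparsify_labels()] result.
#' @return integer 3D array.
#' @export
densify_annotation <- function(ann) {
  stopifnot(inherits(ann, "sparse_annotation"))
  out <- array(NA_integer_, ann$shape)
  for (z in ann$annotated_z) out[z, , ] <- ann$planes[[as.character(z)]]
  out
}
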