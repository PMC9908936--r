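#' Tomogram and label-volume containers
#'
#' A `tomogram` holds a reconstructed 3D scalar field together with the
#' metadata every downstream stage needs: the voxel edge length in Angstrom,
#' the cumulative binning factor relative to acquisition, and the density-sign
#' convention (+1 when denser material has the higher voxel value, -1 for raw
#' cryoET contrast where dense material is dark).
#'
#' Arrays use the package-wide axis convention `dim = c(nz, ny, nx)`, 0-based
#' voxel-center coordinates reported as (z, y, x).
#'
#' @param voxels numeric 3D array, dim (nz, ny, nx).
#' @param voxel_size_A voxel edge length in Angstrom (> 0, isotropic).
#' @param binning cumulative integer binning factor relative to acquisition.
#' @param density_sign +1 or -1; see Description.
#' @return An object of class `tomogram`.
#' @export
tomogram <- function(voxels, voxel_size_A, binning = 1L, density_sign = 1L) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array with dim (nz, ny, nx)")
  if (!is.numeric(voxel_size_A) || length(voxel_size_A) != 1L ||
      !is.finite(voxel_size_A) || voxel_size_A <= 0)
    stop("voxel_size_A must be a single positive number")
  binning <- as.integer(binning)
  if (is.na(binning) || binning < 1L) stop("binning must be an integer >= 1")
  if (!density_sign %in% c(-1L, 1L)) stop("density_sign must be +1 or -1")
  structure(
    list(voxels = voxels, voxel_size_A = voxel_size_A,
         binning = binning, density_sign = as.integer(density_sign)),
    class = "tomogram")
}

#' @param labels integer 3D array with classes 0 (background),
#'   1 (mitochondrion), 2 (granule); 255 (ignore) is reserved for training
#'   masks and is not a valid ground-truth class.
#' @rdname tomogram
#' @export
label_volume <- function(labels, voxel_size_A, binning = 1L) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array with dim (nz, ny, nx)")
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), c(0L, 1L, 2L))
  if (length(bad))
    stop("label classes must be 0/1/2; found: ", paste(bad, collapse = ", "))
  structure(
    list(labels = labels, voxel_size_A = voxel_size_A,
         binning = as.integer(binning)),
    class = "label_volume")
}

#' @export
print.tomogram <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<tomogram> %d x %d x %d (z,y,x), %.3f A/voxel, bin %d, density sign %+d\n",
    d[1], d[2], d[3], x$voxel_size_A, x$binning, x$density_sign))
  cat(sprintf("  intensity range [%.4g, %.4g], mean %.4g\n",
              min(x$voxels), max(x$voxels), mean(x$voxels)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  tb <- table(factor(x$labels, levels = c(0L, 1L, 2L)))
  cat(sprintf("<label_volume> %d x %d x %d (z,y,x), %.3f A/voxel\n",
              d[1], d[2], d[3], x$voxel_size_A))
  cat(sprintf("  background %d | mitochondrion %d | granule %d voxels\n",
              tb[[1]], tb[[2]], tb[[3]]))
  invisible(x)
}

#' Binary class mask from a label volume
#'
#' @param labels a `label_volume` or an integer 3D array of classes.
#' @param target_class `"mitochondrion"` or `"granule"`. The mitochondrion
#'   mask includes granule voxels: granules sit inside the organelle, so the
#'   organelle footprint is the union of classes 1 and 2.
#' @return logical 3D array.
#' @export
class_mask <- function(labels, target_class = c("mitochondrion", "granule")) {
  target_class <- match.arg(target_class)
  arr <- if (inherits(labels, "label_volume")) labels$labels else labels
  if (target_class == "mitochondrion") arr == 1L | arr == 2L else arr == 2L
}

# deterministic 32-bit seed from arbitrary string components
stable_seed <- function(...) {
  s <- paste(vapply(list(...), as.character, ""), collapse = "\r")
  h <- 17
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}
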