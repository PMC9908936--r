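#' Preprocessing configuration
#'
#' Bundles the tomogram post-processing chain applied before annotation and
#' quantification: block-mean binning, a Gaussian low-pass at an absolute
#' spatial frequency, a complementary-Gaussian high-pass that dampens the
#' first few Fourier pixels, and normalization with symmetric sigma clipping.
#'
#' @param bin_factor integer binning factor (>= 1).
#' @param lowpass_cutoff Gaussian low-pass cutoff in 1/Angstrom.
#' @param highpass_pixels scale of the high-pass, in Fourier pixels (1-5).
#' @param clip_sigmas symmetric clip bound after z-scoring, in standard
#'   deviations.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(bin_factor = 4L, lowpass_cutoff = 0.01,
                              highpass_pixels = 3L, clip_sigmas = 3) {
  bin_factor <- as.integer(bin_factor)
  if (is.na(bin_factor) || bin_factor < 1L)
    stop("bin_factor must be an integer >= 1")
  if (lowpass_cutoff <= 0) stop("lowpass_cutoff must be > 0")
  highpass_pixels <- as.integer(highpass_pixels)
  if (is.na(highpass_pixels) || highpass_pixels < 1L || highpass_pixels > 5L)
    stop("highpass_pixels must be an integer in [1, 5]")
  if (clip_sigmas <= 0) stop("clip_sigmas must be > 0")
  structure(list(bin_factor = bin_factor, lowpass_cutoff = lowpass_cutoff,
                 highpass_pixels = highpass_pixels, clip_sigmas = clip_sigmas),
            class = "preprocess_config")
}

#' Block-mean binning
#'
#' Downsamples by averaging non-overlapping `factor^3` blocks. Trailing
#' partial blocks are dropped. Voxel size and the cumulative binning factor
#' are multiplied by `factor`, so their product with the grid extent (the
#' physical field of view covered by whole blocks) is conserved.
#'
#' @param t a [tomogram()].
#' @param factor integer >= 1.
#' @return A binned [tomogram()].
#' @export
bin_volume <- function(t, factor) {
  stopifnot(inherits(t, "tomogram"))
  if (length(factor) != 1L || is.na(factor) || factor != round(factor) ||
      factor < 1)
    stop("factor must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(t)
  d <- dim(t$voxels)
  if (any(d < factor)) stop("each axis must be at least `factor` long")
  dn <- d %/% factor
  v <- t$voxels[seq_len(dn[1] * factor), seq_len(dn[2] * factor),
                seq_len(dn[3] * factor), drop = FALSE]
  dim(v) <- c(factor, dn[1], factor, dn[2], factor, dn[3])
  out <- apply(v, c(2, 4, 6), mean)
  tomogram(out, voxel_size_A = t$voxel_size_A * factor,
           binning = t$binning * factor, density_sign = t$density_sign)
}

# radial spatial-frequency grid in 1/Angstrom for an FFT of dims d
freq_grid_invA <- function(d, voxel_size_A) {
  f1 <- function(n) {
    k <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1))
    k / (n * voxel_size_A)
  }
  fz <- f1(d[1]); fy <- f1(d[2]); fx <- f1(d[3])
  sqrt(outer(outer(fz^2, fy^2, "+"), fx^2, "+"))
}

apply_transfer <- function(t, transfer) {
  v <- t$voxels
  if (!all(is.finite(v))) stop("volume contains non-finite voxels")
  ft <- stats::fft(v) * transfer
  out <- Re(stats::fft(ft, inverse = TRUE)) / length(v)
  dim(out) <- dim(v)
  tomogram(out, t$voxel_size_A, t$binning, t$density_sign)
}

#' Gaussian low-pass filter
#'
#' Multiplies the 3D Fourier transform by `exp(-f^2 / (2 cutoff^2))` where
#' `f` is the radial spatial frequency in 1/Angstrom derived from the voxel
#' size. The DC component is preserved exactly.
#'
#' @param t a [tomogram()].
#' @param cutoff_inv_A Gaussian cutoff in 1/Angstrom (> 0).
#' @return Filtered [tomogram()].
#' @export
lowpass_gauss <- function(t, cutoff_inv_A = 0.01) {
  stopifnot(inherits(t, "tomogram"))
  if (cutoff_inv_A <= 0) stop("cutoff_inv_A must be > 0")
  f <- freq_grid_invA(dim(t$voxels), t$voxel_size_A)
  apply_transfer(t, exp(-f^2 / (2 * cutoff_inv_A^2)))
}

#' Gaussian high-pass (low-order Fourier-pixel dampening)
#'
#' Multiplies Fourier coefficients by `1 - exp(-r^2 / (2 (n_pixels/2)^2))`
#' with `r` the radial distance in Fourier pixels, removing the DC term and
#' dampening the first few Fourier shells while leaving high frequencies
#' essentially untouched.
#'
#' @param t a [tomogram()].
#' @param n_pixels integer in \[1, 5\]: how many low-order Fourier pixels to
#'   dampen.
#' @return Filtered [tomogram()].
#' @export
highpass_dampen <- function(t, n_pixels = 3L) {
  stopifnot(inherits(t, "tomogram"))
  if (length(n_pixels) != 1L || is.na(n_pixels) ||
      n_pixels != round(n_pixels) || n_pixels < 1 || n_pixels > 5)
    stop("n_pixels must be an integer in [1, 5]")
  d <- dim(t$voxels)
  r1 <- function(n) c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1))
  rz <- r1(d[1]); ry <- r1(d[2]); rx <- r1(d[3])
  r <- sqrt(outer(outer(rz^2, ry^2, "+"), rx^2, "+"))
  apply_transfer(t, 1 - exp(-r^2 / (2 * (n_pixels / 2)^2)))
}

#' Normalize and sigma-clip
#'
#' Subtracts the mean, divides by the standard deviation, then clamps to
#' `[-clip_sigmas, +clip_sigmas]`.
#'
#' @param t a [tomogram()].
#' @param clip_sigmas clip bound in standard deviations (> 0).
#' @return Normalized [tomogram()].
#' @export
normalize_clip <- function(t, clip_sigmas = 3) {
  stopifnot(inherits(t, "tomogram"))
  if (clip_sigmas <= 0) stop("clip_sigmas must be > 0")
  v <- t$voxels
  s <- stats::sd(as.vector(v))
  if (!is.finite(s) || s == 0) stop("volume has zero variance")
  v <- (v - mean(v)) / s
  v[v > clip_sigmas] <- clip_sigmas
  v[v < -clip_sigmas] <- -clip_sigmas
  tomogram(v, t$voxel_size_A, t$binning, t$density_sign)
}

#' Reverse contrast
#'
#' Negates voxel values and flips the density-sign flag. Applying it twice
#' is the identity. Raw cryoET tomograms have dense material dark
#' (density_sign -1); segmentation masks are combined with density-positive
#' volumes, so raw data is contrast-reversed first. Synthetic volumes are
#' generated density-positive and need no reversal.
#'
#' @param t a [tomogram()].
#' @return The reversed [tomogram()].
#' @export
reverse_contrast <- function(t) {
  stopifnot(inherits(t, "tomogram"))
  tomogram(-t$voxels, t$voxel_size_A, t$binning, -t$density_sign)
}

#' Run the full preprocessing chain
#'
#' Applies bin -> low-pass -> high-pass -> normalize/clip with the settings
#' in a [preprocess_config()], optionally reversing contrast first when the
#' input is density-negative.
#'
#' @param t a [tomogram()].
#' @param config a [preprocess_config()].
#' @param ensure_density_positive reverse contrast first if density_sign
#'   is -1 (default TRUE).
#' @return Preprocessed [tomogram()].
#' @export
preprocess_tomogram <- function(t, config = preprocess_config(),
                                ensure_density_positive = TRUE) {
  stopifnot(inherits(t, "tomogram"), inherits(config, "preprocess_config"))
  if (ensure_density_positive && t$density_sign < 0) t <- reverse_contrast(t)
  t <- bin_volume(t, config$bin_factor)
  t <- lowpass_gauss(t, config$lowpass_cutoff)
  t <- highpass_dampen(t, config$highpass_pixels)
  normalize_clip(t, config$clip_sigmas)
}
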