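#' Read an MRC2014 volume
#'
#' Parses the 1024-byte MRC2014 header, validates the `MAP ` magic, and reads
#' the voxel grid. Data axes in the file are (x fastest, y, z slowest); the
#' returned array is permuted to the package convention dim (nz, ny, nx).
#' Voxel size is taken from the cell dimensions divided by the grid size.
#'
#' @param path path to an MRC2014 file.
#' @param as `"tomogram"` (numeric voxels) or `"labels"` (integer classes).
#' @return A [tomogram()] or [label_volume()].
#' @export
read_mrc <- function(path, as = c("tomogram", "labels")) {
  as <- match.arg(as)
  if (!file.exists(path)) stop("no such file: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024)
    stop("corrupt MRC file (shorter than the 1024-byte header): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024)
  hdr_int <- readBin(hdr_raw, "integer", n = 256, size = 4, endian = "little")
  hdr_dbl <- readBin(hdr_raw, "numeric", n = 256, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
  mode <- hdr_int[4]
  mx <- hdr_int[8]; my <- hdr_int[9]; mz <- hdr_int[10]
  cella <- hdr_dbl[11:13]
  nsymbt <- hdr_int[24]
  map_magic <- rawToChar(hdr_raw[209:212])
  if (!identical(substr(map_magic, 1, 3), "MAP"))
    stop("malformed MRC header (missing MAP magic): ", path)
  if (any(c(nx, ny, nz) <= 0) || any(c(mx, my, mz) <= 0))
    stop("malformed MRC header (non-positive grid size): ", path)
  if (any(cella <= 0))
    stop("malformed MRC header (zero cell dimensions): ", path)
  bytes <- switch(as.character(mode), "0" = 1L, "1" = 2L, "2" = 4L, "6" = 2L,
                  stop("unsupported MRC mode ", mode, " in ", path))
  n <- as.numeric(nx) * ny * nz
  need <- 1024 + nsymbt + n * bytes
  if (sz < need)
    stop("corrupt MRC file (truncated data block): ", path)
  seek(con, 1024 + nsymbt)
  vals <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n = n, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "6" = readBin(con, "integer", n = n, size = 2, signed = FALSE,
                  endian = "little"))
  vol <- aperm(array(vals, dim = c(nx, ny, nz)), c(3, 2, 1))
  vs <- cella[1] / mx
  extra <- readBin_extra(path)
  if (as == "labels") {
    label_volume(vol, voxel_size_A = vs, binning = extra$binning)
  } else {
    tomogram(vol, voxel_size_A = vs, binning = extra$binning,
             density_sign = extra$density_sign)
  }
}

# binning and density_sign survive round trips via the first header label
readBin_extra <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", n = 1024)
  lab <- rawToChar(raw[225:304])
  m <- regmatches(lab, regexec("bin=([0-9]+) sign=([+-]?1)", lab))[[1]]
  if (length(m) == 3)
    list(binning = as.integer(m[2]), density_sign = as.integer(m[3]))
  else list(binning = 1L, density_sign = 1L)
}

#' Write an MRC2014 volume
#'
#' Tomograms and probability maps are written as mode 2 (float32); label
#' volumes and training masks as mode 1 (int16). Cell dimensions encode the
#' voxel size; dmin/dmax/dmean/rms statistics are populated.
#'
#' @param x a [tomogram()], [label_volume()], or 3D array.
#' @param path output path.
#' @param voxel_size_A required when `x` is a bare array.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(x, path, voxel_size_A = NULL) {
  if (inherits(x, "tomogram")) {
    vol <- x$voxels; vs <- x$voxel_size_A; mode <- 2L
    binning <- x$binning; dsign <- x$density_sign
  } else if (inherits(x, "label_volume")) {
    vol <- x$labels; vs <- x$voxel_size_A; mode <- 1L
    binning <- x$binning; dsign <- 1L
  } else {
    if (is.null(voxel_size_A)) stop("voxel_size_A required for a bare array")
    vol <- x; vs <- voxel_size_A
    mode <- if (is.integer(vol)) 1L else 2L
    binning <- 1L; dsign <- 1L
  }
  if (!all(is.finite(vol))) stop("refusing to write non-finite voxel values")
  d <- dim(vol)  # (nz, ny, nx)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  perm <- aperm(vol, c(3, 2, 1))  # file order: x fastest

  hi <- integer(256)
  hd <- numeric(256)
  hi[1:3] <- c(nx, ny, nz)
  hi[4] <- mode
  hi[8:10] <- c(nx, ny, nz)                # mx,my,mz
  hd[11:13] <- vs * c(nx, ny, nz)          # cella
  hd[14:16] <- 90                          # cellb
  hi[17:19] <- c(1L, 2L, 3L)               # mapc,mapr,maps
  hd[20:22] <- c(min(vol), max(vol), mean(vol))
  hi[24] <- 0L                             # nsymbt
  hd[55] <- stats::sd(as.vector(vol))      # rms
  hi[56] <- 1L                             # nlabl
  lab <- sprintf("mitogranule bin=%d sign=%+d", binning, dsign)
  lab <- substr(paste0(lab, strrep(" ", 80)), 1, 80)

  con <- file(path, "wb")
  on.exit(close(con))
  float_words <- c(11:16, 20:22, 50:52, 55)
  for (i in 1:256) {
    if (i == 53) {
      writeBin(charToRaw("MAP "), con)
    } else if (i == 54) {
      writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian machst
    } else if (i %in% 57:76) {
      k <- i - 56
      writeBin(charToRaw(substr(lab, (k - 1) * 4 + 1, k * 4)), con)
    } else if (i %in% float_words) {
      writeBin(hd[i], con, size = 4, endian = "little")
    } else {
      writeBin(hi[i], con, size = 4, endian = "little")
    }
  }
  if (mode == 2L) {
    writeBin(as.numeric(perm), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(perm), con, size = 2, endian = "little")
  }
  invisible(path)
}
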