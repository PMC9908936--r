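# Shared fixtures: small simulation scenes sized so the whole suite stays
# fast, and a brute-force flood-fill oracle for connected components.

# a small neurite scene: two tubular mitochondria in a 48 x 96 x 96 box at
# the post-bin-4 working scale
small_params <- function(seed = 1L, ...) {
  args <- list(
    shape = c(48L, 96L, 96L), voxel_size_A = 13.88, n_mitochondria = 2L,
    mito_radius_nm = c(22, 26), mito_length_nm = c(55, 75),
    granule_rate_per_nm3 = 1e-4, granule_log_median_nm3 = 1200,
    granule_log_sigma = 0.4, noise_sd = 0.1, z_blur_sigma_vox = 1,
    seed = seed)
  ov <- list(...)
  for (nm in names(ov)) args[[nm]] <- ov[[nm]]
  do.call(simulation_params, args)
}

# independent flood-fill connected components (pure R, queue-based),
# deliberately separate from the package's labeling code
flood_fill_cc <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  s <- abs(offs$dz) + abs(offs$dy) + abs(offs$dx)
  offs <- offs[s > 0 & s <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), ]
  lab <- array(0L, d)
  nxt <- 0L
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
    if (mask[z, y, x] == 0 || lab[z, y, x] != 0) next
    nxt <- nxt + 1L
    queue <- list(c(z, y, x))
    lab[z, y, x] <- nxt
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        nb <- cur + c(offs$dz[k], offs$dy[k], offs$dx[k])
        if (any(nb < 1) || any(nb > d)) next
        if (mask[nb[1], nb[2], nb[3]] != 0 &&
            lab[nb[1], nb[2], nb[3]] == 0) {
          lab[nb[1], nb[2], nb[3]] <- nxt
          queue[[length(queue) + 1L]] <- nb
        }
      }
    }
  }
  lab
}

# canonical membership partition (order-independent comparison of labelings)
cc_partition <- function(lab) {
  idx <- which(lab > 0)
  unname(lapply(split(idx, lab[idx]), sort))
}
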