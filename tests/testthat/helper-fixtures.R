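# Shared fixtures: small grids and noiseless specs keep the suite fast.

grid2 <- function() grid_spec()                  # 91 x 109 x 91, 2 mm
grid4 <- function() grid_spec(voxel_size = 4)    # 46 x 55 x 46, 4 mm
grid8 <- function() grid_spec(c(-88, -120, -72), c(88, 96, 104), 8)

# A small asymmetric test volume with a smooth blob, on an arbitrary grid.
blob_volume <- function(grid = grid8(), centre = c(10, -20, 14),
                        width = 25) {
  g <- as_grid(grid)
  xw <- datspect:::grid_world_coords(g)
  r2 <- (xw[, 1] - centre[1])^2 + (xw[, 2] - centre[2])^2 +
    (xw[, 3] - centre[3])^2
  vol_image(array(exp(-r2 / (2 * width^2)), g$dims), g$affine, "blob")
}

clean_subject_spec <- function(...) {
  args <- list(psf_fwhm_mm = 0, noise = noise_none(),
               spect_t1_offset = list(t = c(0, 0, 0), r = c(0, 0, 0)))
  user <- list(...)
  args[names(user)] <- user
  do.call(subject_spec, args)
}

# Independent one-way ICC oracle via stats::aov (subject as the factor).
icc_oracle_aov <- function(x, y) {
  n <- length(x)
  d <- data.frame(val = c(x, y), subj = factor(rep(seq_len(n), 2)))
  ms <- summary(stats::aov(val ~ subj, data = d))[[1]][["Mean Sq"]]
  msbs <- ms[1]; msws <- ms[2]
  (msbs - msws) / (msbs + (2 - 1) * msws)
}
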