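# Small phantom configurations and constructed fixtures, built in code.

# Quiet config: a compact grid, no noise.
quiet_config <- function(grid = c(12L, 24L, 24L), sigma = 1, gain = 1000,
                         sources = list(), seed = 1L) {
  phantom_config(grid_shape = grid, signal_per_ug = gain, psf_sigma = sigma,
                 noise_additive_sd = 0, noise_multiplicative_cv = 0,
                 rng_seed = seed, sources = sources)
}

# Full-size study conditions: default grid, gain, PSF and noise model.
study_config <- function(seed = 42L) phantom_config(rng_seed = seed)

# A slice made of rectangular intensity tiers: background plus blocks at
# the given levels.  Returns list(slice, tier_masks).
tier_slice <- function(ny = 20, nx = 20, levels = c(5, 50, 500)) {
  sl <- matrix(0, ny, nx)
  masks <- list(background = matrix(TRUE, ny, nx))
  for (i in seq_along(levels)) {
    rows <- (1 + (i - 1) * 4):((i - 1) * 4 + 3)
    m <- matrix(FALSE, ny, nx)
    m[rows, 3:8] <- TRUE
    sl[m] <- levels[i]
    masks$background <- masks$background & !m
    masks[[paste0("tier", i)]] <- m
  }
  list(slice = sl, masks = masks)
}

# Noise-free scan with the three standard fiducials and one graft blob.
graft_scan <- function(iron_ug = 2, noisy = FALSE, seed = 42L) {
  cfg <- if (noisy) study_config(seed) else
    phantom_config(noise_additive_sd = 0, noise_multiplicative_cv = 0,
                   rng_seed = seed)
  fids <- standard_fiducials(cfg$grid_shape)
  cfg$sources <- c(mpiquant:::fiducial_sources(fids),
                   list(iron_source(mpiquant:::default_graft_center(cfg$grid_shape),
                                    iron_ug, "graft")))
  out <- render_scan(cfg)
  out$fiducials <- fids
  out
}
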