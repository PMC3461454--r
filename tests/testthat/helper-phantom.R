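# small, fast phantom used throughout the unit tests: 64 x 64 in-plane,
# 4 slices, annulus radii scaled to fit the reduced field of view
small_phantom <- function(...) {
  args <- list(...)
  defaults <- list(matrix = c(64L, 64L), n_slices = 4L,
                   epi_radius = 14, endo_radius = 9,
                   supersample_factor = 4L, noise_sigma = 2, seed = 1L)
  defaults[names(args)] <- args
  do.call(phantom_config, defaults)
}

small_run <- function(phantom = small_phantom(), ...) {
  run_config(phantom = phantom, ...)
}

# noiseless mono-exponential samples
decay_signal <- function(s0, t1rho, tsl) s0 * exp(-tsl / t1rho)

TSL_SCHEDULE <- c(6, 18, 30, 42, 48)
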