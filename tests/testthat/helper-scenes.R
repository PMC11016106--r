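# Shared fixtures built in code.

small_spec <- function(n = 32, cell = 30, cf = 8) grid_spec(n, n, cell, coarse_factor = cf)

# scene with all four causes present, deterministic
mixed_scene <- function(seed = 11, n = 64, cf = 16,
                        params = scene_params()) {
  simulate_scene(grid_spec(n, n, 30, coarse_factor = cf), params, seed = seed)
}

# independent brute-force eCE oracle: per-pixel loop, no vectorized reuse
brute_force_ece <- function(L, rho, roi = NULL) {
  tot <- 0
  for (i in seq_len(nrow(L))) for (j in seq_len(ncol(L))) {
    if (!is.null(roi) && !roi[i, j]) next
    r <- if (length(rho) == 1) rho else rho[i, j]
    if (!is.na(L[i, j]) && !is.na(r)) tot <- tot + L[i, j] * r
  }
  tot
}
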