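# Shared fixtures: all built in code, deterministic where seeded.

grid14 <- concentration_grid(14)

# noiseless sigmoid on the standard grid
clean_profile <- function(r0 = 0, rmax = 100, ac50 = 0.1, slope = 1,
                          id = "clean", grid = grid14) {
  qhts_profile(id, grid, hill_response(hill_params(r0, rmax, ac50, slope), grid))
}

noisy_profile <- function(r0 = 0, rmax = 100, ac50 = 0.1, slope = 1,
                          sigma = 25, seed = 42, id = "noisy",
                          grid = grid14) {
  set.seed(seed)
  mu <- hill_response(hill_params(r0, rmax, ac50, slope), grid)
  qhts_profile(id, grid, mu + rnorm(length(grid), 0, sigma))
}

flat_profile <- function(level = 0, sigma = 0, seed = 7, id = "flat",
                         grid = grid14) {
  set.seed(seed)
  qhts_profile(id, grid, rep(level, length(grid)) + rnorm(length(grid), 0, sigma))
}

# 13 near-zero points with one high spike at the top concentration: the
# canonical non-robust profile (NLS chases the spike, WNLS does not)
spike_profile <- function(spike = 120, sigma = 5, seed = 5, id = "spike") {
  set.seed(seed)
  r <- rnorm(13, 0, sigma)
  qhts_profile(id, grid14, c(r, spike))
}

negate_profile <- function(p) {
  qhts_profile(p$substance_id, p$conc, -p$resp, p$included)
}
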