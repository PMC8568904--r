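# Small fixtures shared across tests; everything is generated in code.

# minimal two-region connectome with negligible coupling (for isolated-region
# dynamics tests)
tiny_sc <- function() connectome(rbind(c(0, 1e-12), c(1e-12, 0)))

small_sc <- function(n = 10, seed = 3) generate_connectome(synthetic_spec(n, seed = seed))

small_maps <- function(n = 10, seed = 3) generate_spatial_maps(synthetic_spec(n, seed = seed))

# short simulation protocol used throughout the unit tests
short_config <- function(seed = 1, t_total = 120, t_burn = 20, tr = 0.72)
  sim_config(t_total = t_total, t_burn = t_burn, tr = tr, seed = seed)

# deterministic BOLD-like matrix (sinusoids + seeded noise), regions x frames
toy_bold <- function(n_regions = 5, n_frames = 200, seed = 42, tr = 0.72) {
  set.seed(seed)
  t <- seq_len(n_frames)
  B <- t(sapply(seq_len(n_regions), function(i)
    sin(2 * pi * t / (20 + 3 * i)) + 0.5 * rnorm(n_frames)))
  bold_timeseries(B, tr = tr)
}

expect_pmfm_error <- function(expr, class) {
  expect_error(expr, class = class)
}
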