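# Shared fixtures: small, fast simulations used across test files.

default_cfg <- acq_config()

# fine-binned validation config: 2048 bins x 24 ps resolves sub-ns decays
fine_cfg <- acq_config(n_bins = 2048L, bin_width_s = 2.4e-11)

glue_pop <- population_spec(3.7, target_peak = 500, label = 1L)
oil_pop <- population_spec(1.7, target_peak = 500, label = 2L)

small_interface <- function(shape = c(10L, 10L), boundary = 5L, seed = 1L,
                            noise = "poisson") {
  simulate_interface_map(glue_pop, oil_pop, shape = shape,
                         boundary_col = boundary, config = default_cfg,
                         seed = seed, noise = noise)
}

# independent brute-force phasor oracle: plain double loop, no vectorization
brute_force_phasor <- function(counts, config, harmonic = 1) {
  omega <- 2 * pi * harmonic * config$rep_rate_hz
  num_g <- 0
  num_s <- 0
  den <- 0
  for (k in seq_along(counts)) {
    t_k <- (k - 0.5) * config$bin_width_s
    num_g <- num_g + counts[k] * cos(omega * t_k)
    num_s <- num_s + counts[k] * sin(omega * t_k)
    den <- den + counts[k]
  }
  c(g = num_g / den, s = num_s / den)
}

# from-scratch bivariate normal density (solve/det route, distinct from the
# closed-form 2x2 inverse used by the package)
ref_dmvnorm <- function(x, mu, sigma) {
  d <- x - mu
  exp(-0.5 * as.numeric(t(d) %*% solve(sigma) %*% d)) /
    (2 * pi * sqrt(det(sigma)))
}

truth_matrix <- function(map) {
  sh <- map_shape(map)
  matrix(map$truth, nrow = sh[1], ncol = sh[2], byrow = TRUE)
}
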