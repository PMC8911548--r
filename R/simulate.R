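#' Fluorophore population specification
#'
#' Describes one emitting population by its exponential decay components:
#' lifetimes `tau_ns` with amplitude fractions summing to one, the expected
#' peak count of a simulated histogram, and a ground-truth label used when
#' scoring segmentations of simulated maps.
#'
#' @param tau_ns Positive numeric vector of lifetimes in ns (one value for a
#'   mono-exponential decay, several for a multi-exponential mixture).
#' @param fractions Positive amplitude fractions, same length as `tau_ns`,
#'   summing to 1 (within 1e-12). Default: equal fractions.
#' @param target_peak Expected peak count of the noiseless histogram
#'   (positive; default 500, comfortably above the 100-count quality
#'   threshold).
#' @param label Ground-truth cluster identifier (integer, default 1).
#' @return An object of class `population_spec`.
#' @export
#' @examples
#' glue <- population_spec(3.7, label = 1) # rabbit-glue-like binder
#' oil <- population_spec(1.7, label = 2)  # linseed-oil-like binder
population_spec <- function(tau_ns, fractions = NULL, target_peak = 500,
                            label = 1L) {
  if (!is.numeric(tau_ns) || length(tau_ns) == 0 || any(tau_ns <= 0)) {
    stop("All lifetimes must be positive.", call. = FALSE)
  }
  if (is.null(fractions)) {
    fractions <- rep(1 / length(tau_ns), length(tau_ns))
  }
  if (length(fractions) != length(tau_ns) || any(fractions <= 0)) {
    stop("`fractions` must be positive and match `tau_ns` in length.",
         call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-12) {
    stop("`fractions` must sum to 1 (within 1e-12).", call. = FALSE)
  }
  if (!is.numeric(target_peak) || length(target_peak) != 1 || target_peak <= 0) {
    stop("`target_peak` must be a single positive number.", call. = FALSE)
  }
  structure(
    list(tau_ns = as.numeric(tau_ns), fractions = as.numeric(fractions),
         target_peak = as.numeric(target_peak), label = as.integer(label)),
    class = "population_spec"
  )
}

# Expected (noiseless, real-valued) bin intensities lambda_k.
# Under periodic excitation at period T, tails of all previous pulses fold
# into the window: sum_m exp(-(t_k + m T)/tau) = exp(-t_k/tau)/(1 - exp(-T/tau)).
expected_decay <- function(spec, config, wrap = TRUE, irf_sigma_ns = NULL) {
  t <- time_axis(config)
  T_period <- 1 / config$rep_rate_hz
  lam <- rep(0, config$n_bins)
  for (i in seq_along(spec$tau_ns)) {
    tau <- spec$tau_ns[i] * 1e-9
    term <- exp(-t / tau)
    if (wrap) term <- term / (1 - exp(-T_period / tau))
    lam <- lam + spec$fractions[i] * term
  }
  if (!is.null(irf_sigma_ns) && irf_sigma_ns > 0) {
    lam <- convolve_gaussian_irf(lam, config$bin_width_s, irf_sigma_ns * 1e-9)
  }
  lam * (spec$target_peak / max(lam))
}

# Discrete circular convolution with a Gaussian IRF centred at t = 0.
convolve_gaussian_irf <- function(lam, bin_width_s, sigma_s) {
  n <- length(lam)
  k <- seq_len(n) - 1
  # distance on the circle (periodic excitation)
  d <- pmin(k, n - k) * bin_width_s
  kern <- exp(-0.5 * (d / sigma_s)^2)
  kern <- kern / sum(kern)
  Re(stats::fft(stats::fft(lam) * stats::fft(kern), inverse = TRUE)) / n
}

#' Simulate a TCSPC decay histogram
#'
#' Generates one photon-count histogram for a [population_spec()] under
#' periodic excitation. The expected counts in bin k are
#' `lambda_k = A * sum_i f_i * exp(-t_k / tau_i) / (1 - exp(-T / tau_i))`
#' with `T = 1/rep_rate_hz` (the wrap factor accounts for fluorescence left
#' over from earlier pulses; `wrap = FALSE` disables it) and `A` chosen so
#' the largest `lambda_k` equals `target_peak`. With `noise = "poisson"`
#' each bin is an independent Poisson draw with mean `lambda_k`; with
#' `noise = "none"` the expected counts are rounded to the nearest integer.
#' The same seed always reproduces the same histogram.
#'
#' An ideal delta-pulse excitation is assumed by default (`irf_sigma_ns =
#' NULL`); an optional Gaussian instrument response of the given width can be
#' convolved in for robustness studies.
#'
#' @param spec A [population_spec()].
#' @param config An [acq_config()].
#' @param seed Integer seed (ignored for `noise = "none"`).
#' @param noise `"poisson"` (default) or `"none"`.
#' @param wrap Include the periodic-excitation wrap factor (default `TRUE`).
#' @param irf_sigma_ns Optional Gaussian IRF standard deviation in ns.
#' @return Integer vector of length `config$n_bins`.
#' @export
simulate_decay <- function(spec, config, seed = 0L,
                           noise = c("poisson", "none"),
                           wrap = TRUE, irf_sigma_ns = NULL) {
  stopifnot(inherits(spec, "population_spec"), is_acq_config(config))
  noise <- match.arg(noise)
  lam <- expected_decay(spec, config, wrap = wrap, irf_sigma_ns = irf_sigma_ns)
  if (noise == "none") {
    return(as.integer(round(lam)))
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  as.integer(stats::rpois(length(lam), lam))
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

# Deterministic per-pixel seed so maps are reproducible even under partial
# regeneration. Mixing constants keep products within exact double range.
pixel_seed <- function(seed, row, col) {
  (as.numeric(seed %% 2147483647) * 1000003 +
     as.numeric(row) * 10007 + as.numeric(col) * 101) %% 2147483629
}

#' Simulate a two-population interface map
#'
#' Builds a rectangular decay map whose left block (`col < boundary_col`)
#' draws from `pop_a` and whose right block draws from `pop_b` — emulating a
#' measurement scanned across the boundary between two paint mixtures. The
#' ground-truth labels are stored in the `truth` column. Each pixel's
#' histogram uses a seed derived deterministically from `(seed, row, col)`,
#' so the whole map is reproducible.
#'
#' @param pop_a,pop_b [population_spec()]s for the left and right blocks.
#' @param shape `c(n_rows, n_cols)` of the pixel grid.
#' @param boundary_col First column (0-based) belonging to `pop_b`; must lie
#'   strictly inside the grid.
#' @param config An [acq_config()].
#' @param seed Integer master seed.
#' @param noise Passed to [simulate_decay()].
#' @return A [decay_map()] with a `truth` column.
#' @export
#' @examples
#' m <- simulate_interface_map(population_spec(3.7, label = 1),
#'                             population_spec(1.7, label = 2),
#'                             shape = c(6, 8), boundary_col = 4, seed = 1)
#' table(m$truth)
simulate_interface_map <- function(pop_a, pop_b, shape, boundary_col,
                                   config = acq_config(), seed = 0L,
                                   noise = c("poisson", "none")) {
  stopifnot(inherits(pop_a, "population_spec"),
            inherits(pop_b, "population_spec"))
  noise <- match.arg(noise)
  shape <- as.integer(shape)
  if (boundary_col <= 0 || boundary_col >= shape[2]) {
    stop("`boundary_col` must lie strictly inside the grid columns.",
         call. = FALSE)
  }
  px <- expand_pixels(shape)
  n_px <- shape[1] * shape[2]
  counts <- matrix(0L, nrow = n_px, ncol = config$n_bins)
  truth <- integer(n_px)
  for (i in seq_len(n_px)) {
    is_a <- px$col[i] < boundary_col
    spec <- if (is_a) pop_a else pop_b
    truth[i] <- spec$label
    counts[i, ] <- simulate_decay(spec, config,
                                  seed = pixel_seed(seed, px$row[i], px$col[i]),
                                  noise = noise)
  }
  decay_map(counts, shape, config, truth = truth)
}

#' Simulate a ladder of noiseless decays with prescribed peak counts
#'
#' One mono-exponential, noiseless decay per requested peak value, laid out
#' as a single-row map in the given order; decay `j` has
#' `peak_count == peaks[j]` exactly. A convenient fixture for exercising the
#' strict `> threshold` peak-count filter.
#'
#' @param peaks Non-empty vector of non-negative integers.
#' @param config An [acq_config()].
#' @param tau_ns Lifetime of every ladder decay (default 3.7 ns).
#' @return A [decay_map()] of shape `c(1, length(peaks))`.
#' @export
simulate_peak_ladder <- function(peaks, config = acq_config(), tau_ns = 3.7) {
  if (length(peaks) == 0) {
    stop("`peaks` must be non-empty.", call. = FALSE)
  }
  if (any(peaks < 0) || any(peaks != round(peaks))) {
    stop("`peaks` must be non-negative integers.", call. = FALSE)
  }
  counts <- matrix(0L, nrow = length(peaks), ncol = config$n_bins)
  for (j in seq_along(peaks)) {
    if (peaks[j] == 0) next
    spec <- population_spec(tau_ns, target_peak = peaks[j])
    counts[j, ] <- simulate_decay(spec, config, noise = "none")
  }
  decay_map(counts, c(1L, length(peaks)), config)
}
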