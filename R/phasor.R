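#' Phasor transform of a decay histogram
#'
#' Projects a photon-count histogram onto the first (or a higher) harmonic of
#' the excitation frequency. With `omega = 2 * pi * harmonic * rep_rate_hz`
#' and bin-centre times `t_k` from [time_axis()]:
#' \deqn{g = \frac{\sum_k c_k \cos(\omega t_k)}{\sum_k c_k}, \qquad
#'       s = \frac{\sum_k c_k \sin(\omega t_k)}{\sum_k c_k}.}
#' The pair (g, s) is a fit-free summary of the decay kinetics: all
#' mono-exponential decays fall on the universal semicircle
#' `(g - 1/2)^2 + s^2 = 1/4`, and any mixture falls inside it.
#'
#' @param counts Non-negative numeric vector of per-bin counts with a
#'   positive total.
#' @param config An [acq_config()].
#' @param harmonic Positive integer harmonic of the repetition rate
#'   (default 1).
#' @return A tibble with one row: columns `g`, `s`, `total_counts`.
#' @export
#' @examples
#' cfg <- acq_config()
#' d <- simulate_decay(population_spec(3.7), cfg, noise = "none")
#' phasor_transform(d, cfg)
phasor_transform <- function(counts, config, harmonic = 1L) {
  stopifnot(is_acq_config(config))
  if (harmonic < 1 || harmonic != round(harmonic)) {
    stop("`harmonic` must be a positive integer.", call. = FALSE)
  }
  if (length(counts) != config$n_bins) {
    stop("Histogram length does not match config n_bins.", call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("Counts must be non-negative.", call. = FALSE)
  }
  total <- sum(counts)
  if (total <= 0) {
    stop("Undefined phasor: decay has zero total counts (filter first).",
         call. = FALSE)
  }
  omega <- 2 * pi * harmonic * config$rep_rate_hz
  t <- time_axis(config)
  tibble::tibble(
    g = sum(counts * cos(omega * t)) / total,
    s = sum(counts * sin(omega * t)) / total,
    total_counts = total
  )
}

#' Closed-form phasor of a mono-exponential decay
#'
#' For a continuous mono-exponential decay of lifetime `tau` observed at
#' angular frequency `omega = 2 * pi * harmonic * rep_rate_hz`:
#' `g = 1 / (1 + (omega tau)^2)`, `s = omega tau / (1 + (omega tau)^2)`.
#' This is the exact point on the universal semicircle and serves as the
#' analytic oracle for the discrete transform.
#'
#' @param tau_ns Positive lifetime in ns.
#' @param config An [acq_config()].
#' @param harmonic Positive integer harmonic (default 1).
#' @return A tibble with columns `g`, `s` (one row per `tau_ns`).
#' @export
#' @examples
#' mono_exponential_phasor(3.7, acq_config()) # (0.8223, 0.3823)
mono_exponential_phasor <- function(tau_ns, config = acq_config(),
                                    harmonic = 1L) {
  stopifnot(is_acq_config(config))
  if (any(tau_ns <= 0)) {
    stop("`tau_ns` must be positive.", call. = FALSE)
  }
  wt <- 2 * pi * harmonic * config$rep_rate_hz * tau_ns * 1e-9
  tibble::tibble(g = 1 / (1 + wt^2), s = wt / (1 + wt^2))
}

#' Phase lifetime from phasor coordinates
#'
#' `tau_phase = s / (2 * pi * f * g)` with `f` the laser repetition rate;
#' equals the true lifetime for a mono-exponential decay and an
#' intensity-weighted effective lifetime otherwise.
#'
#' @param g,s Phasor coordinates (vectorized).
#' @param rep_rate_hz Repetition rate in Hz (default 2e7).
#' @return Phase lifetime(s) in ns.
#' @details Requires `g > 0`; non-positive `g` (decays rotated past a quarter
#'   period, never produced by physical non-negative decays at the first
#'   harmonic) has no meaningful phase lifetime and raises an error here.
#'   Map-level code marks such pixels as missing instead of calling this.
#' @export
#' @examples
#' tau_phase(0.8223, 0.3823) # ~3.70 ns
tau_phase <- function(g, s, rep_rate_hz = 2e7) {
  if (any(g <= 0)) {
    stop("`tau_phase` is undefined for g <= 0.", call. = FALSE)
  }
  s / (2 * pi * rep_rate_hz * g) * 1e9
}

#' Peak-count quality filter
#'
#' Marks the pixels whose decay histogram has peak count strictly greater
#' than `threshold`; only those pixels enter the phasor analysis. The strict
#' inequality means a decay peaking at exactly `threshold` counts is
#' excluded.
#'
#' @param map A [decay_map()].
#' @param threshold Non-negative integer (default 100).
#' @return Logical matrix of dimension `map_shape(map)`; `TRUE` = retained.
#' @export
filter_by_peak_count <- function(map, threshold = 100L) {
  stopifnot(inherits(map, "decay_map"))
  if (threshold < 0) {
    stop("`threshold` must be >= 0.", call. = FALSE)
  }
  peaks <- vapply(map$counts, function(x) max(x), numeric(1))
  sh <- map_shape(map)
  # map rows are row-major, matrix() fills column-major: transpose via byrow
  matrix(peaks > threshold, nrow = sh[1], ncol = sh[2], byrow = TRUE)
}

#' Compute the phasor cloud of a decay map
#'
#' Applies the peak-count filter, phasor-transforms every retained pixel, and
#' attaches the phase lifetime. The result is a tibble with one row per
#' retained pixel — columns `row`, `col`, `g`, `s`, `total_counts`, `tau_ns`
#' (`NA` where `g <= 0`), and `truth` when the map carries ground-truth
#' labels — keeping the pixel back-references that make phasor-domain
#' clusters traceable to image positions (reciprocity).
#'
#' @param map A [decay_map()].
#' @param threshold Peak-count threshold (strict; default 100).
#' @param harmonic Phasor harmonic (default 1).
#' @return A tibble of class `phasor_cloud` with attributes `config`,
#'   `shape`, `retained_mask`, `threshold`, `harmonic`.
#' @export
#' @examples
#' m <- simulate_interface_map(population_spec(3.7, label = 1),
#'                             population_spec(1.7, label = 2),
#'                             shape = c(5, 6), boundary_col = 3, seed = 1)
#' cloud <- compute_phasor_cloud(m)
#' dplyr::count(cloud, truth)
compute_phasor_cloud <- function(map, threshold = 100L, harmonic = 1L) {
  stopifnot(inherits(map, "decay_map"))
  mask <- filter_by_peak_count(map, threshold)
  # mask is (row, col); map rows are row-major
  keep <- mask[cbind(map$row + 1L, map$col + 1L)]
  if (!any(keep)) {
    stop(sprintf(
      "Empty phasor cloud: no decay has peak count > %d.", threshold),
      call. = FALSE)
  }
  cfg <- map_config(map)
  omega <- 2 * pi * harmonic * cfg$rep_rate_hz
  t <- time_axis(cfg)
  cm <- counts_matrix(map)[keep, , drop = FALSE]
  totals <- rowSums(cm)
  g <- as.vector(cm %*% cos(omega * t)) / totals
  s <- as.vector(cm %*% sin(omega * t)) / totals
  tau <- ifelse(g > 0, s / (2 * pi * cfg$rep_rate_hz * pmax(g, .Machine$double.xmin)) * 1e9,
                NA_real_)
  out <- tibble::tibble(
    row = map$row[keep], col = map$col[keep],
    g = g, s = s, total_counts = totals, tau_ns = tau
  )
  if (!is.null(map[["truth"]])) out$truth <- map[["truth"]][keep]
  structure(out,
            config = cfg,
            shape = map_shape(map),
            retained_mask = mask,
            threshold = as.integer(threshold),
            harmonic = as.integer(harmonic),
            class = c("phasor_cloud", class(tibble::tibble())))
}

#' @export
print.phasor_cloud <- function(x, ...) {
  sh <- attr(x, "shape")
  cat(sprintf(
    "<phasor_cloud> %d phasors retained of %d pixels (peak > %d)\n",
    nrow(x), sh[1] * sh[2], attr(x, "threshold")))
  NextMethod()
}

#' Phase-lifetime map of a phasor cloud
#'
#' Spreads the per-pixel phase lifetimes back onto the acquisition grid.
#' Pixels removed by the peak-count filter, and retained pixels with
#' `g <= 0`, carry the missing marker `NA`.
#'
#' @param cloud A [compute_phasor_cloud()] result.
#' @return Numeric matrix of dimension `map_shape(cloud)`, lifetimes in ns.
#' @export
tau_phase_map <- function(cloud) {
  stopifnot(inherits(cloud, "phasor_cloud"))
  sh <- attr(cloud, "shape")
  m <- matrix(NA_real_, nrow = sh[1], ncol = sh[2])
  m[cbind(cloud$row + 1L, cloud$col + 1L)] <- cloud$tau_ns
  m
}

#' 2-D density histogram of a phasor cloud
#'
#' Bins the (g, s) coordinates onto a regular grid, the numerical counterpart
#' of the density-coloured phasor plot. Points on or beyond the bounds are
#' clamped into the edge bins so the grid total always equals the cloud size.
#'
#' @param cloud A `phasor_cloud`.
#' @param n_bins_g,n_bins_s Number of grid cells along g and s (defaults
#'   100 and 60).
#' @param g_range,s_range Axis bounds (defaults `c(0, 1)` and `c(0, 0.6)`,
#'   covering the universal semicircle).
#' @return Integer matrix (`n_bins_g` rows, `n_bins_s` columns) with
#'   attributes `g_breaks`, `s_breaks`.
#' @export
density_histogram <- function(cloud, n_bins_g = 100L, n_bins_s = 60L,
                              g_range = c(0, 1), s_range = c(0, 0.6)) {
  stopifnot(inherits(cloud, "phasor_cloud"))
  if (nrow(cloud) == 0) {
    stop("Cloud is empty.", call. = FALSE)
  }
  if (diff(g_range) <= 0 || diff(s_range) <= 0) {
    stop("Degenerate axis bounds.", call. = FALSE)
  }
  ix <- bin_index(cloud$g, g_range, n_bins_g)
  iy <- bin_index(cloud$s, s_range, n_bins_s)
  grid <- matrix(0L, nrow = n_bins_g, ncol = n_bins_s)
  for (i in seq_along(ix)) {
    grid[ix[i], iy[i]] <- grid[ix[i], iy[i]] + 1L
  }
  attr(grid, "g_breaks") <- seq(g_range[1], g_range[2], length.out = n_bins_g + 1)
  attr(grid, "s_breaks") <- seq(s_range[1], s_range[2], length.out = n_bins_s + 1)
  grid
}

bin_index <- function(x, range, n) {
  i <- floor((x - range[1]) / diff(range) * n) + 1
  pmin(pmax(as.integer(i), 1L), as.integer(n))
}

#' Phasor-plot display
#'
#' 2-D binned density of the phasor cloud with the universal semicircle
#' overlaid; mono-exponential decays fall on the semicircle, mixtures inside.
#'
#' @param object A `phasor_cloud`.
#' @param bins Number of hexagon-free square bins per axis (default 80).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phasor_cloud <- function(object, bins = 80, ...) {
  semi <- tibble::tibble(
    g = 0.5 + 0.5 * cos(seq(0, pi, length.out = 200)),
    s = 0.5 * sin(seq(0, pi, length.out = 200))
  )
  ggplot2::ggplot(object, ggplot2::aes(x = .data$g, y = .data$s)) +
    ggplot2::geom_bin2d(bins = bins) +
    ggplot2::geom_path(data = semi, linetype = "dashed", colour = "grey40") +
    ggplot2::scale_fill_viridis_c(name = "phasors") +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 0.6)) +
    ggplot2::labs(x = "g", y = "s", title = "Phasor plot") +
    ggplot2::theme_minimal()
}
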