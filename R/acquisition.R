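#' TCSPC acquisition configuration
#'
#' Timing and instrument parameters of a time-correlated single photon
#' counting (TCSPC) acquisition. The defaults describe a 20 MHz pulsed
#' excitation with an 8-bit TCSPC card resolving 256 bins of 195 ps each,
#' i.e. a 49.92 ns histogram inside the 50 ns excitation period.
#'
#' @param rep_rate_hz Laser repetition rate in Hz (default `2e7`). Sets the
#'   excitation period `T = 1/rep_rate_hz` and the phasor harmonic frequency.
#' @param n_bins Number of histogram bins (integer, at least 2; default 256).
#' @param bin_width_s Width of one histogram bin in seconds (default
#'   `1.95e-10`, i.e. 195 ps).
#' @param emission_band Optional length-2 numeric, emission filter band in nm
#'   (metadata only).
#' @param numerical_aperture Numerical aperture of the delivery fibre
#'   (default 0.22); used by [spot_diameter()].
#'
#' @return An object of class `acq_config`.
#' @details The histogram window `n_bins * bin_width_s` must fit within one
#'   excitation period, otherwise bins would alias across pulses.
#' @seealso [time_axis()], [spot_diameter()]
#' @export
#' @examples
#' cfg <- acq_config()
#' cfg$n_bins * cfg$bin_width_s # 49.92 ns window
acq_config <- function(rep_rate_hz = 2e7,
                       n_bins = 256L,
                       bin_width_s = 1.95e-10,
                       emission_band = NULL,
                       numerical_aperture = 0.22) {
  if (!is.numeric(rep_rate_hz) || length(rep_rate_hz) != 1 || rep_rate_hz <= 0) {
    stop("`rep_rate_hz` must be a single positive number.", call. = FALSE)
  }
  if (!is.numeric(n_bins) || length(n_bins) != 1 || n_bins != round(n_bins) ||
      n_bins < 2) {
    stop("`n_bins` must be a single integer >= 2.", call. = FALSE)
  }
  if (!is.numeric(bin_width_s) || length(bin_width_s) != 1 || bin_width_s <= 0) {
    stop("`bin_width_s` must be a single positive number.", call. = FALSE)
  }
  if (n_bins * bin_width_s > 1 / rep_rate_hz + 1e-15) {
    stop("Histogram window n_bins * bin_width_s exceeds the excitation ",
         "period 1/rep_rate_hz.", call. = FALSE)
  }
  if (!is.null(emission_band)) {
    stopifnot(is.numeric(emission_band), length(emission_band) == 2)
  }
  if (!is.numeric(numerical_aperture) || numerical_aperture <= 0 ||
      numerical_aperture >= 1) {
    stop("`numerical_aperture` must lie in (0, 1).", call. = FALSE)
  }
  structure(
    list(
      rep_rate_hz = as.numeric(rep_rate_hz),
      n_bins = as.integer(n_bins),
      bin_width_s = as.numeric(bin_width_s),
      emission_band = emission_band,
      numerical_aperture = as.numeric(numerical_aperture)
    ),
    class = "acq_config"
  )
}

#' @export
print.acq_config <- function(x, ...) {
  cat("<acq_config>\n")
  cat(sprintf("  repetition rate : %.4g MHz\n", x$rep_rate_hz / 1e6))
  cat(sprintf("  bins            : %d x %.4g ps (window %.4g ns)\n",
              x$n_bins, x$bin_width_s * 1e12,
              x$n_bins * x$bin_width_s * 1e9))
  if (!is.null(x$emission_band)) {
    cat(sprintf("  emission band   : %g-%g nm\n",
                x$emission_band[1], x$emission_band[2]))
  }
  cat(sprintf("  fibre NA        : %.3g\n", x$numerical_aperture))
  invisible(x)
}

is_acq_config <- function(x) inherits(x, "acq_config")

#' Bin-centre time axis of an acquisition
#'
#' Returns the photon-arrival time assigned to each histogram bin under the
#' bin-centre convention `t_k = (k + 1/2) * bin_width_s`, `k = 0, ...,
#' n_bins - 1`. Centring the sample inside the bin halves the leading-order
#' discretization bias of the phasor projections compared with left-edge
#' sampling.
#'
#' @param config An [acq_config()].
#' @return Numeric vector of length `config$n_bins`, strictly increasing,
#'   in seconds.
#' @export
#' @examples
#' t <- time_axis(acq_config())
#' t[1] * 1e12 # 97.5 ps
time_axis <- function(config) {
  if (!is_acq_config(config)) {
    stop("`config` must be an acq_config object.", call. = FALSE)
  }
  (seq_len(config$n_bins) - 0.5) * config$bin_width_s
}

#' Peak count of a decay histogram
#'
#' The maximum bin value of a photon-count histogram; the quantity the
#' quality filter thresholds (decays with peak count > 100 are retained by
#' default downstream).
#'
#' @param counts Non-negative integer vector of per-bin photon counts.
#' @return A single non-negative integer.
#' @seealso [filter_by_peak_count()]
#' @export
peak_count <- function(counts) {
  if (length(counts) == 0) {
    stop("Empty decay histogram.", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("Counts must be finite and non-negative.", call. = FALSE)
  }
  as.integer(max(counts))
}

#' Irradiated spot diameter of the fibre-delivered beam
#'
#' Diameter of the excitation spot produced by a fibre of numerical aperture
#' `na` held at `distance_mm` from the sample, under a cone-divergence model:
#' the half-angle of the emerging cone is `asin(na)`, so the spot diameter is
#' `2 * distance_mm * tan(asin(na))`.
#'
#' @param distance_mm Fibre-to-sample distance in mm (non-negative).
#' @param na Numerical aperture, in (0, 1). Default 0.22.
#' @return Spot diameter in mm.
#' @export
#' @examples
#' round(spot_diameter(10), 1) # 4.5 mm
#' round(spot_diameter(2), 1)  # 0.9 mm
spot_diameter <- function(distance_mm, na = 0.22) {
  if (!is.numeric(na) || length(na) != 1 || na <= 0 || na >= 1) {
    stop("`na` must lie strictly in (0, 1).", call. = FALSE)
  }
  if (any(distance_mm < 0)) {
    stop("`distance_mm` must be non-negative.", call. = FALSE)
  }
  2 * distance_mm * tan(asin(na))
}

#' Construct a decay map
#'
#' A decay map is one TCSPC histogram per pixel of a regular
#' `shape = c(n_rows, n_cols)` grid, held as a tibble with one row per pixel:
#' columns `row`, `col` (0-based, row-major), a `counts` list-column of
#' integer vectors of length `config$n_bins`, and optionally `truth`
#' (ground-truth population labels, simulation only). The acquisition
#' configuration and grid shape travel as attributes.
#'
#' @param counts Integer matrix, one histogram per row (`n_rows * n_cols`
#'   rows in row-major pixel order, `config$n_bins` columns), or a list of
#'   integer vectors.
#' @param shape Integer vector `c(n_rows, n_cols)`.
#' @param config An [acq_config()].
#' @param truth Optional integer vector of ground-truth labels, one per pixel.
#' @return A tibble of class `decay_map`.
#' @export
decay_map <- function(counts, shape, config, truth = NULL) {
  if (!is_acq_config(config)) {
    stop("`config` must be an acq_config object.", call. = FALSE)
  }
  if (is.list(counts)) {
    counts <- do.call(rbind, counts)
  }
  shape <- as.integer(shape)
  if (length(shape) != 2 || any(shape < 1)) {
    stop("`shape` must be two positive integers (n_rows, n_cols).",
         call. = FALSE)
  }
  n_px <- shape[1] * shape[2]
  if (nrow(counts) != n_px) {
    stop(sprintf("Expected %d histograms for shape %dx%d, got %d.",
                 n_px, shape[1], shape[2], nrow(counts)), call. = FALSE)
  }
  if (ncol(counts) != config$n_bins) {
    stop(sprintf("Histogram length %d does not match config n_bins = %d.",
                 ncol(counts), config$n_bins), call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("Counts must be non-negative integers.", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  px <- expand_pixels(shape)
  out <- tibble::tibble(
    row = px$row,
    col = px$col,
    counts = lapply(seq_len(n_px), function(i) counts[i, ])
  )
  if (!is.null(truth)) {
    stopifnot(length(truth) == n_px)
    out$truth <- as.integer(truth)
  }
  new_decay_map(out, shape, config)
}

# row-major 0-based pixel grid
expand_pixels <- function(shape) {
  list(
    row = rep(seq_len(shape[1]) - 1L, each = shape[2]),
    col = rep(seq_len(shape[2]) - 1L, times = shape[1])
  )
}

new_decay_map <- function(df, shape, config) {
  structure(df,
            shape = as.integer(shape),
            config = config,
            class = c("decay_map", class(tibble::tibble())))
}

#' @export
print.decay_map <- function(x, ...) {
  sh <- attr(x, "shape")
  cfg <- attr(x, "config")
  cat(sprintf("<decay_map> %d x %d pixels, %d bins x %.4g ps, %.4g MHz\n",
              sh[1], sh[2], cfg$n_bins, cfg$bin_width_s * 1e12,
              cfg$rep_rate_hz / 1e6))
  NextMethod()
}

#' Grid shape and configuration accessors
#'
#' @param x A `decay_map` or `phasor_cloud` object.
#' @return `map_shape()` returns `c(n_rows, n_cols)`; `map_config()` the
#'   attached [acq_config()].
#' @export
map_shape <- function(x) attr(x, "shape")

#' @rdname map_shape
#' @export
map_config <- function(x) attr(x, "config")

# counts list-column as a dense matrix (pixels x bins)
counts_matrix <- function(map) {
  do.call(rbind, map$counts)
}

decay_map_header <- function(map) {
  sh <- map_shape(map)
  cfg <- map_config(map)
  sprintf(
    "# phasorseg-decaymap v1, rows=%d, cols=%d, n_bins=%d, bin_width_s=%.6g, rep_rate_hz=%.6g",
    sh[1], sh[2], cfg$n_bins, cfg$bin_width_s, cfg$rep_rate_hz
  )
}

#' Write and read decay maps as delimited text
#'
#' The on-disk dialect is comma-separated text: a header line
#' `# phasorseg-decaymap v1, rows=R, cols=C, n_bins=N, bin_width_s=..., rep_rate_hz=...`
#' followed by one line per pixel, `row,col,c0,c1,...,c{N-1}`. If `path` ends
#' in `.tar.gz` the same text file plus a flat key-value config file are
#' written into a compressed archive, which [read_decay_map()] also accepts.
#'
#' `read_decay_map(write_decay_map(map))` is the identity: counts round-trip
#' bit-exactly and the shape and timing parameters are preserved. Ground-truth
#' labels are not part of the dialect; [run_simulate()] writes them to a
#' separate CSV.
#'
#' @param map A [decay_map()].
#' @param path Output path (`.csv`/any text extension, or `.tar.gz`).
#' @param config Optional [acq_config()]; if supplied on read it must agree
#'   with the file header.
#' @return `write_decay_map()` returns `path` invisibly; `read_decay_map()`
#'   returns a [decay_map()].
#' @export
write_decay_map <- function(map, path) {
  if (!inherits(map, "decay_map")) {
    stop("`map` must be a decay_map.", call. = FALSE)
  }
  if (grepl("\\.tar\\.gz$", path)) {
    return(write_decay_archive(map, path))
  }
  cm <- counts_matrix(map)
  body <- paste(map$row, map$col,
                apply(cm, 1, paste, collapse = ","), sep = ",")
  writeLines(c(decay_map_header(map), body), path)
  invisible(path)
}

write_decay_archive <- function(map, path) {
  dir <- tempfile("decaymap_dir_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  write_decay_map_plain <- file.path(dir, "decaymap.csv")
  cm <- counts_matrix(map)
  body <- paste(map$row, map$col,
                apply(cm, 1, paste, collapse = ","), sep = ",")
  writeLines(c(decay_map_header(map), body), write_decay_map_plain)
  cfg <- map_config(map)
  write_run_config(run_config(acquisition = cfg),
                   file.path(dir, "config.txt"))
  path <- normalizePath(path, mustWork = FALSE)
  old <- setwd(dir)
  on.exit(setwd(old), add = TRUE)
  utils::tar(path, files = c("decaymap.csv", "config.txt"),
             compression = "gzip", tar = "internal")
  invisible(path)
}

#' @rdname write_decay_map
#' @export
read_decay_map <- function(path, config = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("File not found: %s", path), call. = FALSE)
  }
  if (grepl("\\.tar\\.gz$", path)) {
    dir <- tempfile("decaymap_untar_")
    utils::untar(path, exdir = dir, tar = "internal")
    on.exit(unlink(dir, recursive = TRUE), add = TRUE)
    inner <- file.path(dir, "decaymap.csv")
    if (!file.exists(inner)) {
      stop("Archive does not contain decaymap.csv.", call. = FALSE)
    }
    path <- inner
  }
  lines <- readLines(path)
  if (length(lines) < 2) {
    stop("Decay-map file must have a header and at least one pixel row.",
         call. = FALSE)
  }
  hdr <- parse_decay_header(lines[1])
  cfg <- acq_config(rep_rate_hz = hdr$rep_rate_hz, n_bins = hdr$n_bins,
                    bin_width_s = hdr$bin_width_s)
  if (!is.null(config)) {
    same <- isTRUE(all.equal(config$rep_rate_hz, cfg$rep_rate_hz)) &&
      config$n_bins == cfg$n_bins &&
      isTRUE(all.equal(config$bin_width_s, cfg$bin_width_s))
    if (!same) {
      stop("Supplied config disagrees with the file header.", call. = FALSE)
    }
    cfg <- config
  }
  n_px <- hdr$rows * hdr$cols
  body <- lines[-1]
  if (length(body) != n_px) {
    stop(sprintf("Header promises %d pixels but file has %d data rows.",
                 n_px, length(body)), call. = FALSE)
  }
  counts <- matrix(0L, nrow = n_px, ncol = hdr$n_bins)
  rows <- integer(n_px)
  cols <- integer(n_px)
  for (i in seq_along(body)) {
    fields <- strsplit(body[i], ",", fixed = TRUE)[[1]]
    if (length(fields) != hdr$n_bins + 2) {
      stop(sprintf(
        "Row %d: expected %d fields (row, col, %d counts), found %d.",
        i, hdr$n_bins + 2, hdr$n_bins, length(fields)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals))) {
      stop(sprintf("Row %d: non-numeric field.", i), call. = FALSE)
    }
    cts <- vals[-(1:2)]
    if (any(cts < 0) || any(cts != round(cts))) {
      stop(sprintf("Row %d: counts must be non-negative integers.", i),
           call. = FALSE)
    }
    rows[i] <- vals[1]
    cols[i] <- vals[2]
    counts[i, ] <- as.integer(cts)
  }
  # reorder into row-major pixel order regardless of file ordering
  ord <- order(rows, cols)
  expect <- expand_pixels(c(hdr$rows, hdr$cols))
  if (!all(rows[ord] == expect$row) || !all(cols[ord] == expect$col)) {
    stop("Pixel indices do not tile the declared grid exactly once.",
         call. = FALSE)
  }
  decay_map(counts[ord, , drop = FALSE], c(hdr$rows, hdr$cols), cfg)
}

parse_decay_header <- function(line) {
  if (!startsWith(line, "# phasorseg-decaymap v1")) {
    stop("Not a phasorseg-decaymap v1 file (bad header).", call. = FALSE)
  }
  grab <- function(key, line) {
    m <- regmatches(line, regexpr(paste0(key, "=[0-9eE.+-]+"), line))
    if (length(m) == 0) {
      stop(sprintf("Header is missing `%s`.", key), call. = FALSE)
    }
    as.numeric(sub(paste0(key, "="), "", m))
  }
  list(
    rows = as.integer(grab("rows", line)),
    cols = as.integer(grab("cols", line)),
    n_bins = as.integer(grab("n_bins", line)),
    bin_width_s = grab("bin_width_s", line),
    rep_rate_hz = grab("rep_rate_hz", line)
  )
}

#' Run configuration
#'
#' Bundles the acquisition parameters with the analysis defaults: the
#' peak-count quality threshold (strictly greater than; default 100), the
#' number of mixture components K (default 2, two known populations either
#' side of an interface), the random seed, and the lifetime colour range of
#' rendered maps (2.0-4.5 ns).
#'
#' @param acquisition An [acq_config()].
#' @param peak_threshold Integer >= 0, retain pixels with peak count strictly
#'   greater than this.
#' @param k_clusters Integer >= 1, mixture components.
#' @param seed Integer seed for all randomness.
#' @param tau_color_min_ns,tau_color_max_ns Endpoints of the lifetime colour
#'   ramp in ns.
#' @return An object of class `run_config`.
#' @export
run_config <- function(acquisition = acq_config(),
                       peak_threshold = 100L,
                       k_clusters = 2L,
                       seed = 0L,
                       tau_color_min_ns = 2.0,
                       tau_color_max_ns = 4.5) {
  stopifnot(is_acq_config(acquisition))
  if (peak_threshold < 0) stop("`peak_threshold` must be >= 0.", call. = FALSE)
  if (k_clusters < 1) stop("`k_clusters` must be >= 1.", call. = FALSE)
  structure(
    list(
      acquisition = acquisition,
      peak_threshold = as.integer(peak_threshold),
      k_clusters = as.integer(k_clusters),
      seed = as.integer(seed),
      tau_color_min_ns = tau_color_min_ns,
      tau_color_max_ns = tau_color_max_ns
    ),
    class = "run_config"
  )
}

#' Read and write flat key-value run-configuration files
#'
#' One `key = value` pair per line; keys: `rep_rate_hz`, `n_bins`,
#' `bin_width_s`, `peak_threshold`, `k_clusters`, `seed`,
#' `tau_color_min_ns`, `tau_color_max_ns`.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `read_run_config()` returns a [run_config()];
#'   `write_run_config()` returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  acq <- config$acquisition
  kv <- c(
    rep_rate_hz = acq$rep_rate_hz,
    n_bins = acq$n_bins,
    bin_width_s = acq$bin_width_s,
    peak_threshold = config$peak_threshold,
    k_clusters = config$k_clusters,
    seed = config$seed,
    tau_color_min_ns = config$tau_color_min_ns,
    tau_color_max_ns = config$tau_color_max_ns
  )
  writeLines(sprintf("%s = %.10g", names(kv), kv), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("Config file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2
  if (any(bad)) {
    stop(sprintf("Config line %d is not `key = value`.", which(bad)[1]),
         call. = FALSE)
  }
  keys <- trimws(vapply(parts, `[[`, "", 1))
  vals <- as.numeric(trimws(vapply(parts, `[[`, "", 2)))
  kv <- stats::setNames(as.list(vals), keys)
  pick <- function(key, default) if (!is.null(kv[[key]])) kv[[key]] else default
  run_config(
    acquisition = acq_config(
      rep_rate_hz = pick("rep_rate_hz", 2e7),
      n_bins = pick("n_bins", 256),
      bin_width_s = pick("bin_width_s", 1.95e-10)
    ),
    peak_threshold = pick("peak_threshold", 100),
    k_clusters = pick("k_clusters", 2),
    seed = pick("seed", 0),
    tau_color_min_ns = pick("tau_color_min_ns", 2.0),
    tau_color_max_ns = pick("tau_color_max_ns", 4.5)
  )
}
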