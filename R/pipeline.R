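#' End-to-end phasor segmentation of a decay map
#'
#' Runs the full analysis chain on a decay map: peak-count filter, phasor
#' transform and phase lifetimes, K-component Gaussian mixture fit on the
#' (g, s) cloud, canonical cluster ordering (longest-lived first),
#' hard-edge assignment, reciprocity mapping back to the pixel grid, and
#' per-cluster lifetime summaries.
#'
#' @param map A [decay_map()].
#' @param threshold Peak-count threshold (strict; default 100).
#' @param k Mixture components (default 2).
#' @param seed Integer seed for the mixture initialization.
#' @param harmonic Phasor harmonic (default 1).
#' @param ... Further arguments passed to [fit_gmm()].
#' @return An object of class `phasor_segmentation`: a list with elements
#'   `cloud`, `fit` (canonically ordered), `labels`, `seg`
#'   (the label matrix), `tau_map`, and `summary` (the [cluster_summary()]
#'   tibble).
#' @export
#' @examples
#' m <- simulate_interface_map(population_spec(3.7, label = 1),
#'                             population_spec(1.7, label = 2),
#'                             shape = c(10, 10), boundary_col = 5, seed = 1)
#' seg <- segment_decay_map(m, seed = 1)
#' seg$summary
segment_decay_map <- function(map, threshold = 100L, k = 2L, seed = 0L,
                              harmonic = 1L, ...) {
  cloud <- compute_phasor_cloud(map, threshold = threshold,
                                harmonic = harmonic)
  fit <- fit_gmm(cloud, k = k, seed = seed, ...)
  fit <- order_clusters(fit, cloud)
  labels <- hard_assign(fit)
  seg <- map_labels_to_image(cloud, labels)
  structure(
    list(cloud = cloud, fit = fit, labels = labels, seg = seg,
         tau_map = tau_phase_map(cloud),
         summary = cluster_summary(cloud, labels)),
    class = "phasor_segmentation"
  )
}

#' @export
print.phasor_segmentation <- function(x, ...) {
  cat(sprintf("<phasor_segmentation> %d phasors, K = %d\n",
              nrow(x$cloud), x$fit$params$k))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.phasor_segmentation <- function(x, ...) x$summary

#' @export
glance.phasor_segmentation <- function(x, ...) {
  sh <- attr(x$cloud, "shape")
  tibble::tibble(
    n_pixels = sh[1] * sh[2],
    n_retained = nrow(x$cloud),
    threshold = attr(x$cloud, "threshold"),
    k = x$fit$params$k,
    log_lik = x$fit$log_lik_trace[length(x$fit$log_lik_trace)],
    n_iter = x$fit$n_iter,
    converged = x$fit$converged
  )
}

#' @export
autoplot.phasor_segmentation <- function(object, ...) {
  autoplot(object$seg)
}

#' Simulate an interface experiment and write it to disk
#'
#' Writes the decay-map text file and a `row,col,label` ground-truth CSV for
#' a two-population interface simulation.
#'
#' @param out_dir Output directory (created if missing).
#' @param tau_a_ns,tau_b_ns Lifetimes (ns) of the left and right population.
#' @param shape `c(n_rows, n_cols)` (default `c(50, 60)`, i.e. 3000 pixels).
#' @param boundary_col First column of population b (default mid-grid).
#' @param peak Expected peak counts (default 500).
#' @param seed Integer seed (default 0).
#' @param noise `"poisson"` (default) or `"none"`.
#' @param config An [acq_config()].
#' @return Invisibly, a list with the written `decay_path` and `truth_path`.
#' @export
run_simulate <- function(out_dir, tau_a_ns = 3.7, tau_b_ns = 1.7,
                         shape = c(50L, 60L), boundary_col = NULL,
                         peak = 500, seed = 0L,
                         noise = c("poisson", "none"),
                         config = acq_config()) {
  noise <- match.arg(noise)
  if (is.null(boundary_col)) boundary_col <- shape[2] %/% 2
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  map <- simulate_interface_map(
    population_spec(tau_a_ns, target_peak = peak, label = 1L),
    population_spec(tau_b_ns, target_peak = peak, label = 2L),
    shape = shape, boundary_col = boundary_col,
    config = config, seed = seed, noise = noise
  )
  decay_path <- file.path(out_dir, "decaymap.csv")
  write_decay_map(map, decay_path)
  truth_path <- file.path(out_dir, "truth.csv")
  utils::write.csv(
    data.frame(row = map$row, col = map$col, label = map$truth),
    truth_path, row.names = FALSE)
  message(sprintf("simulated %dx%d map (seed %d) -> %s",
                  shape[1], shape[2], seed, decay_path))
  invisible(list(decay_path = decay_path, truth_path = truth_path,
                 map = map))
}

#' Segment a decay-map file and write all analysis artifacts
#'
#' Reads a decay map, runs [segment_decay_map()], and writes: the lifetime
#' map (CSV + float TIFF + rendered PNG), the phasor-plot density grid
#' (CSV), the mixture fit report, the cluster summary CSV, the label mask,
#' and the cluster / probability-blend renderings.
#'
#' @param input Decay-map file (text dialect or `.tar.gz` archive).
#' @param out_dir Output directory (created if missing).
#' @param threshold Peak-count threshold (default 100).
#' @param k Mixture components (default 2).
#' @param seed Integer seed (default 0).
#' @param tau_color_range Colour-ramp endpoints in ns (default `c(2, 4.5)`).
#' @return Invisibly, the `phasor_segmentation` object.
#' @export
run_segment <- function(input, out_dir, threshold = 100L, k = 2L, seed = 0L,
                        tau_color_range = c(2.0, 4.5)) {
  map <- read_decay_map(input)
  res <- segment_decay_map(map, threshold = threshold, k = k, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tau_map_csv(res$tau_map, file.path(out_dir, "tau_map.csv"))
  write_tau_map_tiff(res$tau_map, file.path(out_dir, "tau_map.tif"))
  write_image(render_tau_map(res$tau_map, tau_color_range[1],
                             tau_color_range[2]),
              file.path(out_dir, "tau_map.png"))
  dens <- density_histogram(res$cloud)
  utils::write.csv(as.data.frame(dens), file.path(out_dir, "phasor_density.csv"),
                   row.names = FALSE)
  write_fit_report(res$fit, file.path(out_dir, "fit_report.txt"))
  utils::write.csv(res$summary, file.path(out_dir, "cluster_summary.csv"),
                   row.names = FALSE)
  write_labels_png(res$seg, file.path(out_dir, "labels.png"))
  write_image(render_cluster_map(res$seg),
              file.path(out_dir, "cluster_map.png"))
  write_image(render_probability_blend(res$cloud, res$fit),
              file.path(out_dir, "probability_blend.png"))
  gl <- glance(res)
  message(sprintf(
    "retained %d/%d pixels; EM: %d iterations, log-lik %.4f",
    gl$n_retained, gl$n_pixels, gl$n_iter, gl$log_lik))
  invisible(res)
}

#' Aggregate cluster summaries from several runs
#'
#' Concatenates `cluster_summary.csv` files produced by [run_segment()] into
#' one table with columns `run`, `cluster`, `n`, `fraction`, `mean_tau_ns`,
#' `sd_tau_ns` (fixed column order).
#'
#' @param summary_files Character vector of `cluster_summary.csv` paths.
#' @param out Optional output CSV path.
#' @return The combined tibble.
#' @export
run_report <- function(summary_files, out = NULL) {
  if (length(summary_files) == 0) {
    stop("At least one summary file is required.", call. = FALSE)
  }
  rows <- lapply(summary_files, function(f) {
    if (!file.exists(f)) {
      stop(sprintf("Summary file not found: %s", f), call. = FALSE)
    }
    df <- tryCatch(utils::read.csv(f),
                   error = function(e) stop(sprintf(
                     "Malformed summary file %s: %s", f, conditionMessage(e)),
                     call. = FALSE))
    need <- c("cluster", "n", "fraction", "mean_tau_ns", "sd_tau_ns")
    if (!all(need %in% names(df))) {
      stop(sprintf("Malformed summary file %s: missing columns.", f),
           call. = FALSE)
    }
    df$run <- sub("\\.csv$", "", basename(dirname(f)))
    if (df$run[1] == "") df$run <- basename(f)
    df[, c("run", need)]
  })
  combined <- tibble::as_tibble(do.call(rbind, rows))
  if (!is.null(out)) {
    utils::write.csv(combined, out, row.names = FALSE)
  }
  combined
}

#' Command-line entry point
#'
#' Dispatches `simulate`, `segment` and `report` subcommands; the installed
#' wrapper script `system.file("cli", "phasorseg", package = "phasorseg")`
#' calls this with `commandArgs(trailingOnly = TRUE)`. Exit status 0 on
#' success, 1 for runtime/data errors, 2 for usage or domain errors.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (invisibly).
#' @export
phasorseg_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: phasorseg <command> [options]",
    "commands:",
    "  simulate --out DIR [--tau-a NS] [--tau-b NS] [--shape RxC]",
    "           [--peak N] [--seed N] [--noise poisson|none]",
    "  segment  --in FILE --out DIR [--threshold N] [--k N] [--seed N]",
    "           [--config FILE]",
    "  report   --out FILE SUMMARY.csv [SUMMARY.csv ...]",
    sep = "\n")
  if (length(args) == 0) {
    message(usage)
    return(invisible(2L))
  }
  cmd <- args[1]
  rest <- args[-1]
  status <- tryCatch({
    switch(cmd,
      simulate = cli_simulate(rest),
      segment = cli_segment(rest),
      report = cli_report(rest),
      {
        message(sprintf("unknown command `%s`\n%s", cmd, usage))
        2L
      })
  },
  phasorseg_usage_error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  },
  error = function(e) {
    msg <- conditionMessage(e)
    message("error: ", msg)
    # domain/usage errors (bad parameter values) exit 2, data errors 1
    if (grepl("must|undefined|Degenerate|strictly|positive|usage",
              msg, ignore.case = TRUE)) 2L else 1L
  })
  invisible(as.integer(status))
}

usage_error <- function(msg) {
  stop(structure(class = c("phasorseg_usage_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# tiny flag parser: --key value pairs plus positional arguments
parse_flags <- function(args) {
  flags <- list()
  positional <- character(0)
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      if (i == length(args) || startsWith(args[i + 1], "--")) {
        usage_error(sprintf("flag %s needs a value", a))
      }
      flags[[substring(a, 3)]] <- args[i + 1]
      i <- i + 2
    } else {
      positional <- c(positional, a)
      i <- i + 1
    }
  }
  list(flags = flags, positional = positional)
}

flag_num <- function(flags, key, default) {
  if (is.null(flags[[key]])) return(default)
  v <- suppressWarnings(as.numeric(flags[[key]]))
  if (is.na(v)) usage_error(sprintf("flag --%s must be numeric", key))
  v
}

cli_simulate <- function(args) {
  p <- parse_flags(args)
  f <- p$flags
  if (is.null(f$out)) usage_error("simulate requires --out DIR")
  shape <- c(50L, 60L)
  if (!is.null(f$shape)) {
    parts <- strsplit(f$shape, "x", fixed = TRUE)[[1]]
    if (length(parts) != 2) usage_error("--shape must look like 50x60")
    shape <- as.integer(parts)
  }
  noise <- if (is.null(f$noise)) "poisson" else f$noise
  if (!noise %in% c("poisson", "none")) {
    usage_error("--noise must be poisson or none")
  }
  run_simulate(f$out,
               tau_a_ns = flag_num(f, "tau-a", 3.7),
               tau_b_ns = flag_num(f, "tau-b", 1.7),
               shape = shape,
               peak = flag_num(f, "peak", 500),
               seed = as.integer(flag_num(f, "seed", 0)),
               noise = noise)
  0L
}

cli_segment <- function(args) {
  p <- parse_flags(args)
  f <- p$flags
  if (is.null(f$`in`) || is.null(f$out)) {
    usage_error("segment requires --in FILE and --out DIR")
  }
  defaults <- if (!is.null(f$config)) read_run_config(f$config) else run_config()
  run_segment(f$`in`, f$out,
              threshold = as.integer(flag_num(f, "threshold",
                                              defaults$peak_threshold)),
              k = as.integer(flag_num(f, "k", defaults$k_clusters)),
              seed = as.integer(flag_num(f, "seed", defaults$seed)),
              tau_color_range = c(defaults$tau_color_min_ns,
                                  defaults$tau_color_max_ns))
  0L
}

cli_report <- function(args) {
  p <- parse_flags(args)
  if (length(p$positional) == 0) {
    usage_error("report requires at least one summary file")
  }
  combined <- run_report(p$positional, out = p$flags$out)
  if (is.null(p$flags$out)) {
    utils::write.csv(combined, stdout(), row.names = FALSE)
  }
  0L
}
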