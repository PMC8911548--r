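#' Map phasor-cluster labels back to image space
#'
#' Uses the pixel back-references carried by the phasor cloud (reciprocity:
#' each phasor came from exactly one pixel) to place each cluster label on
#' the acquisition grid. Pixels removed by the quality filter stay
#' unclassified with label 0.
#'
#' @param cloud A `phasor_cloud`.
#' @param labels Integer labels in `1..K` aligned with the cloud rows.
#' @param shape Optional `c(n_rows, n_cols)`; defaults to the cloud's grid.
#' @return Integer matrix of class `seg_map`; 0 = unclassified.
#' @export
map_labels_to_image <- function(cloud, labels, shape = NULL) {
  if (length(labels) != nrow(cloud)) {
    stop("`labels` must align with the cloud rows.", call. = FALSE)
  }
  if (is.null(shape)) shape <- attr(cloud, "shape")
  shape <- as.integer(shape)
  if (any(cloud$row < 0) || any(cloud$row >= shape[1]) ||
      any(cloud$col < 0) || any(cloud$col >= shape[2])) {
    stop("Pixel back-references fall outside the grid.", call. = FALSE)
  }
  key <- cloud$row * shape[2] + cloud$col
  if (anyDuplicated(key)) {
    stop("Duplicate pixel references in cloud: reciprocity violated.",
         call. = FALSE)
  }
  m <- matrix(0L, nrow = shape[1], ncol = shape[2])
  m[cbind(cloud$row + 1L, cloud$col + 1L)] <- as.integer(labels)
  structure(m, class = c("seg_map", "matrix", "array"))
}

# neutral grey for filtered/unclassified pixels
GREY_SENTINEL <- c(128L, 128L, 128L)

# cluster palette: red, green, then documented extensions
CLUSTER_PALETTE <- rbind(
  c(255L, 0L, 0L),    # cluster 1: red
  c(0L, 255L, 0L),    # cluster 2: green
  c(0L, 0L, 255L),    # blue
  c(255L, 0L, 255L),  # magenta
  c(255L, 165L, 0L)   # orange
)

new_rendered_image <- function(rgb, legend) {
  storage.mode(rgb) <- "integer"
  structure(rgb, legend = legend,
            class = c("rendered_image", "array"))
}

#' Render a phase-lifetime map as false colour
#'
#' Finite lifetimes are mapped linearly onto a blue-to-red colour ramp (HSV
#' hue sweeping 240 degrees to 0 degrees), clipped at the endpoints; the
#' default 2.0-4.5 ns range places short lifetimes in blue and long ones in
#' red. Missing pixels (filtered or undefined) are neutral grey.
#'
#' @param tau_map Numeric matrix of lifetimes in ns with `NA` for missing
#'   pixels (see [tau_phase_map()]).
#' @param t_min_ns,t_max_ns Colour-ramp endpoints in ns (defaults 2.0, 4.5).
#' @return A `rendered_image`: `n_rows x n_cols x 3` integer array in
#'   0..255, with a `legend` attribute recording the endpoints.
#' @export
render_tau_map <- function(tau_map, t_min_ns = 2.0, t_max_ns = 4.5) {
  if (t_min_ns >= t_max_ns) {
    stop("`t_min_ns` must be below `t_max_ns`.", call. = FALSE)
  }
  frac <- (tau_map - t_min_ns) / (t_max_ns - t_min_ns)
  frac <- pmin(pmax(frac, 0), 1)
  hue <- (240 * (1 - frac)) / 360 # 240 deg (blue) -> 0 deg (red)
  rgb <- array(0L, dim = c(nrow(tau_map), ncol(tau_map), 3))
  ok <- is.finite(frac)
  cols <- grDevices::hsv(h = hue[ok], s = 1, v = 1)
  cr <- grDevices::col2rgb(cols)
  for (ch in 1:3) {
    plane <- matrix(GREY_SENTINEL[ch], nrow(tau_map), ncol(tau_map))
    plane[ok] <- cr[ch, ]
    rgb[, , ch] <- plane
  }
  new_rendered_image(rgb, legend = list(
    type = "tau_ramp", t_min_ns = t_min_ns, t_max_ns = t_max_ns,
    missing = GREY_SENTINEL))
}

#' Render a segmentation map in cluster colours
#'
#' Cluster 1 is red, cluster 2 green (further clusters: blue, magenta,
#' orange); unclassified pixels are neutral grey.
#'
#' @param seg A [map_labels_to_image()] result.
#' @return A `rendered_image`.
#' @export
render_cluster_map <- function(seg) {
  k <- max(seg)
  if (k > nrow(CLUSTER_PALETTE)) {
    stop(sprintf("Palette supports up to %d clusters, got %d.",
                 nrow(CLUSTER_PALETTE), k), call. = FALSE)
  }
  rgb <- array(0L, dim = c(nrow(seg), ncol(seg), 3))
  for (ch in 1:3) {
    plane <- matrix(GREY_SENTINEL[ch], nrow(seg), ncol(seg))
    for (lab in seq_len(max(k, 0))) {
      plane[seg == lab] <- CLUSTER_PALETTE[lab, ch]
    }
    rgb[, , ch] <- plane
  }
  legend <- list(type = "clusters",
                 palette = CLUSTER_PALETTE[seq_len(max(k, 1)), , drop = FALSE],
                 missing = GREY_SENTINEL)
  new_rendered_image(rgb, legend)
}

#' Render soft cluster memberships as blended colours
#'
#' Instead of cutting hard edges, each retained pixel is coloured by the
#' responsibility-weighted average of the cluster palette colours, giving
#' intermediate tones where the mixture model is uncertain. A pixel with
#' responsibilities (1, 0) renders exactly as the hard cluster colour.
#'
#' @param cloud A `phasor_cloud`.
#' @param fit A [fit_gmm()] result aligned with `cloud` (canonically ordered
#'   via [order_clusters()] if colour identity matters).
#' @param shape Optional grid shape; defaults to the cloud's.
#' @return A `rendered_image`.
#' @export
render_probability_blend <- function(cloud, fit, shape = NULL) {
  stopifnot(inherits(fit, "phasor_gmm"))
  resp <- fit$responsibilities
  if (nrow(resp) != nrow(cloud)) {
    stop("Fit responsibilities do not align with the cloud.", call. = FALSE)
  }
  k <- ncol(resp)
  if (k > nrow(CLUSTER_PALETTE)) {
    stop("Palette too small for this K.", call. = FALSE)
  }
  if (is.null(shape)) shape <- attr(cloud, "shape")
  rgb <- array(0L, dim = c(shape[1], shape[2], 3))
  mix <- resp %*% CLUSTER_PALETTE[seq_len(k), , drop = FALSE]
  for (ch in 1:3) {
    plane <- matrix(GREY_SENTINEL[ch], shape[1], shape[2])
    plane[cbind(cloud$row + 1L, cloud$col + 1L)] <- as.integer(round(mix[, ch]))
    rgb[, , ch] <- plane
  }
  new_rendered_image(rgb, legend = list(
    type = "probability_blend",
    palette = CLUSTER_PALETTE[seq_len(k), , drop = FALSE],
    missing = GREY_SENTINEL))
}

#' Segmentation accuracy against ground truth
#'
#' Fraction of retained (classified) pixels whose label matches the
#' ground truth under the best label permutation, so the metric is invariant
#' to the arbitrary numbering of clusters. Exhaustive over permutations
#' (intended for small K; the default pipelines use K = 2).
#'
#' @param seg A [map_labels_to_image()] result (0 = unclassified, ignored).
#' @param truth Integer matrix of the same shape with ground-truth labels.
#' @return Accuracy in `[0, 1]`.
#' @export
segmentation_accuracy <- function(seg, truth) {
  if (!all(dim(seg) == dim(truth))) {
    stop("Shape mismatch between segmentation and truth.", call. = FALSE)
  }
  keep <- seg > 0
  if (!any(keep)) {
    stop("No retained pixels: accuracy undefined.", call. = FALSE)
  }
  labs <- sort(unique(as.vector(seg[keep])))
  truths <- sort(unique(as.vector(truth[keep])))
  k <- max(length(labs), length(truths))
  if (k > 6) stop("Exhaustive permutation scoring supports K <= 6.",
                  call. = FALSE)
  perms <- all_permutations(truths, k)
  best <- 0
  sv <- as.vector(seg[keep])
  tv <- as.vector(truth[keep])
  for (p in perms) {
    mapped <- p[match(sv, labs)]
    best <- max(best, mean(mapped == tv, na.rm = TRUE))
  }
  best
}

all_permutations <- function(values, k) {
  values <- c(values, rep(NA, max(0, k - length(values))))
  if (k == 1) return(list(values))
  out <- list()
  rec <- function(chosen, remaining) {
    if (length(remaining) == 0) {
      out[[length(out) + 1]] <<- chosen
      return(invisible())
    }
    for (i in seq_along(remaining)) {
      rec(c(chosen, remaining[i]), remaining[-i])
    }
  }
  rec(c(), values)
  out
}

#' Write a rendered image to PNG or TIFF
#'
#' @param img A `rendered_image`.
#' @param path Output path; format chosen by extension (`.png` or
#'   `.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "rendered_image"))
  arr <- img / 255
  class(arr) <- "array"
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(arr, path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(arr, path)
  } else {
    stop("Unsupported image extension (use .png or .tif/.tiff).",
         call. = FALSE)
  }
  invisible(path)
}

#' Write a label mask as single-channel PNG
#'
#' Raw label values (0 = unclassified) stored in an 8-bit grey channel.
#'
#' @param seg A `seg_map`.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_labels_png <- function(seg, path) {
  if (max(seg) > 255) stop("More than 255 labels.", call. = FALSE)
  png::writePNG(matrix(as.integer(seg) / 255, nrow(seg), ncol(seg)), path)
  invisible(path)
}

#' Export a phase-lifetime map
#'
#' `write_tau_map_csv()` writes tidy `row,col,tau_ns` records (missing pixels
#' omitted). `write_tau_map_tiff()` writes a single-channel 32-bit TIFF in a
#' fixed-point encoding: stored sample = `tau_ns / scale_ns` (default scale
#' 100 ns, i.e. ~2e-8 ns quantization), missing pixels stored as the
#' sentinel 0; `read_tau_map_tiff()` inverts the encoding.
#'
#' @param tau_map Numeric lifetime matrix (ns) with `NA` missing marker.
#' @param path Output path.
#' @param scale_ns Full-scale lifetime of the TIFF encoding (default 100).
#' @return `path`, invisibly (`read_tau_map_tiff()`: the lifetime matrix).
#' @export
write_tau_map_csv <- function(tau_map, path) {
  idx <- which(is.finite(tau_map), arr.ind = TRUE)
  df <- data.frame(row = idx[, 1] - 1L, col = idx[, 2] - 1L,
                   tau_ns = tau_map[idx])
  df <- df[order(df$row, df$col), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tau_map_csv
#' @export
write_tau_map_tiff <- function(tau_map, path, scale_ns = 100) {
  m <- tau_map / scale_ns
  if (any(m > 1, na.rm = TRUE)) {
    stop("Lifetimes exceed the TIFF full scale; raise `scale_ns`.",
         call. = FALSE)
  }
  m[!is.finite(m)] <- 0
  tiff::writeTIFF(m, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' @rdname write_tau_map_csv
#' @export
read_tau_map_tiff <- function(path, scale_ns = 100) {
  m <- tiff::readTIFF(path) * scale_ns
  m[m == 0] <- NA_real_
  m
}

#' Display a segmentation map
#'
#' @param object A `seg_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.seg_map <- function(object, ...) {
  df <- tibble::tibble(
    row = as.vector(row(object)) - 1L,
    col = as.vector(col(object)) - 1L,
    cluster = factor(as.vector(object))
  )
  pal <- c("0" = "grey50",
           stats::setNames(grDevices::rgb(CLUSTER_PALETTE[, 1],
                                          CLUSTER_PALETTE[, 2],
                                          CLUSTER_PALETTE[, 3],
                                          maxColorValue = 255),
                           as.character(seq_len(nrow(CLUSTER_PALETTE)))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$cluster)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = pal) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row", fill = "cluster",
                  title = "Cluster segmentation") +
    ggplot2::theme_minimal()
}

#' Display a phase-lifetime map
#'
#' @param tau_map Numeric lifetime matrix in ns.
#' @param t_min_ns,t_max_ns Colour range endpoints (defaults 2.0 and 4.5 ns).
#' @return A ggplot object.
#' @export
plot_tau_map <- function(tau_map, t_min_ns = 2.0, t_max_ns = 4.5) {
  df <- tibble::tibble(
    row = as.vector(row(tau_map)) - 1L,
    col = as.vector(col(tau_map)) - 1L,
    tau_ns = as.vector(tau_map)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$tau_ns)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(
      colours = c("blue", "cyan", "green", "yellow", "red"),
      limits = c(t_min_ns, t_max_ns), oob = scales_squish,
      na.value = "grey50", name = "tau (ns)") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row", title = "Phase-lifetime map") +
    ggplot2::theme_minimal()
}

# clamp out-of-range values into the colour limits (avoids a scales
# dependency in Imports; same behaviour as scales::squish)
scales_squish <- function(x, range = c(0, 1), only.finite = TRUE) {
  force(range)
  finite <- if (only.finite) is.finite(x) else TRUE
  x[finite & x < range[1]] <- range[1]
  x[finite & x > range[2]] <- range[2]
  x
}
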