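# Fitted small interface shared by the map tests.
fitted_interface <- function(shape = c(10L, 10L), boundary = 5L, seed = 1L,
                             noise = "poisson") {
  m <- simulate_interface_map(glue_pop, oil_pop, shape = shape,
                              boundary_col = boundary, config = default_cfg,
                              seed = seed, noise = noise)
  cloud <- compute_phasor_cloud(m)
  fit <- order_clusters(fit_gmm(cloud, k = 2, seed = seed), cloud)
  list(map = m, cloud = cloud, fit = fit, labels = hard_assign(fit))
}

test_that("cluster labels map back to their pixels bijectively", {
  fx <- fitted_interface()
  seg <- map_labels_to_image(fx$cloud, fx$labels)
  expect_equal(dim(seg), c(10, 10))
  expect_equal(sum(seg > 0), nrow(fx$cloud))
  # reciprocity: each phasor owns exactly its source pixel
  expect_equal(seg[cbind(fx$cloud$row + 1, fx$cloud$col + 1)], fx$labels)
  # canonical order: left half (3.7 ns) is cluster 1, right half cluster 2
  expect_true(all(seg[, 1:5] == 1))
  expect_true(all(seg[, 6:10] == 2))

  dup <- fx$cloud
  dup$col[2] <- dup$col[1]
  dup$row[2] <- dup$row[1]
  expect_error(map_labels_to_image(dup, fx$labels), "reciprocity|Duplicate")
  expect_error(map_labels_to_image(fx$cloud, fx$labels[-1]), "align")
})

test_that("sub-threshold pixels stay unclassified", {
  ladder <- simulate_peak_ladder(c(50L, 500L, 500L, 500L), default_cfg)
  cloud <- compute_phasor_cloud(ladder, threshold = 100)
  seg <- map_labels_to_image(cloud, rep(1L, nrow(cloud)))
  expect_equal(as.vector(seg), c(0L, 1L, 1L, 1L))
})

test_that("lifetime rendering hits the documented colour endpoints", {
  tm <- matrix(c(2.0, 4.5, NA, 3.25), 2, 2)
  img <- render_tau_map(tm)
  expect_equal(img[1, 1, ], c(0L, 0L, 255L))    # 2.0 ns -> pure blue
  expect_equal(img[2, 1, ], c(255L, 0L, 0L))    # 4.5 ns -> pure red
  expect_equal(img[1, 2, ], c(128L, 128L, 128L)) # missing -> grey
  # clipping at the ends
  img2 <- render_tau_map(matrix(c(0.1, 99), 1, 2))
  expect_equal(img2[1, 1, ], c(0L, 0L, 255L))
  expect_equal(img2[1, 2, ], c(255L, 0L, 0L))
  expect_error(render_tau_map(tm, 4.5, 2.0), "below")
  leg <- attr(img, "legend")
  expect_equal(c(leg$t_min_ns, leg$t_max_ns), c(2.0, 4.5))
})

test_that("cluster rendering uses red, green and grey", {
  seg <- structure(matrix(c(1L, 2L, 0L, 1L), 2, 2),
                   class = c("seg_map", "matrix", "array"))
  img <- render_cluster_map(seg)
  expect_equal(img[1, 1, ], c(255L, 0L, 0L))
  expect_equal(img[2, 1, ], c(0L, 255L, 0L))
  expect_equal(img[1, 2, ], c(128L, 128L, 128L))
  cols <- unique(apply(img, c(1, 2), paste, collapse = ","))
  expect_length(unique(as.vector(cols)), 3)

  all_grey <- structure(matrix(0L, 3, 3),
                        class = c("seg_map", "matrix", "array"))
  imgg <- render_cluster_map(all_grey)
  expect_true(all(imgg == 128L))

  too_many <- structure(matrix(1:9, 3, 3),
                        class = c("seg_map", "matrix", "array"))
  expect_error(render_cluster_map(too_many), "Palette")
})

test_that("probability blending interpolates the cluster palette", {
  fx <- fitted_interface(noise = "none")
  # noiseless fit: responsibilities are effectively 0/1
  blend <- render_probability_blend(fx$cloud, fx$fit)
  hard <- render_cluster_map(map_labels_to_image(fx$cloud, fx$labels))
  certain <- apply(fx$fit$responsibilities, 1, max) >= 0.999
  idx <- cbind(fx$cloud$row + 1, fx$cloud$col + 1)
  for (ch in 1:3) {
    expect_equal(blend[, , ch][idx][certain], hard[, , ch][idx][certain])
  }

  # synthetic half-and-half responsibilities give the channel-wise average
  fake <- structure(list(responsibilities = matrix(0.5, 1, 2),
                         params = list(k = 2L)),
                    class = "phasor_gmm")
  one_px <- fx$cloud[1, ]
  attr(one_px, "shape") <- c(1L, 1L)
  one_px$row <- 0L
  one_px$col <- 0L
  img <- render_probability_blend(one_px, fake, shape = c(1, 1))
  expect_equal(as.vector(img[1, 1, ]), c(128L, 128L, 0L))
})

test_that("rendering is a pure function of its inputs", {
  fx <- fitted_interface(seed = 3)
  seg <- map_labels_to_image(fx$cloud, fx$labels)
  expect_identical(render_cluster_map(seg), render_cluster_map(seg))
  tm <- tau_phase_map(fx$cloud)
  expect_identical(render_tau_map(tm), render_tau_map(tm))
})

test_that("segmentation accuracy is permutation-invariant", {
  fx <- fitted_interface()
  seg <- map_labels_to_image(fx$cloud, fx$labels)
  truth <- truth_matrix(fx$map)
  expect_equal(segmentation_accuracy(seg, truth), 1.0)
  flipped <- seg
  flipped[] <- ifelse(seg > 0, 3L - as.vector(seg), 0L)
  class(flipped) <- class(seg)
  expect_equal(segmentation_accuracy(flipped, truth), 1.0)
  expect_error(segmentation_accuracy(seg, truth[1:5, 1:5]), "mismatch")

  none <- seg
  none[] <- 0L
  expect_error(segmentation_accuracy(none, truth), "No retained")
})

test_that("random labels on balanced truth score near one half", {
  truth <- matrix(rep(c(1L, 2L), each = 500), 25, 40)
  labels <- withr::with_seed(77, sample(1:2, 1000, replace = TRUE))
  seg <- structure(matrix(labels, 25, 40),
                   class = c("seg_map", "matrix", "array"))
  acc <- segmentation_accuracy(seg, truth)
  # best-permutation accuracy of coin-flip labels concentrates near 0.5
  expect_lt(abs(acc - 0.5), 0.05)
})

test_that("the default interface simulation segments almost perfectly", {
  fx <- fitted_interface(shape = c(20L, 20L), boundary = 10L, seed = 0)
  seg <- map_labels_to_image(fx$cloud, fx$labels)
  acc <- segmentation_accuracy(seg, truth_matrix(fx$map))
  expect_gte(acc, 0.95)
})

test_that("images write to PNG and TIFF and labels to grey PNG", {
  fx <- fitted_interface(shape = c(6L, 6L), boundary = 3L, seed = 2)
  seg <- map_labels_to_image(fx$cloud, fx$labels)
  img <- render_cluster_map(seg)

  png_path <- withr::local_tempfile(fileext = ".png")
  write_image(img, png_path)
  back <- png::readPNG(png_path)
  expect_equal(round(back * 255), img[, , ], ignore_attr = TRUE)

  tif_path <- withr::local_tempfile(fileext = ".tif")
  write_image(img, tif_path)
  expect_true(file.exists(tif_path))
  expect_error(write_image(img, "x.bmp"), "extension")

  lab_path <- withr::local_tempfile(fileext = ".png")
  write_labels_png(seg, lab_path)
  raw <- round(png::readPNG(lab_path) * 255)
  expect_equal(raw, unclass(seg), ignore_attr = TRUE)

  tm <- tau_phase_map(fx$cloud)
  csv_path <- withr::local_tempfile(fileext = ".csv")
  write_tau_map_csv(tm, csv_path)
  df <- utils::read.csv(csv_path)
  expect_equal(nrow(df), sum(is.finite(tm)))
  expect_named(df, c("row", "col", "tau_ns"))

  ftif <- withr::local_tempfile(fileext = ".tif")
  write_tau_map_tiff(tm, ftif)
  round_trip <- read_tau_map_tiff(ftif)
  expect_equal(round_trip[is.finite(tm)], tm[is.finite(tm)],
               tolerance = 1e-6)
  expect_true(all(is.na(round_trip[!is.finite(tm)])))

  expect_s3_class(ggplot2::autoplot(seg), "ggplot")
  expect_s3_class(plot_tau_map(tm), "ggplot")
})
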