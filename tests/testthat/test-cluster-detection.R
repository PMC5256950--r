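test_that("rolling-ball subtraction removes flat and smooth backgrounds", {
  expect_true(all(rolling_ball_subtract(matrix(13.7, 40, 40), 5) == 0))
  # a single spike survives nearly untouched on a flat background
  img <- matrix(10, 40, 40); img[20, 20] <- 500
  out <- rolling_ball_subtract(img, 5)
  expect_equal(out[20, 20], 490, tolerance = 0.01 * 490)
  # radius larger than the image: background is the global minimum
  img2 <- matrix(c(5, 7, 9, 11), 2, 2)
  expect_equal(rolling_ball_subtract(img2, 50), img2 - 5)
})

test_that("rolling-ball correction recovers detection under a smooth gradient", {
  sim <- simulate_membrane_stack(membrane_sim_params(field_px = 128, seed = 3))
  flat <- sim$stack$data[, , 1]
  grad <- flat + outer(seq(0, 300, length.out = 128), rep(1, 128))
  n_flat <- detect_clusters(flat, pixel_size_nm = 130)$n
  n_grad <- detect_clusters(grad, pixel_size_nm = 130)$n
  expect_lt(abs(n_grad - n_flat) / n_flat, 0.10)
})

test_that("band-pass filter nulls constants, passes spikes, rejects ramps", {
  expect_lt(max(abs(bandpass_subtract(matrix(42, 64, 64), 2, 130))), 1e-9)
  # low-frequency ramp: residual below 1 % of the amplitude away from edges
  ramp <- outer(seq(0, 1000, length.out = 200), rep(1, 200))
  res <- bandpass_subtract(ramp, 2, 130)
  core <- res[60:140, 60:140]
  expect_lt(max(abs(core)), 0.01 * 1000)
  # delta spike attenuated by exactly (1 - peak of the discrete blur kernel)
  img <- matrix(0, 101, 101); img[51, 51] <- 1000
  sigma_px <- 2 * 1000 / 130
  r <- ceiling(3 * sigma_px)
  g <- stats::dnorm(-r:r, sd = sigma_px); g <- g / sum(g)
  expect_equal(bandpass_subtract(img, 2, 130)[51, 51],
               1000 * (1 - max(g)^2), tolerance = 1e-6)
})

test_that("connected-component labelling matches a flood-fill oracle", {
  set.seed(42)
  for (trial in seq_len(1000)) {
    mask <- matrix(stats::runif(256) < 0.4, 16, 16)
    conn <- if (trial %% 2) 8 else 4
    expect_identical(canonical_labels(label_components(mask, conn)),
                     canonical_labels(flood_fill_label(mask, conn)))
  }
})

test_that("thresholding and particle analysis behave at the boundaries", {
  expect_equal(threshold_label(matrix(50, 32, 32), threshold = 80)$n, 0)
  # two disjoint 3x3 blobs
  img <- matrix(0, 20, 20)
  img[3:5, 3:5] <- 100
  img[12:14, 15:17] <- 150
  cs <- threshold_label(img, threshold = 80, min_area = 2)
  expect_equal(cs$n, 2)
  expect_equal(cs$records$area_px, c(9L, 9L))
  expect_equal(sort(cs$records$x_px), c(4 - 0.5, 13 - 0.5))
  # a pixel exactly at the threshold is background (strict inequality)
  expect_equal(threshold_label(matrix(80, 8, 8), threshold = 80)$n, 0)
})

test_that("spatially uncorrelated noise leaves only single pixels, removed by min_area", {
  # homogeneously distributed marker: suprathreshold pixels are isolated
  set.seed(7)
  frame <- matrix(stats::rnorm(128 * 128, mean = 0, sd = 22), 128, 128)
  cs1 <- threshold_label(frame, threshold = 80, min_area = 1)
  cs2 <- threshold_label(frame, threshold = 80, min_area = 2)
  expect_gt(cs1$n, 0)                       # noise pixels do cross threshold
  expect_true(all(cs1$records$area_px == 1))
  expect_equal(cs2$n, 0)                    # all removed as single pixels
})

test_that("raising the threshold shrinks the mask and nests the clusters", {
  # the suprathreshold mask is monotone decreasing in the threshold, and
  # every cluster at a higher threshold lies inside one cluster of the lower
  # threshold (counts alone are not monotone: one particle may split in two)
  sim <- simulate_membrane_stack(membrane_sim_params(field_px = 96, seed = 9))
  bp <- bandpass_subtract(rolling_ball_subtract(sim$stack$data[, , 1], 50),
                          2, 130)
  prev <- NULL
  for (thr in seq(40, 280, by = 60)) {
    cs <- threshold_label(bp, threshold = thr)
    mask <- cs$labels > 0
    if (!is.null(prev)) {
      expect_lte(sum(mask), sum(prev))
      expect_true(all(prev[mask]))   # nesting: high-threshold mask inside low
    }
    prev <- mask
  }
})

test_that("translating the image translates all centroids", {
  sim <- simulate_membrane_stack(membrane_sim_params(field_px = 96, seed = 14))
  img <- sim$stack$data[, , 1]
  shifted <- matrix(stats::median(img), 96, 96)
  shifted[11:96, 6:96] <- img[1:86, 1:91]
  a <- threshold_label(bandpass_subtract(img, 2, 130), threshold = 80)
  b <- threshold_label(bandpass_subtract(shifted, 2, 130), threshold = 80)
  # match interior clusters (avoid those created/destroyed at the borders)
  interior <- a$records$x_px > 12 & a$records$x_px < 74 &
    a$records$y_px > 12 & a$records$y_px < 79
  ra <- a$records[interior, ]
  for (i in seq_len(nrow(ra))) {
    d <- sqrt((b$records$x_px - ra$x_px[i] - 10)^2 +
              (b$records$y_px - ra$y_px[i] - 5)^2)
    expect_lt(min(d), 1e-6)
  }
})

test_that("ROI polygons restrict the analysed area", {
  img <- matrix(0, 30, 30)
  img[5:6, 5:6] <- 100       # inside ROI
  img[25:26, 25:26] <- 100   # outside ROI
  roi <- cbind(c(1, 15, 15, 1), c(1, 1, 15, 15))
  cs <- threshold_label(img, threshold = 80, roi = roi, pixel_size_nm = 130)
  expect_equal(cs$n, 1)
  expect_equal(cs$roi_area_um2, 14 * 14 * 0.13^2, tolerance = 0.02)
  # empty ROI gives an empty, zero-density summary
  roi0 <- matrix(FALSE, 30, 30)
  cs0 <- threshold_label(img, threshold = 80, roi = roi0)
  expect_equal(cs0$n, 0)
})

test_that("cluster summaries reproduce the density and diameter arithmetic", {
  img <- matrix(0, 30, 30)
  centers <- expand.grid(x = c(5, 15, 25), y = c(5, 15, 25))
  for (i in seq_len(9)) img[centers$x[i] + (0:1), centers$y[i] + (0:1)] <- 100
  cs <- threshold_label(img, threshold = 80, pixel_size_nm = 130)
  expect_equal(cs$n, 9)
  summ <- summarize_clusters(cs, roi_area_um2 = 9)
  expect_equal(summ$density_um2, 1.0)
  # a 5-pixel cluster at 130 nm pixels: 0.0845 um^2, diameter ~328 nm,
  # inside the 300-500 nm band reported for receptor nanoclusters
  area5 <- 5 * 0.13^2
  expect_equal(area5, 0.0845)
  diam5 <- 2 * sqrt(area5 / pi) * 1000
  expect_equal(diam5, 328, tolerance = 1e-2)
  expect_true(diam5 > 300 && diam5 < 500)
})

test_that("receptors per cluster reproduces the published ratios", {
  expect_equal(receptors_per_cluster(12, 2)$receptors, 6L)
  expect_equal(receptors_per_cluster(5, 3)$receptors, 2L)
  expect_equal(receptors_per_cluster(0, 2)$receptors, 0L)
  r <- receptors_per_cluster(12, 2, receptor_sem = 1, cluster_sem = 0.4)
  expect_equal(r$sem, 6 * sqrt((1 / 12)^2 + (0.4 / 2)^2), tolerance = 1e-12)
  expect_warning(r0 <- receptors_per_cluster(12, 0), "undefined")
  expect_true(is.na(r0$receptors))
})

test_that("the detector is unbiased for resolvable clusters across densities", {
  # clusters closer than ~2x the PSF FWHM (3.5 px at 130 nm) merge into one
  # diffraction-limited particle; against that resolvable ground truth the
  # pipeline count is unbiased within 20 % from sparse to crowded fields
  for (dens in c(0.25, 0.5, 1.0, 2.0)) {
    ratio <- vapply(1:8, function(s) {
      sim <- simulate_membrane_stack(membrane_sim_params(
        field_px = 128, density_um2 = dens, seed = 1000 * dens + s))
      detect_clusters(sim$stack)$n / resolvable_count(sim$truth$centers, 3.5)
    }, numeric(1))
    expect_gt(mean(ratio), 0.8)
    expect_lt(mean(ratio), 1.2)
  }
})

test_that("ROI bleach traces average the 5x5 window per frame", {
  data <- array(rep(1:4, each = 100), dim = c(10, 10, 4))
  st <- frame_stack(data, 130)
  expect_equal(roi_bleach_trace(st, c(5, 5)), 1:4)
  expect_error(roi_bleach_trace(st, c(1, 5)), "clipped")
  # a simulated 2-fluorophore staircase shows its plateaus in the ROI trace
  sim <- simulate_bleach_trace(bleach_sim_params(n_fluor = 2, noise_sd = 0,
                                                 frames = 60, seed = 3))
  stack <- frame_stack(array(rep(sim$trace, each = 49), dim = c(7, 7, 60)), 130)
  tr <- roi_bleach_trace(stack, c(4, 4))
  expect_length(tr, 60)
  expect_equal(length(unique(round(tr, 6))), 3)   # 2, 1, 0 fluorophores
})
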