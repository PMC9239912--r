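make_toy_bold <- function(d = c(6, 6, 4), T_ = 20, seed = 31) {
  set.seed(seed)
  g <- voxel_grid(d)
  bold_series(array(stats::rnorm(prod(d) * T_, 100, 5), c(d, T_)), g)
}

test_that("extract_roi_timeseries is the per-ROI voxel mean", {
  d <- c(4, 4, 4)
  g <- voxel_grid(d)
  arr <- array(0, c(d, 2))
  lab <- array(0L, d); lab[1, 1, 1] <- 1L; lab[2, 1, 1] <- 1L
  arr[1, 1, 1, ] <- c(1, 2); arr[2, 1, 1, ] <- c(3, 4)
  tab <- parcellation_table(1:2, c("a", "b"))
  ts <- extract_roi_timeseries(bold_series(arr, g), label_volume(lab, g), tab)
  expect_equal(unname(ts$values[, 1]), c(2, 3))
  expect_false(ts$valid[2])                      # absent ROI -> invalid
  expect_true(all(is.na(ts$values[, 2])))
})

test_that("extract_roi_timeseries matches a naive masked-mean oracle", {
  bold <- make_toy_bold(c(10, 10, 10), T_ = 20)
  set.seed(32)
  lab <- array(sample(0:5, 1000, TRUE), c(10, 10, 10))
  tab <- parcellation_table(1:5, paste0("r", 1:5))
  lv <- label_volume(lab, bold$grid)
  ts <- extract_roi_timeseries(bold, lv, tab)
  for (k in 1:5) {
    sel <- which(lab == k)
    expected <- sapply(1:20, function(t) {
      vol <- bold$data[, , , t]
      mean(vol[sel])
    })
    expect_equal(unname(ts$values[, k]), expected, tolerance = 1e-12)
  }
})

test_that("extract_roi_timeseries is permutation-equivariant in ROI order", {
  bold <- make_toy_bold()
  set.seed(33)
  lab <- array(sample(0:4, prod(c(6, 6, 4)), TRUE), c(6, 6, 4))
  lv <- label_volume(lab, bold$grid)
  tab <- parcellation_table(1:4, paste0("r", 1:4))
  perm <- c(3L, 1L, 4L, 2L)
  tab_p <- parcellation_table(tab$index[perm], tab$name[perm])
  a <- extract_roi_timeseries(bold, lv, tab)
  b <- extract_roi_timeseries(bold, lv, tab_p)
  expect_equal(unname(b$values), unname(a$values[, perm]))
})

test_that("pearson_fc reproduces the textbook correlation", {
  d <- c(2, 1, 1)
  g <- voxel_grid(d)
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 5)
  arr <- array(0, c(d, 4))
  arr[1, 1, 1, ] <- x; arr[2, 1, 1, ] <- y
  lab <- array(1:2, d)
  ts <- extract_roi_timeseries(bold_series(arr, g), label_volume(lab, g),
                               parcellation_table(1:2, c("a", "b")))
  fc <- pearson_fc(ts)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(fc$values[1, 2], r_oracle, tolerance = 1e-12)
  expect_equal(unname(diag(fc$values)), c(1, 1))

  # anticorrelation: a column versus its negation around the mean
  arr[2, 1, 1, ] <- -x
  ts2 <- extract_roi_timeseries(bold_series(arr, g), label_volume(lab, g),
                                parcellation_table(1:2, c("a", "b")))
  expect_equal(pearson_fc(ts2)$values[1, 2], -1)
})

test_that("pearson_fc marks invalid and constant ROIs missing, keeps bounds", {
  d <- c(3, 1, 1)
  g <- voxel_grid(d)
  arr <- array(0, c(d, 5))
  arr[1, 1, 1, ] <- stats::rnorm(5)
  arr[2, 1, 1, ] <- 7                     # constant -> zero variance
  lab <- array(c(1L, 2L, 0L), d)
  tab <- parcellation_table(1:3, c("a", "b", "empty"))
  ts <- extract_roi_timeseries(bold_series(arr, g), label_volume(lab, g), tab)
  fc <- pearson_fc(ts)
  expect_true(all(is.na(fc$values[2, ])))
  expect_true(all(is.na(fc$values[, 3])))
  expect_equal(fc$values[1, 1], 1)
  expect_identical(fc$values, t(fc$values))
  expect_true(all(abs(fc$values[is.finite(fc$values)]) <= 1))

  short <- ts; short$values <- ts$values[1:2, , drop = FALSE]
  expect_error(pearson_fc(short), "3 timepoints")
})

test_that("tsnr is mean over sample SD with zero-variance exclusion", {
  d <- c(2, 1, 1)
  g <- voxel_grid(d)
  series <- c(95, 100, 105, 100, 100)     # mean 100
  arr <- array(0, c(d, 5))
  arr[1, 1, 1, ] <- series
  arr[2, 1, 1, ] <- 50                    # constant
  mask <- binary_mask(array(TRUE, d), g)
  out <- tsnr(bold_series(arr, g), mask)
  expect_equal(out$map[1, 1, 1], mean(series) / stats::sd(series))
  expect_true(is.na(out$map[2, 1, 1]))
  expect_equal(unname(out$summary["n_voxels"]), 1)

  empty <- binary_mask(array(FALSE, d), g)
  expect_error(tsnr(bold_series(arr, g), empty), "empty")
})

test_that("tsnr scale and shift behave analytically", {
  bold <- make_toy_bold(c(5, 5, 5), T_ = 30, seed = 34)
  mask <- binary_mask(array(TRUE, c(5, 5, 5)), bold$grid)
  base <- tsnr(bold, mask)
  scaled <- bold_series(bold$data * 3.7, bold$grid)
  expect_equal(tsnr(scaled, mask)$map, base$map, tolerance = 1e-12)

  shifted <- bold_series(bold$data + 10, bold$grid)
  flat <- matrix(bold$data, ncol = 30)
  sdv <- apply(flat, 1L, stats::sd)
  expect_equal(as.vector(tsnr(shifted, mask)$map),
               (rowMeans(flat) + 10) / sdv, tolerance = 1e-12)
})

test_that("framewise displacement follows the arc-length formula", {
  zero <- matrix(0, 10, 6)
  expect_equal(framewise_displacement(zero)$fd, rep(0, 10))

  m <- matrix(0, 5, 6)
  m[3:5, 4] <- 1                          # 1 mm x-translation step at frame 3
  fd <- framewise_displacement(m)
  expect_equal(fd$fd, c(0, 0, 1, 0, 0))
  expect_equal(fd$max, 1)

  r <- matrix(0, 4, 6)
  r[2:4, 1] <- 0.01                       # 0.01 rad step, radius 50 mm
  expect_equal(framewise_displacement(r)$fd[2], 0.5)
  expect_equal(framewise_displacement(r, head_radius_mm = 80)$fd[2], 0.8)

  expect_error(framewise_displacement(matrix(0, 5, 4)), "6")
})

test_that("motion parameter files round-trip through the FSL layout", {
  m <- matrix(stats::rnorm(36, sd = 0.01), 6, 6)
  p <- withr::local_tempfile(fileext = ".par")
  write(t(m), p, ncolumns = 6)
  back <- read_motion_params(p)
  expect_equal(unname(back), m, tolerance = 1e-6)
})

test_that("fc_summaries matches a flatten-and-compute moment oracle", {
  # constant off-diagonal
  v <- matrix(0.3, 4, 4); diag(v) <- 1
  fc <- structure(list(values = v, roi_indices = 1:4, valid = rep(TRUE, 4)),
                  class = "fc_matrix")
  s <- fc_summaries(fc)
  expect_equal(unname(s["fc_mean"]), 0.3)
  expect_equal(unname(s["fc_range"]), 0)
  expect_equal(unname(s["fc_prop_positive"]), 1)

  # symmetric two-point distribution
  v2 <- matrix(0, 3, 3); diag(v2) <- 1
  v2[1, 2] <- v2[2, 1] <- -0.2; v2[1, 3] <- v2[3, 1] <- 0.2
  fc2 <- structure(list(values = v2, roi_indices = 1:3,
                        valid = rep(TRUE, 3)), class = "fc_matrix")
  s2 <- fc_summaries(fc2)
  expect_equal(unname(s2["fc_mean"]), 0)
  expect_equal(unname(s2["fc_skewness"]), 0)

  # random symmetric matrix against direct moments
  set.seed(35)
  N <- 12
  r <- matrix(stats::runif(N * N, -1, 1), N, N)
  r <- (r + t(r)) / 2; diag(r) <- 1
  fc3 <- structure(list(values = r, roi_indices = 1:N,
                        valid = rep(TRUE, N)), class = "fc_matrix")
  s3 <- fc_summaries(fc3)
  x <- r[upper.tri(r)]
  m2 <- mean((x - mean(x))^2)
  expect_equal(unname(s3["fc_mean"]), mean(x), tolerance = 1e-12)
  expect_equal(unname(s3["fc_sd"]), stats::sd(x), tolerance = 1e-12)
  expect_equal(unname(s3["fc_skewness"]),
               mean((x - mean(x))^3) / m2^1.5, tolerance = 1e-12)
  expect_equal(unname(s3["fc_kurtosis"]),
               mean((x - mean(x))^4) / m2^2 - 3, tolerance = 1e-12)
  expect_equal(unname(s3["fc_prop_gt_0.5"]), mean(abs(x) > 0.5))
})
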