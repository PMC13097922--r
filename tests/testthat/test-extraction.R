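test_that("3x3 median filter matches hand-computed medians", {
  # exhaustive 3x3 case: center is the median of 1..9
  m <- matrix(1:9, 3, 3, byrow = TRUE)
  expect_equal(median_filter_2d(m)[2, 2], 5)
  # constant grid unchanged
  cm <- matrix(7, 5, 6)
  expect_equal(median_filter_2d(cm), cm)
  # single impulse in a zero background removed
  z <- matrix(0, 5, 5); z[3, 3] <- 100
  expect_equal(median_filter_2d(z)[3, 3], 0)
  expect_true(all(median_filter_2d(z) == 0))
  # too small for the kernel
  expect_error(median_filter_2d(matrix(1:4, 2, 2)), "3x3")
})

test_that("median filter border policies behave as documented", {
  m <- matrix(10, 3, 3)
  # replicate: corners see only the constant
  expect_equal(median_filter_2d(m, "replicate"), m)
  # zero padding: corner neighborhood has 5 zeros out of 9 -> median 0
  expect_equal(median_filter_2d(m, "zero")[1, 1], 0)
  expect_equal(median_filter_2d(m, "zero")[2, 2], 10)
})

test_that("median filter is idempotent on piecewise-constant regions", {
  m <- matrix(1, 9, 9); m[1:4, ] <- 5
  f1 <- median_filter_2d(m)
  expect_equal(median_filter_2d(f1), f1)
})

test_that("SIR computation follows (Tag - Control) / M0 with derived M0", {
  ti <- c(500, 1500, 3000)
  ctrl <- lapply(1:3, function(k) matrix(200, 6, 6))
  # tag = 1.5 * control at every TI
  tag <- lapply(1:3, function(k) matrix(300, 6, 6))
  s <- image_series(ti, tag, ctrl, m0 = "derived")
  sir <- compute_sir_series(s, apply_filter = FALSE)
  expect_equal(sir$sir[[1]], matrix(0.5, 6, 6))
  # tag == control -> SIR == 0
  s0 <- image_series(ti, ctrl, ctrl, m0 = "derived")
  sir0 <- compute_sir_series(s0, apply_filter = FALSE)
  expect_true(all(vapply(sir0$sir, function(x) all(x == 0), logical(1))))
})

test_that("SIR is invariant under a common positive intensity scaling", {
  s1 <- tiny_series()
  s2 <- s1
  s2$tag <- lapply(s1$tag, function(x) 3.7 * x)
  s2$control <- lapply(s1$control, function(x) 3.7 * x)
  a <- compute_sir_series(s1, apply_filter = TRUE)
  b <- compute_sir_series(s2, apply_filter = TRUE)
  for (k in seq_along(a$sir)) expect_equal(a$sir[[k]], b$sir[[k]])
})

test_that("low-M0 voxels are masked as missing", {
  ti <- c(500, 3000)
  ctrl <- lapply(1:2, function(k) {
    m <- matrix(500, 6, 6); m[1, 1] <- 0.1; m  # near-zero background voxel
  })
  tag <- lapply(ctrl, function(x) x * 1.2)
  s <- image_series(ti, tag, ctrl, m0 = "derived")
  sir <- compute_sir_series(s, apply_filter = FALSE)
  expect_true(is.na(sir$sir[[1]][1, 1]))
  expect_equal(sir$n_floor, 1)
})

test_that("ROI curve extraction averages member voxels", {
  ti <- c(500, 1500, 3000)
  ctrl <- lapply(1:3, function(k) matrix(100, 4, 4))
  tag <- lapply(1:3, function(k) {
    m <- matrix(100, 4, 4); m[1, 1] <- 100 + 10 * k; m[1, 2] <- 100 + 30 * k; m
  })
  s <- image_series(ti, tag, ctrl, m0 = "derived")
  sir <- compute_sir_series(s, apply_filter = FALSE)
  # single-voxel mask equals that voxel's trace
  m1 <- matrix(FALSE, 4, 4); m1[1, 1] <- TRUE
  c1 <- extract_roi_curve(sir, roi_mask(m1, "one"))
  expect_equal(c1$sir, (10 * (1:3)) / 100)
  expect_equal(c1$n_voxels, 1L)
  expect_equal(c1$label, "one")
  # two-voxel mask averages
  m2 <- m1; m2[1, 2] <- TRUE
  c2 <- extract_roi_curve(sir, roi_mask(m2, "two"))
  expect_equal(c2$sir, (10 * (1:3) + 30 * (1:3)) / 2 / 100)
  # ROI mean lies within the member-voxel envelope at every TI
  expect_true(all(c2$sir >= pmin(c1$sir, 30 * (1:3) / 100)))
  expect_true(all(c2$sir <= pmax(c1$sir, 30 * (1:3) / 100)))
})

test_that("an effectively empty ROI raises an error naming the TI", {
  ti <- c(500, 3000)
  ctrl <- lapply(1:2, function(k) {
    m <- matrix(500, 4, 4); m[2, 2] <- 0; m  # voxel under the M0 floor
  })
  s <- image_series(ti, ctrl, ctrl, m0 = "derived")
  sir <- compute_sir_series(s, apply_filter = FALSE)
  m <- matrix(FALSE, 4, 4); m[2, 2] <- TRUE
  expect_error(extract_roi_curve(sir, roi_mask(m, "bad")), "TI = 500")
})

test_that("mask and series dimension mismatches are rejected", {
  s <- tiny_series()
  sir <- compute_sir_series(s, apply_filter = FALSE)
  expect_error(extract_roi_curve(sir, roi_mask(matrix(TRUE, 5, 5))),
               "dimensions")
  expect_error(roi_mask(matrix(FALSE, 3, 3)), "no voxels")
})

test_that("NIfTI series round-trips through sidecar read/write", {
  s <- tiny_series(ti = c(600, 1800, 2900))
  dir <- file.path(tempdir(), "series_rt")
  sidecar <- write_image_series(s, dir)
  s2 <- read_image_series(sidecar)
  expect_equal(s2$ti, s$ti)
  for (k in 1:3) {
    expect_equal(as.array(s2$tag[[k]]), as.array(s$tag[[k]]),
                 ignore_attr = TRUE)
    expect_equal(as.array(s2$control[[k]]), as.array(s$control[[k]]),
                 ignore_attr = TRUE)
  }
  expect_identical(s2$m0, "derived")
  # mask round-trip
  m <- matrix(FALSE, 8, 8); m[3:5, 3:5] <- TRUE
  mp <- file.path(dir, "mask.nii.gz")
  write_roi_mask(roi_mask(m, "sq"), mp)
  m2 <- read_roi_mask(mp, label = "sq")
  expect_equal(array(m, dim(m)), m2$mask, ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})

test_that("3-D volumes are median-filtered slice by slice", {
  a <- array(0, c(5, 5, 2))
  a[3, 3, 1] <- 50  # impulse in slice 1 only
  ti <- c(500, 3000)
  ctrl <- list(array(100, c(5, 5, 2)), array(100, c(5, 5, 2)))
  tag <- list(a + 100, array(100, c(5, 5, 2)))
  s <- image_series(ti, tag, ctrl, m0 = "derived")
  sir <- compute_sir_series(s, apply_filter = TRUE)
  expect_equal(sir$sir[[1]][3, 3, 1], 0)  # impulse removed within its slice
})
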