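test_that("lowpass_filter has unit DC gain and Butterworth attenuation", {
  expect_equal(lowpass_filter(rep(3.7, 500), 50, 10, 4), rep(3.7, 500),
               tolerance = 1e-12)
  t <- (0:1499) / 50
  mid <- 300:1200                          # away from edge transients
  hi <- lowpass_filter(sin(2 * pi * 10 * t), 50, 5, 4)   # 2x cutoff
  expect_lt(max(abs(hi[mid])), 0.01)
  lo <- lowpass_filter(sin(2 * pi * 0.5 * t), 50, 5, 4)  # 0.1x cutoff
  expect_gt(max(abs(lo[mid])), 0.99)
  expect_length(hi, 1500L)
  expect_error(lowpass_filter(t, 50, 25, 4), "Nyquist")
  expect_error(lowpass_filter(t, 50, 30, 4), "Nyquist")
})

test_that("remove_outliers is a Hampel filter", {
  expect_equal(remove_outliers(c(1, 1, 1, 50, 1, 1, 1), 5, 3),
               rep(1, 7))
  expect_equal(remove_outliers(rep(2.5, 20), 5, 3), rep(2.5, 20))
  x <- sin(2 * pi * (0:199) / 50)          # clean sinusoid: nothing flagged
  expect_identical(remove_outliers(x, 5, 3), x)
  expect_error(remove_outliers(1:5, 4, 3), "odd")
  expect_error(remove_outliers(1:5, 7, 3), "larger")
})

test_that("compute_svm1 is the root-sum-of-squares", {
  expect_equal(compute_svm1(3, 4, 0), 5)
  expect_equal(compute_svm1(0, 0, 0), 0)
  expect_equal(compute_svm1(c(1, 2), c(2, 3), c(2, 6)), c(3, 7))
  expect_error(compute_svm1(1:3, 1:2, 1:3), "mismatch")
})

test_that("detect_salient_points finds separated strict minima", {
  expect_equal(detect_salient_points(c(5, 3, 4, 2, 6, 1, 5), 1),
               c(2L, 4L, 6L))
  expect_equal(detect_salient_points(1:10, 1), integer(0))
  # depth 1 at index 2 beats depth 2 at index 4 (2 apart < 3)
  expect_equal(detect_salient_points(c(5, 1, 4, 2, 6), 3), 2L)
  expect_error(detect_salient_points(1:5, 0), "min_separation")
})

test_that("detect_salient_points matches the greedy-by-depth oracle", {
  withr::with_seed(42, {
    for (i in 1:25) {
      x <- stats::rnorm(60)
      sep <- sample(1:8, 1)
      got <- detect_salient_points(x, sep)
      expect_identical(got, brute_salient(x, sep))
      if (length(got) > 1) expect_true(all(diff(got) >= sep))
      # every reported point is a strict local minimum
      expect_true(all(x[got - 1] > x[got] & x[got] < x[got + 1]))
    }
  })
})

test_that("segment_cycles pairs consecutive salient points with a gate", {
  cfg <- segmentation_config(min_cycle_s = 0.02, max_cycle_s = 100,
                             resample_len = 8)
  segs <- segment_cycles(c(3L, 8L, 13L), fs = 1, cfg)
  expect_equal(unname(segs), cbind(c(3L, 8L), c(8L, 13L)))
  # short candidate dropped by the duration gate
  cfg2 <- segmentation_config(min_cycle_s = 4, max_cycle_s = 10,
                              resample_len = 8)
  segs2 <- segment_cycles(c(2L, 3L, 12L), fs = 1, cfg2)
  expect_equal(unname(segs2), cbind(3L, 12L))
  expect_equal(nrow(segment_cycles(5L, fs = 1, cfg)), 0L)
  expect_error(segment_cycles(c(5L, 2L), fs = 1, cfg), "ascending")
})

test_that("ncc is a normalized, affine-invariant similarity", {
  x <- c(0.3, 1.2, -0.5, 2.2)
  expect_equal(ncc(x, x), 1)
  expect_equal(ncc(x, -x), -1)
  expect_equal(ncc(c(1, 2, 3), c(3, 5, 7)), 1)
  expect_error(ncc(rep(1, 4), x), "constant")
  expect_error(ncc(x, c(1, 2)), "mismatch")
})

test_that("resample_cycle interpolates linearly and keeps endpoints", {
  ramp <- matrix(0:4, nrow = 1)
  expect_equal(resample_cycle(ramp, 9)[1, ], seq(0, 4, by = 0.5))
  const <- matrix(rep(2, 6), nrow = 1)
  expect_equal(resample_cycle(const, 11)[1, ], rep(2, 11))
  m <- rbind(sin(1:7), cos(1:7), 1:7)
  expect_equal(resample_cycle(m, 7), m, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(resample_cycle(matrix(1), 5), "2 columns")
})

test_that("validate_cycles keeps template-like candidates, drops noise", {
  pat <- 5 + sin(2 * pi * (0:19) / 20)
  svm1 <- rep(pat, 5)
  svm1[61:80] <- 5 + withr::with_seed(11, stats::rnorm(20))  # odd one out
  axes <- rbind(svm1, svm1 * 0.5, svm1 * 0.2)
  segs <- cbind(start = seq(1, 81, by = 20), end = seq(21, 101, by = 20))
  cfg <- segmentation_config(min_cycle_s = 0.1, max_cycle_s = 10,
                             ncc_threshold = 0.99, resample_len = 32)
  got <- validate_cycles(axes, svm1, segs, fs = 20, cfg)
  expect_length(got, 4L)                   # noise candidate dropped
  expect_true(all(vapply(got, function(c) c$ncc_score, numeric(1)) >= 0.99))
  expect_true(all(vapply(got, function(c) identical(dim(c$window),
                                                    c(3L, 32L)),
                         logical(1))))
  # single candidate is its own template
  one <- validate_cycles(axes, svm1, segs[1, , drop = FALSE], 20, cfg)
  expect_length(one, 1L)
  expect_equal(one[[1]]$ncc_score, 1)
})

test_that("pipeline cycles are disjoint, validated, and countable", {
  p <- gait_class_params("sober", step_rate_hz = 1.9, stride_time_cv = 0,
                         noise_sd = 0)
  r <- generate_recording(p, duration_s = 20, fs = 50, seed = 5)
  cfg <- segmentation_config(resample_len = 64)
  cycles <- preprocess_recording(r, cfg)
  expect_gt(length(cycles), 0L)
  # non-overlap: half-open [start, end) intervals in source indices
  ord <- order(vapply(cycles, function(c) c$start_idx, numeric(1)))
  s <- vapply(cycles[ord], function(c) c$start_idx, numeric(1))
  e <- vapply(cycles[ord], function(c) c$end_idx, numeric(1))
  expect_true(all(e[-length(e)] <= s[-1]))
  expect_true(all(vapply(cycles, function(c)
    c$ncc_score >= cfg$ncc_threshold, logical(1))))
  expect_true(all(vapply(cycles, function(c)
    identical(dim(c$window), c(3L, 64L)), logical(1))))
  # the 3-harmonic waveform leaves one dominant SVM1 minimum per stride,
  # so cycles are strides: floor(duration * stride_rate) - 1, within 1
  expect_lte(abs(length(cycles) - (floor(20 * 1.9 / 2) - 1)), 1)
})

test_that("filter + outlier chain is stable on clean in-band input", {
  # a second pass can only differ through residual in-band attenuation and
  # filtfilt edge transients; see the methods vignette for the bound
  p <- gait_class_params("sober", step_rate_hz = 1.9, stride_time_cv = 0,
                         noise_sd = 0)
  r <- generate_recording(p, duration_s = 10, fs = 50, seed = 1)
  chain <- function(x) remove_outliers(lowpass_filter(x, 50, 10, 4), 11, 3)
  for (ch in list(r$ax, r$ay, r$az)) {
    once <- chain(ch)
    expect_lt(max(abs(chain(once) - once)), 5e-3)
  }
})
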