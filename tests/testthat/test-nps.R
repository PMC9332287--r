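test_that("ROI extraction yields one raw patch per (spec, slice) pair", {
  vol <- ct_volume(array(rep(1:4, each = 64 * 64), c(64, 64, 4)), c(1, 1))
  specs <- list(
    roi_spec(c(16, 16), 8, 1:2),
    roi_spec(c(32, 32), 8, 1:2),
    roi_spec(c(48, 48), 8, 1:2)
  )
  patches <- extract_rois(vol, specs)
  expect_length(patches, 6)
  expect_true(all(vapply(patches, function(p) all(dim(p) == 8), logical(1))))
  # three ROIs over five slices (the uniform-organ protocol) -> 15 patches
  vol5 <- ct_volume(array(0, c(64, 64, 5)), c(1, 1))
  specs5 <- lapply(specs, function(s) roi_spec(s$center, s$size, 1:5))
  expect_length(extract_rois(vol5, specs5), 15)
  # constant volume -> constant patch
  expect_equal(extract_rois(vol5, specs5[1])[[1]], matrix(0, 8, 8))
  # one pixel beyond the border is an error naming spec and slice
  err <- expect_error(
    extract_rois(vol5, roi_spec(c(61, 32), 8, 2:3)),
    "out of bounds"
  )
  expect_match(conditionMessage(err), "slice 2")
})

test_that("polynomial detrending removes trends and keeps noise", {
  expect_equal(detrend(matrix(55, 16, 16)), matrix(0, 16, 16))
  ramp <- outer(seq_len(16), seq_len(16), function(i, j) 3 * i - 2 * j + 7)
  expect_equal(detrend(ramp, order = 1), matrix(0, 16, 16))
  expect_equal(detrend(ramp, order = 2), matrix(0, 16, 16))
  quad <- outer(seq_len(16), seq_len(16), function(i, j) (i - 8)^2 + i * j)
  expect_equal(detrend(quad, order = 2), matrix(0, 16, 16),
               tolerance = 1e-10)
  # ramp + noise: residual variance approximates the noise variance
  set.seed(33)
  sigma <- 12
  vars <- replicate(40, {
    noise <- matrix(rnorm(32 * 32, sd = sigma), 32, 32)
    stats::var(as.vector(detrend(ramp32 <- outer(1:32, 1:32, `+`) + noise)))
  })
  expect_equal(mean(vars), sigma^2, tolerance = 0.05 * sigma^2)
  expect_error(detrend(matrix(0, 4, 5)), "square")
  expect_error(detrend(matrix(0, 4, 4), order = 3), "order")
})

test_that("white-noise NPS satisfies Parseval and has correct axes", {
  patches <- uniform_patch_stack(32, hu = 0,
                                 noise = list(model = "white", sigma = 25),
                                 seed = 77, n = 100)
  residuals <- lapply(patches, detrend)
  nps <- nps_2d(residuals, spacing = c(1, 1))
  expect_true(all(nps$values >= 0))
  expect_equal(nps$n_rois_averaged, 100)
  # frequency axes: symmetric grid whose extreme is Nyquist = 1/(2 dx)
  expect_equal(min(nps$freq_x), -0.5)
  expect_equal(max(abs(nps$freq_x)), 0.5)
  expect_equal(sort(nps$freq_y), nps$freq_y)
  # integral of the NPS over frequency = residual variance (sigma^2 here)
  total <- sum(nps$values) * diff(nps$freq_x[1:2]) * diff(nps$freq_y[1:2])
  expect_gt(total, 0.95 * 25^2)
  expect_lt(total, 1.05 * 25^2)
  # all-zero patches give an all-zero spectrum
  expect_equal(nps_2d(list(matrix(0, 16, 16)), c(1, 1))$values,
               matrix(0, 16, 16))
  expect_error(nps_2d(list(matrix(0, 8, 8), matrix(0, 16, 16)), c(1, 1)),
               "size")
})

test_that("a pure cosine concentrates NPS power in its conjugate bins", {
  n <- 32
  k <- 5  # cycles across the patch
  x <- matrix(rep(0:(n - 1), each = n), n, n)
  patch <- 10 * cos(2 * pi * k * x / n)
  nps <- nps_2d(list(patch), spacing = c(1, 1))
  f0 <- k / n
  on_target <- abs(abs(outer(rep(1, n), nps$freq_x)) - f0) < 1e-9 &
    outer(nps$freq_y, rep(1, n)) == 0
  expect_equal(sum(nps$values[on_target]) / sum(nps$values), 1,
               tolerance = 1e-10)
})

test_that("radial profile summarizes peak and mean frequency correctly", {
  n <- 32
  k <- 5
  x <- matrix(rep(0:(n - 1), each = n), n, n)
  nps <- nps_2d(list(10 * cos(2 * pi * k * x / n)), spacing = c(1, 1))
  prof <- radial_profile(nps)
  f0 <- k / n
  binw <- diff(prof$freq_bins[1:2])
  expect_lt(abs(prof$peak_frequency - f0), binw)
  expect_lt(abs(prof$mean_frequency - f0), binw)
  expect_equal(prof$peak_value, max(prof$values))
  expect_true(all(diff(prof$freq_bins) > 0))
  expect_gte(prof$mean_frequency, min(prof$freq_bins))
  expect_lte(prof$mean_frequency, max(prof$freq_bins))

  # flat spectrum: every bin averages to the same value and the mean
  # frequency equals the direct power-weighted bin-center mean
  flat <- structure(
    list(values = matrix(3, 16, 16),
         freq_x = atvseg:::fft_freq(16, 1), freq_y = atvseg:::fft_freq(16, 1),
         spacing = c(1, 1), n_rois_averaged = 1),
    class = "nps_2d"
  )
  pf <- radial_profile(flat, n_bins = 8)
  expect_true(all(abs(pf$values - 3) < 1e-12))
  expect_equal(pf$mean_frequency,
               sum(pf$freq_bins * pf$values) / sum(pf$values))

  # scale invariance of the normalized summaries
  double <- flat
  double$values <- flat$values * 2
  pd <- radial_profile(double, n_bins = 8)
  expect_equal(pd$peak_frequency, pf$peak_frequency)
  expect_equal(pd$mean_frequency, pf$mean_frequency)
  expect_error(radial_profile(flat, n_bins = 1), ">= 2")
})

test_that("ATV denoising shifts the noise spectrum to lower frequencies", {
  cfg <- denoiser_config()
  shifts <- vapply(1:5, function(seed) {
    patches <- uniform_patch_stack(32, hu = 50,
                                   noise = list(model = "white", sigma = 25),
                                   seed = seed, n = 10)
    den <- lapply(patches, function(p) denoise_slice(p, cfg)$slice)
    raw_prof <- radial_profile(nps_2d(lapply(patches, detrend), c(1, 1)))
    den_prof <- radial_profile(nps_2d(lapply(den, detrend), c(1, 1)))
    den_prof$mean_frequency < raw_prof$mean_frequency
  }, logical(1))
  expect_true(all(shifts))
})

test_that("nps_from_volume chains ROI extraction, detrending and profiling", {
  vol <- build_phantom(default_thorax_spec(sigma = 25, seed = 9))$volume
  res <- nps_from_volume(vol, default_liver_rois())
  expect_s3_class(res$nps, "nps_2d")
  expect_equal(res$nps$n_rois_averaged, 15)
  gl <- glance(res$profile)
  expect_true(gl$mean_frequency > 0)
  td <- tidy(res$profile)
  expect_equal(nrow(td), gl$n_bins)
  expect_s3_class(autoplot(res$profile), "ggplot")
})
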