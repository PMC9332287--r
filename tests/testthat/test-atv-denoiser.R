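test_that("backward-difference gradient magnitude matches hand evaluation", {
  expect_equal(backward_difference_gradient(matrix(40, 5, 5)),
               matrix(0, 5, 5))
  # 2x2 slice [[0,0],[0,100]] (x = column, y = row): only the (1,1) pixel
  # has nonzero backward differences, both equal to 100
  m <- matrix(c(0, 0, 0, 100), 2, 2)
  d <- backward_difference_gradient(m, sqrt_epsilon = 0)
  expect_equal(d[1, 1], 0)
  expect_equal(d[1, 2], 0)
  expect_equal(d[2, 1], 0)
  expect_equal(d[2, 2], sqrt(100^2 + 100^2))
  # depends on differences only
  set.seed(2)
  v <- matrix(rnorm(36, 0, 50), 6, 6)
  expect_equal(backward_difference_gradient(v + 137),
               backward_difference_gradient(v))
  # epsilon guard keeps D at sqrt(gx^2 + gy^2 + eps^2)
  expect_equal(backward_difference_gradient(matrix(40, 3, 3), 0.5),
               matrix(0.5, 3, 3))
})

test_that("delta is the documented quantile of the gradient distribution", {
  # constant slice: degenerate distribution -> floor
  expect_equal(estimate_delta(matrix(7, 10, 10), 0.8, delta_floor = 1e-6),
               1e-6)
  # slice engineered so D is exactly 80 zeros and 20 tens:
  # columns 1..8 at 0, column 9 at 10, column 10 at 20
  m <- cbind(matrix(0, 10, 8), matrix(10, 10, 1), matrix(20, 10, 1))
  d <- backward_difference_gradient(m)
  expect_identical(sort(unique(as.vector(d))), c(0, 10))
  expect_equal(sum(d == 10), 20)
  # type-7 quantile: h = 99 * 0.8 + 1 = 80.2 -> 0 + 0.2 * (10 - 0) = 2
  expect_equal(estimate_delta(m, 0.8), 2)
  expect_error(denoiser_config(delta_quantile = 1.0), "0, 1")
  expect_error(denoiser_config(delta_quantile = 0), "0, 1")
})

test_that("anisotropic weights count in-bounds neighbors through the kernel", {
  w <- anisotropic_weights(matrix(40, 5, 5), delta = 10)
  expect_equal(w[3, 3], 4)  # interior: 4 neighbors at exp(0)
  expect_equal(w[1, 1], 2)  # corner: 2 in-bounds neighbors
  expect_equal(w[1, 3], 3)  # edge: 3 in-bounds neighbors
  # all four neighbors differing by exactly delta -> 4 * exp(-1)
  m <- matrix(10, 3, 3)
  m[2, 2] <- 0
  expect_equal(anisotropic_weights(m, delta = 10)[2, 2], 4 * exp(-1))
  expect_error(anisotropic_weights(m, delta = 0), "positive")
  # translation invariance
  set.seed(3)
  v <- matrix(rnorm(49, 0, 30), 7, 7)
  expect_equal(anisotropic_weights(v + 55, 12), anisotropic_weights(v, 12))
})

test_that("objective is the weighted TV and scales with differences", {
  v <- matrix(30, 4, 4)
  expect_equal(atv_objective(v, anisotropic_weights(v, 1)), 0)
  # 2x2 example chained from the D and w examples, delta = 100:
  # only pixel (1,1) contributes, with 2 in-bounds neighbors both at
  # distance 100 = delta -> w = 2 exp(-1); D = sqrt(2) * 100
  m <- matrix(c(0, 0, 0, 100), 2, 2)
  w <- anisotropic_weights(m, delta = 100)
  expect_equal(w[2, 2], 2 * exp(-1))
  expect_equal(atv_objective(m, w), 2 * exp(-1) * sqrt(2) * 100)
  # doubling a zero-mean slice doubles R under frozen weights
  set.seed(4)
  z <- matrix(rnorm(64, 0, 20), 8, 8)
  z <- z - mean(z)
  wz <- anisotropic_weights(z, 25)
  expect_equal(atv_objective(2 * z, wz), 2 * atv_objective(z, wz))
  expect_error(atv_objective(z, wz[1:4, 1:4]), "mismatch")
})

test_that("analytic gradient agrees with finite differences (frozen weights)", {
  for (seed in 1:5) {
    set.seed(seed)
    v <- matrix(rnorm(64, 50, 20), 8, 8)
    w <- anisotropic_weights(v, estimate_delta(v))
    g <- atv_objective_gradient(v, w, sqrt_epsilon = 1e-3)
    fd <- fd_objective_gradient(v, w, sqrt_epsilon = 1e-3)
    expect_lt(max(abs(g$gradient - fd)) / max(abs(fd)), 1e-4)
    expect_equal(g$norm, sqrt(sum(g$gradient^2)))
  }
  # constant slice: exactly zero gradient thanks to the epsilon guard
  g0 <- atv_objective_gradient(matrix(40, 6, 6),
                               anisotropic_weights(matrix(40, 6, 6), 1),
                               sqrt_epsilon = 1e-3)
  expect_equal(g0$gradient, matrix(0, 6, 6))
  expect_equal(g0$norm, 0)
  # gradient depends on differences only
  set.seed(6)
  v <- matrix(rnorm(49, 0, 30), 7, 7)
  w <- anisotropic_weights(v, 20)
  expect_equal(atv_objective_gradient(v + 41, w, 1e-3)$gradient,
               atv_objective_gradient(v, w, 1e-3)$gradient)
})

test_that("step size is gamma times the root-sum-square of pixel values", {
  expect_equal(step_size(matrix(0, 4, 4), 1), 0)
  expect_equal(step_size(matrix(3, 2, 2), 1), 6)
  expect_equal(step_size(matrix(3, 2, 2), 0.8), 4.8)
  # negative HU enters squared
  expect_equal(step_size(matrix(-3, 2, 2), 1), 6)
})

test_that("denoise_slice is an identity at zero iterations and on constants", {
  set.seed(8)
  v <- matrix(rnorm(100, 0, 10), 10, 10)
  res0 <- denoise_slice(v, denoiser_config(iterations = 0))
  expect_identical(res0$slice, v)
  expect_length(res0$state$objective_history, 1)

  resc <- denoise_slice(matrix(55, 12, 12), denoiser_config())
  expect_equal(resc$slice, matrix(55, 12, 12))
  expect_equal(resc$state$iteration, 0L)  # |grad| = 0 early stop
})

test_that("denoising a noisy uniform patch reduces objective and variance", {
  patch <- withr::with_seed(42, matrix(50 + rnorm(64 * 64, sd = 20), 64, 64))
  res <- denoise_slice(patch, denoiser_config())
  r <- res$state$objective_history
  expect_length(r, 21)
  expect_lt(r[21], r[1])
  expect_lt(stats::var(as.vector(res$slice)), stats::var(as.vector(patch)))
  # regression bound on the achieved reduction for this seeded experiment
  expect_lt(r[21] / r[1], 0.5)
  # determinism: bit-identical rerun
  res2 <- denoise_slice(patch, denoiser_config())
  expect_identical(res$slice, res2$slice)
  expect_identical(res$state$objective_history, res2$state$objective_history)
})

test_that("gamma decays by exactly 0.8 at each recorded objective increase", {
  patch <- withr::with_seed(42, matrix(50 + rnorm(64 * 64, sd = 20), 64, 64))
  for (norm in c("rms", "sum")) {
    st <- denoise_slice(patch, denoiser_config(lambda_norm = norm))$state
    g <- c(st$config$gamma_init, st$gamma_history)
    r <- st$objective_history
    expect_true(all(diff(g) <= 0))
    for (t in seq_len(st$iteration)) {
      if (r[t + 1] > r[t]) {
        expect_equal(g[t + 1], g[t] * 0.8)
      } else {
        expect_equal(g[t + 1], g[t])
      }
    }
    expect_equal(st$gamma,
                 st$config$gamma_init * 0.8^sum(diff(r) > 0))
  }
  # the unnormalized step oscillates on this patch, so decays must occur
  st_sum <- denoise_slice(patch, denoiser_config(lambda_norm = "sum"))$state
  expect_gt(sum(diff(st_sum$objective_history) > 0), 0)
})

test_that("high-contrast edges survive denoising while flat regions smooth", {
  img <- withr::with_seed(11, {
    m <- matrix(0, 64, 64)
    m[, 33:64] <- 300
    m + matrix(rnorm(64 * 64, sd = 20), 64, 64)
  })
  out <- denoise_slice(img, denoiser_config())$slice
  lvl_in <- mean(img[, 40:64]) - mean(img[, 1:25])
  lvl_out <- mean(out[, 40:64]) - mean(out[, 1:25])
  expect_lt(abs(lvl_out - 300), 30)  # step height within 10% of 300 HU
  var_in <- (stats::var(as.vector(img[, 1:25])) +
               stats::var(as.vector(img[, 40:64]))) / 2
  var_out <- (stats::var(as.vector(out[, 1:25])) +
                stats::var(as.vector(out[, 40:64]))) / 2
  expect_lt(var_out, 0.5 * var_in)
})

test_that("weight refresh modes both run and differ on noisy input", {
  patch <- withr::with_seed(13, matrix(rnorm(32 * 32, 0, 15), 32, 32))
  a <- denoise_slice(patch, denoiser_config(weight_refresh = "per_iteration"))
  b <- denoise_slice(patch, denoiser_config(weight_refresh = "fixed_initial"))
  expect_false(identical(a$slice, b$slice))
  expect_lt(a$state$objective_history[21], a$state$objective_history[1])
  expect_lt(b$state$objective_history[21], b$state$objective_history[1])
})

test_that("denoise_volume works slice-wise and deterministically", {
  const <- ct_volume(array(40, c(16, 16, 3)), spacing = c(1, 1))
  expect_equal(denoise_volume(const)$volume$data, const$data)

  one <- withr::with_seed(21, matrix(30 + rnorm(24 * 24, 0, 20), 24, 24))
  v <- ct_volume(array(rep(one, 3), c(24, 24, 3)), spacing = c(1, 1))
  res <- denoise_volume(v, denoiser_config())
  expect_identical(res$volume$data[, , 1], res$volume$data[, , 3])
  for (st in res$states) {
    r <- st$objective_history
    expect_lte(r[length(r)], r[1])
  }
})

test_that("denoiser state tidiers expose the run history", {
  patch <- withr::with_seed(42, matrix(50 + rnorm(32 * 32, sd = 20), 32, 32))
  st <- denoise_slice(patch, denoiser_config(iterations = 5))$state
  td <- tidy(st)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 6)
  expect_true(is.na(td$lambda[1]))
  gl <- glance(st)
  expect_equal(gl$iterations, 5)
  expect_equal(gl$objective_final / gl$objective_initial, gl$objective_ratio)
  log <- withr::local_tempfile(fileext = ".csv")
  write_objective_log(st, log)
  expect_equal(nrow(utils::read.csv(log)), 6)
  p <- autoplot(st)
  expect_s3_class(p, "ggplot")
})
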