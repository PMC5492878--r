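test_that("prediction step follows A x and A P A' + Q", {
  st <- kalman_state(c(1, 2, 3), diag(3))
  id <- kalman_params(rep(1, 3), rep(1e-12, 3), rep(1, 3))
  pr <- kalman_predict(st, id)
  expect_equal(pr$x_pred, c(1, 2, 3))
  expect_equal(pr$P_pred, diag(3), tolerance = 1e-10)

  p <- kalman_params(rep(0.5, 3), rep(1, 3), rep(1, 3))
  pr2 <- kalman_predict(kalman_state(c(2, 2, 2), diag(3)), p)
  expect_equal(pr2$x_pred, c(1, 1, 1))
  expect_equal(pr2$P_pred, diag(1.25, 3))

  # from zero state and covariance, the predicted covariance is exactly Q
  accel <- default_kalman_params("accel")
  pr3 <- kalman_predict(kalman_state(rep(0, 3), matrix(0, 3, 3)), accel)
  expect_equal(pr3$x_pred, rep(0, 3))
  expect_equal(pr3$P_pred, accel$Q)
})

test_that("update step matches the closed-form scalar Kalman step", {
  p <- kalman_params(rep(1, 3), rep(1, 3), rep(1, 3))
  st <- kalman_update(x_pred = rep(0, 3), P_pred = diag(3),
                      z = rep(1, 3), params = p)
  expect_equal(diag(attr(st, "gain")), rep(0.5, 3), tolerance = 1e-12)
  expect_equal(st$x, rep(0.5, 3), tolerance = 1e-12)
  expect_equal(diag(st$P), rep(0.5, 3), tolerance = 1e-12)
})

test_that("update limiting cases: trust measurement / ignore measurement", {
  tiny_r <- kalman_params(rep(1, 3), rep(1, 3), rep(1e-12, 3))
  st <- kalman_update(rep(0, 3), diag(3), z = c(1, 2, 3), params = tiny_r)
  expect_equal(st$x, c(1, 2, 3), tolerance = 1e-9)

  p <- kalman_params(rep(1, 3), rep(1, 3), rep(1, 3))
  st0 <- kalman_update(c(4, 5, 6), matrix(0, 3, 3), z = c(0, 0, 0), params = p)
  expect_equal(attr(st0, "gain"), matrix(0, 3, 3))
  expect_equal(st0$x, c(4, 5, 6))

  expect_error(kalman_update(rep(0, 2), diag(3), rep(0, 3), p), "shape")
})

test_that("gain diagonals stay in [0, 1) and covariance stays symmetric PSD", {
  params <- default_kalman_params("gyro")
  st <- kalman_state(rep(0, 3), params$R)
  set.seed(5)
  for (k in 1:200) {
    pr <- kalman_predict(st, params)
    st <- kalman_update(pr$x_pred, pr$P_pred, rnorm(3), params)
    g <- diag(attr(st, "gain"))
    expect_true(all(g >= 0 & g < 1))
    expect_lt(max(abs(st$P - t(st$P))), 1e-12)
    expect_gte(min(eigen(st$P, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("a constant stream passes through the filter unchanged", {
  s <- constant_stream(300, ax = 0.4, ay = -0.3, az = 0.87, gx = 5, gy = -2,
                       gz = 0.5)
  f <- filter_stream(s)
  expect_equal(as.data.frame(f), as.data.frame(s), tolerance = 1e-12)
})

test_that("filtering a noisy static stream reduces variance and RMSE", {
  set.seed(6)
  n <- 2000
  truth <- c(1, 0, 0)
  s <- generate_static_calibration(noise = noise_model(), duration_s = n / 100,
                                   seed = 6)
  f <- filter_stream(s)
  for (i in 1:3) {
    ch <- c("ax", "ay", "az")[i]
    expect_lt(var(f[[ch]]), var(s[[ch]]))
    expect_lt(sqrt(mean((f[[ch]] - truth[i])^2)),
              sqrt(mean((s[[ch]] - truth[i])^2)))
  }
  for (ch in c("gx", "gy", "gz")) expect_lt(var(f[[ch]]), var(s[[ch]]))
})

test_that("step response matches an independently coded scalar recursion", {
  z <- c(rep(0, 99), rep(1, 401))
  oracle <- oracle_scalar_kalman(z, a = 1, q = 1e-4, r = 1e-2)
  lag_oracle <- which(oracle >= 0.9)[1] - 99

  params <- kalman_params(rep(1, 3), rep(1e-4, 3), rep(1e-2, 3),
                          mean = c(0, 0, 0))
  s <- imu_stream(t = (seq_along(z) - 1) / 100, ax = z, ay = z, az = z,
                  gx = 0, gy = 0, gz = 0)
  f <- filter_stream(s, accel_params = params)
  expect_equal(f$ax, oracle, tolerance = 1e-12)
  expect_true(is.finite(lag_oracle) && lag_oracle > 0)
  expect_equal(which(f$ax >= 0.9)[1] - 99, lag_oracle)
})

test_that("the 3-axis filter equals composed matrix predict/update steps", {
  set.seed(8)
  z <- matrix(rnorm(900), ncol = 3)
  params <- kalman_params(c(0.9974, 1, 0.9953), c(4.3e-5, 3.29e-5, 5.38e-5),
                          c(2e-5, 2e-5, 3e-5), mean = c(0, 0, 0))
  st <- kalman_state(z[1, ], params$R)
  ref <- matrix(0, nrow(z), 3)
  ref[1, ] <- st$x
  for (k in 2:nrow(z)) {
    pr <- kalman_predict(st, params)
    st <- kalman_update(pr$x_pred, pr$P_pred, z[k, ], params)
    ref[k, ] <- st$x
  }
  s <- imu_stream(t = (seq_len(nrow(z)) - 1) / 100,
                  ax = z[, 1], ay = z[, 2], az = z[, 3],
                  gx = 0, gy = 0, gz = 0)
  f <- filter_stream(s, accel_params = params)
  expect_equal(cbind(f$ax, f$ay, f$az), ref, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the covariance iteration converges to the Riccati fixed point", {
  for (channel in c("accel", "gyro")) {
    ss <- kalman_steady_state(default_kalman_params(channel))
    expect_lt(ss$riccati_residual, 1e-8)
    expect_lt(max(abs(ss$P_filt - t(ss$P_filt))), 1e-12)
    expect_true(all(diag(ss$gain) >= 0 & diag(ss$gain) < 1))
  }
})

test_that("filtering an empty stream errors", {
  s <- constant_stream(3)
  expect_error(filter_stream(s[0, ]), "empty")
})
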