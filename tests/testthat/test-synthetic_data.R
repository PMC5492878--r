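test_that("static calibration has the requested shape and rest values", {
  cal <- generate_static_calibration(duration_s = 120, fs = 100, seed = 1)
  expect_equal(nrow(cal), 12000)
  expect_equal(stream_fs(cal), 100)

  quiet <- generate_static_calibration(noise = tiny_noise(), duration_s = 1,
                                       seed = 1)
  expect_equal(quiet$ax, rep(1, 100), tolerance = 1e-9)
  expect_equal(quiet$ay + quiet$az + quiet$gx + quiet$gy + quiet$gz,
               rep(0, 100), tolerance = 1e-9)

  expect_error(generate_static_calibration(duration_s = 0), "invalid config")
  expect_error(noise_model(accel_sd = c(0, 1, 1) * 0.001), "invalid config")
  expect_error(noise_model(accel_coef = c(1.2, 0.9, 0.9)), "invalid config")
})

test_that("AR fitting closes the loop on the generator's own coefficients", {
  nm <- noise_model()
  cal <- generate_static_calibration(noise = nm, duration_s = 120, seed = 2)
  n <- nrow(cal)
  for (ax in list(c("ax", 1), c("ay", 2), c("az", 3))) {
    phi <- nm$accel_coef[as.integer(ax[2])]
    fit <- fit_ar(cal[[ax[1]]], 1)
    se <- sqrt((1 - phi^2) / n)
    expect_lt(abs(fit$coefficients[1] - phi), 3 * se + 5 / n)
  }
})

test_that("walking template is periodic at the gait frequency, resultant above 1 g", {
  sig <- template_signals(activity_template("Wk"), identity_jitter())
  res <- sqrt(rowSums(sig$accel^2))
  expect_true(all(res > 0.95))
  # dominant spectral peak of the vertical-axis oscillation at 1 Hz
  ax <- sig$accel[, 1] - mean(sig$accel[, 1])
  sp <- stats::spec.pgram(ts(ax, frequency = 100), plot = FALSE, taper = 0)
  expect_equal(sp$freq[which.max(sp$spec)], 1, tolerance = 0.15)
})

test_that("fall templates end lying with the configured impact peak", {
  for (cls in fall_classes()) {
    s <- generate_activity(cls, noise = tiny_noise(), seed = 3,
                           jitter = identity_jitter())
    theta <- trunk_angle(s$ax, s$ay, s$az)
    expect_lt(abs(theta[nrow(s)] - 90), 2)
    res <- resultant_acceleration(s$ax, s$ay, s$az)
    expect_equal(max(res), 2, tolerance = 0.01)

    s3 <- generate_activity(cls, noise = tiny_noise(), seed = 3,
                            jitter = identity_jitter(), impact_g = 3)
    expect_equal(max(resultant_acceleration(s3$ax, s3$ay, s3$az)), 3,
                 tolerance = 0.01)
  }
})

test_that("ADL templates return upright; the bow is a transient excursion", {
  for (cls in c("Wk", "Sd", "Sq", "Bw")) {
    s <- generate_activity(cls, noise = tiny_noise(), seed = 4,
                           jitter = identity_jitter())
    theta <- trunk_angle(s$ax, s$ay, s$az)
    expect_lt(theta[nrow(s)], 30)
    if (cls == "Bw") expect_gt(max(theta), 45)
  }
})

test_that("quasi-static lead-in of every non-gait template averages 1 g", {
  for (cls in setdiff(activity_classes(), "Wk")) {
    sig <- template_signals(activity_template(cls), identity_jitter())
    res <- sqrt(rowSums(sig$accel[1:50, ]^2))
    expect_equal(mean(res), 1, tolerance = 0.1)
  }
})

test_that("fall peaks dominate every ADL peak in both modalities", {
  peaks <- sapply(activity_classes(), function(cls) {
    sig <- template_signals(activity_template(cls), identity_jitter())
    c(a = max(sqrt(rowSums(sig$accel^2))),
      w = max(sqrt(rowSums(sig$gyro^2))))
  })
  falls <- fall_classes()
  adls <- adl_classes()
  expect_gt(min(peaks["a", falls]), max(peaks["a", adls]))
  expect_gt(min(peaks["w", falls]), max(peaks["w", adls]))
})

test_that("generation is deterministic in the seed and varies across seeds", {
  a <- generate_activity("Sd", seed = 5, subject = 2)
  b <- generate_activity("Sd", seed = 5, subject = 2)
  expect_identical(a, b)
  c_ <- generate_activity("Sd", seed = 6, subject = 2)
  expect_false(identical(a$ax, c_$ax))
})

test_that("dataset generation replicates the 6-class corpus shape", {
  ds <- generate_dataset(n_per_class = 2, subjects = 2, seed = 7)
  expect_length(ds, 12)
  labs <- vapply(ds, stream_label, "")
  expect_equal(unname(table(labs)[activity_classes()]), rep(2L, 6),
               ignore_attr = TRUE)
  for (s in ds) validate_imu_stream(s)

  one <- generate_dataset(n_per_class = 1, subjects = 3, seed = 7)
  expect_length(one, 6)
})

test_that("a regenerated corpus writes byte-identical CSV files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(generate_dataset(n_per_class = 1, subjects = 2, seed = 8,
                                 duration_s = 1), d1)
  write_dataset(generate_dataset(n_per_class = 1, subjects = 2, seed = 8,
                                 duration_s = 1), d2)
  for (fn in list.files(d1)) {
    expect_identical(readLines(file.path(d1, fn)),
                     readLines(file.path(d2, fn)))
  }
  back <- read_dataset(d1)
  expect_length(back, 6)
  expect_equal(vapply(back, stream_label, ""),
               vapply(generate_dataset(n_per_class = 1, subjects = 2,
                                       seed = 8, duration_s = 1),
                      stream_label, ""))
})
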