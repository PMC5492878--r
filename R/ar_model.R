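#' Fit an autoregressive model to a static calibration series
#'
#' Fits an AR(p) model, p in 1..3, to one sensor axis of a static calibration
#' recording.  The series is mean-removed first (the acceleration axes carry
#' a constant gravity component which would otherwise force the fit towards a
#' spurious unit root) and the mean is retained in the fit so the Kalman
#' stage can carry it as a state offset.
#'
#' The default estimator is conditional least squares: regress \eqn{x_t} on
#' its p lags, no intercept, after centering.  Yule-Walker estimation is an
#' accepted alternative (the two differ by O(1/n)) and is available via
#' `method`.  The residual variance is the mean squared one-step-ahead
#' prediction residual, and the final prediction error is Akaike's
#' \deqn{FPE = \hat\sigma^2 \, (n + p + 1) / (n - p - 1).}
#'
#' @param series Numeric vector, the recorded axis.  Must be non-constant and
#'   at least `10 * order` samples long.
#' @param order AR order, 1, 2 or 3.
#' @param method `"ls"` (conditional least squares, default) or
#'   `"yule_walker"`.
#' @return An object of class `ar_fit` with fields `order`, `coefficients`,
#'   `residual_variance`, `fpe`, `n_samples`, `mean` and `method`.
#' @examples
#' set.seed(1)
#' x <- as.numeric(stats::arima.sim(list(ar = 0.5), 2000, sd = 0.1))
#' fit_ar(x, 1)
#' @export
fit_ar <- function(series, order, method = c("ls", "yule_walker")) {
  method <- match.arg(method)
  if (!order %in% 1:3) stop("AR order must be 1, 2 or 3")
  n <- length(series)
  if (n < 10 * order) {
    stop(sprintf("insufficient data: need at least %d samples for AR(%d), got %d",
                 10 * order, order, n))
  }
  if (stats::sd(series) == 0) {
    stop("degenerate fit: series is constant, AR model undefined")
  }
  mu <- mean(series)
  x <- series - mu
  p <- order
  if (method == "ls") {
    y <- x[(p + 1):n]
    X <- sapply(seq_len(p), function(j) x[(p + 1 - j):(n - j)])
    X <- matrix(X, ncol = p)
    coefs <- drop(solve(crossprod(X), crossprod(X, y)))
  } else {
    coefs <- as.numeric(stats::ar.yw(x, aic = FALSE, order.max = p,
                                     demean = FALSE)$ar)
  }
  # one-step residuals under the fitted coefficients, whichever estimator
  pred <- rep(0, n - p)
  for (j in seq_len(p)) pred <- pred + coefs[j] * x[(p + 1 - j):(n - j)]
  resid <- x[(p + 1):n] - pred
  rv <- mean(resid^2)
  structure(list(order = p,
                 coefficients = unname(coefs),
                 residual_variance = rv,
                 fpe = rv * (n + p + 1) / (n - p - 1),
                 n_samples = n,
                 mean = mu,
                 method = method),
            class = "ar_fit")
}

#' @export
print.ar_fit <- function(x, ...) {
  cat(sprintf("AR(%d) fit (%s, n = %d): coefficients %s, sigma2 = %.4g, FPE = %.4g\n",
              x$order, x$method, x$n_samples,
              paste(sprintf("%.4f", x$coefficients), collapse = ", "),
              x$residual_variance, x$fpe))
  invisible(x)
}

#' Select an AR order by final prediction error
#'
#' Given candidate fits of increasing order on the same series, returns the
#' lowest-order fit whose FPE is within `rel_factor` times the minimum FPE
#' across all candidates.  With the default factor of 2, AR(1) is chosen
#' whenever the higher orders improve the FPE by less than 2x -- i.e. when
#' the differences are "tiny" in the same-decade sense -- which is the
#' operating regime of static IMU noise, where AR(3) has a marginally smaller
#' FPE than AR(1) but no practical advantage.
#'
#' @param fits List of [fit_ar()] results on the same series.
#' @param rel_factor Relative FPE tolerance (> 1); default 2.
#' @return The selected `ar_fit`.
#' @export
select_order <- function(fits, rel_factor = 2) {
  if (length(fits) == 0L) stop("empty input: no AR fits to select from")
  if (inherits(fits, "ar_fit")) fits <- list(fits)
  fpe <- vapply(fits, function(f) f$fpe, numeric(1))
  ord <- vapply(fits, function(f) f$order, numeric(1))
  o <- order(ord)
  fits <- fits[o]; fpe <- fpe[o]
  ok <- fpe <= rel_factor * min(fpe)
  fits[[which(ok)[1L]]]
}

#' Kalman filter parameters for one tri-axial channel
#'
#' Bundles the per-channel filter matrices: diagonal state transition `A`
#' (per-axis AR(1) coefficients), diagonal process-noise covariance `Q`
#' (per-axis FPE), diagonal measurement-noise covariance `R` (configured),
#' identity observation map `H`, and zero control input.  An optional 3-vector
#' `mean` is the state offset about which the AR model was identified; `NULL`
#' (the default) means the filter removes each stream's own channel means
#' before filtering and restores them afterwards.
#'
#' @param A_diag,Q_diag,R_diag Numeric length-3 diagonals.  `Q_diag` and
#'   `R_diag` must be strictly positive.
#' @param mean Optional length-3 state offset, or `NULL`.
#' @return An object of class `kalman_params` with 3x3 matrices `A`, `Q`,
#'   `R`, `H` and the offset `mean`.
#' @export
kalman_params <- function(A_diag, Q_diag, R_diag, mean = NULL) {
  stopifnot(length(A_diag) == 3, length(Q_diag) == 3, length(R_diag) == 3)
  if (any(!is.finite(c(A_diag, Q_diag, R_diag)))) {
    stop("invalid config: Kalman parameter diagonals must be finite")
  }
  if (any(Q_diag <= 0)) stop("invalid config: Q diagonal entries must be > 0")
  if (any(R_diag <= 0)) stop("invalid config: R diagonal entries must be > 0")
  if (!is.null(mean) && length(mean) != 3) {
    stop("invalid config: state offset 'mean' must be NULL or length 3")
  }
  structure(list(A = diag(A_diag, 3), Q = diag(Q_diag, 3),
                 R = diag(R_diag, 3), H = diag(3), mean = mean),
            class = "kalman_params")
}

#' @export
print.kalman_params <- function(x, ...) {
  cat("<kalman_params>\n")
  cat("  A diag:", signif(diag(x$A), 5), "\n")
  cat("  Q diag:", signif(diag(x$Q), 5), "\n")
  cat("  R diag:", signif(diag(x$R), 5), "\n")
  invisible(x)
}

#' Derive Kalman parameters from per-axis AR(1) calibration fits
#'
#' Maps three order-1 AR fits (one per axis of a channel) to the filter
#' parameters: `A = diag(a1_x, a1_y, a1_z)`, `Q = diag(FPE_x, FPE_y, FPE_z)`
#' (no rounding), `R = diag(r_diag)`, `H = I`.  The measurement-noise
#' diagonal `r_diag` is a configuration input; it is not identifiable from
#' the calibration alone.
#'
#' @param fit_x,fit_y,fit_z Order-1 [fit_ar()] results for the X/Y/Z axes.
#' @param r_diag Length-3 positive measurement-noise variances.
#' @param mean State offset passed through to [kalman_params()]; the default
#'   `"calibration"` uses the three fitted series means, `NULL` defers to the
#'   per-stream mean at filter time.
#' @return A [kalman_params()] object.
#' @export
build_kalman_params <- function(fit_x, fit_y, fit_z, r_diag,
                                mean = "calibration") {
  fits <- list(fit_x, fit_y, fit_z)
  for (f in fits) {
    if (!inherits(f, "ar_fit")) stop("fits must be ar_fit objects")
    if (f$order != 1L) {
      stop(sprintf("order mismatch: Kalman parameters require AR(1) fits, got AR(%d)",
                   f$order))
    }
  }
  if (identical(mean, "calibration")) {
    mean <- vapply(fits, function(f) f$mean, numeric(1))
  }
  kalman_params(A_diag = vapply(fits, function(f) f$coefficients[1L], numeric(1)),
                Q_diag = vapply(fits, function(f) f$fpe, numeric(1)),
                R_diag = r_diag,
                mean = mean)
}

#' Reference Kalman parameters for a trunk-worn IMU
#'
#' Filter parameters identified from a 2-minute static calibration of the
#' sensor board: per-axis AR(1) coefficients on the diagonal of `A`, the
#' matching FPE values on the diagonal of `Q`, and the configured
#' measurement-noise diagonal `R`.  Acceleration entries are in g (variances
#' in g^2), angular-velocity entries in deg/s (variances in (deg/s)^2).
#' These serve as sensible defaults when no site-specific calibration
#' recording is available.
#'
#' @param channel `"accel"` or `"gyro"`.
#' @return A [kalman_params()] object with `mean = NULL` (per-stream offset).
#' @export
default_kalman_params <- function(channel = c("accel", "gyro")) {
  channel <- match.arg(channel)
  if (channel == "accel") {
    kalman_params(A_diag = c(0.9974, 1, 0.9953),
                  Q_diag = c(4.3e-5, 3.29e-5, 5.38e-5),
                  R_diag = c(2e-5, 2e-5, 3e-5))
  } else {
    kalman_params(A_diag = c(1, 0.9269, 0.9997),
                  Q_diag = c(0.0012, 0.0010, 0.0011),
                  R_diag = c(0.002, 0.00087, 0.00109))
  }
}

#' Calibrate both filter channels from a static recording
#'
#' Runs the full identification procedure on a static calibration stream:
#' per axis, fits AR(1..3), selects the order by FPE ([select_order()]),
#' verifies AR(1) is adequate, and assembles [kalman_params()] for the
#' acceleration and gyroscope channels.
#'
#' @param stream Static calibration [imu_stream()] (sensor at rest,
#'   recommended length >= 2 min).
#' @param accel_r,gyro_r Measurement-noise diagonals; defaults are the
#'   reference values of [default_kalman_params()].
#' @param rel_factor FPE tolerance for [select_order()].
#' @return A list with elements `accel` and `gyro` ([kalman_params()]) and
#'   `fits`, the 6 x 3 list of all per-axis [fit_ar()] results.
#' @export
calibrate_kalman <- function(stream, accel_r = c(2e-5, 2e-5, 3e-5),
                             gyro_r = c(0.002, 0.00087, 0.00109),
                             rel_factor = 2) {
  validate_imu_stream(stream)
  axes <- c("ax", "ay", "az", "gx", "gy", "gz")
  fits <- lapply(axes, function(ch) {
    lapply(1:3, function(p) fit_ar(stream[[ch]], p))
  })
  names(fits) <- axes
  chosen <- lapply(fits, select_order, rel_factor = rel_factor)
  first_order <- lapply(fits, `[[`, 1L)
  list(
    accel = build_kalman_params(first_order$ax, first_order$ay, first_order$az,
                                r_diag = accel_r),
    gyro = build_kalman_params(first_order$gx, first_order$gy, first_order$gz,
                               r_diag = gyro_r),
    selected_orders = vapply(chosen, `[[`, numeric(1), "order"),
    fits = fits
  )
}

#' Write / read a calibration file
#'
#' Serialises the output of [calibrate_kalman()] (per-channel A/Q/R diagonals
#' and state offsets) as structured YAML text so the filtering stage can be
#' run later or on another machine.
#'
#' @param calibration List with `accel` and `gyro` [kalman_params()].
#' @param path File path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns a list with `accel` and `gyro`.
#' @export
write_calibration <- function(calibration, path) {
  enc <- function(p) list(A = as.numeric(diag(p$A)),
                          Q = as.numeric(diag(p$Q)),
                          R = as.numeric(diag(p$R)),
                          mean = if (is.null(p$mean)) "stream" else as.numeric(p$mean))
  yaml::write_yaml(list(format = "imufall-calibration", version = 1L,
                        accel = enc(calibration$accel),
                        gyro = enc(calibration$gyro)),
                   path, precision = 17L)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!identical(obj$format, "imufall-calibration")) {
    stop("not an imufall calibration file")
  }
  dec <- function(ch) {
    mean <- if (identical(ch$mean, "stream")) NULL else as.numeric(ch$mean)
    kalman_params(as.numeric(ch$A), as.numeric(ch$Q), as.numeric(ch$R), mean)
  }
  list(accel = dec(obj$accel), gyro = dec(obj$gyro))
}
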