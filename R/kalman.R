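#' Kalman filter state
#'
#' State of one 3-axis channel filter: the estimate `x` (`X(k|k)`, channel
#' units) and the estimation-error covariance `P` (`P(k|k)`), which must be
#' symmetric positive semidefinite.
#'
#' @param x Numeric length-3 state estimate.
#' @param P 3x3 covariance matrix.
#' @return An object of class `kalman_state`.
#' @export
kalman_state <- function(x, P) {
  stopifnot(length(x) == 3, all(dim(P) == c(3, 3)))
  if (max(abs(P - t(P))) > 1e-8) stop("P must be symmetric")
  if (min(eigen(P, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    stop("P must be positive semidefinite")
  }
  structure(list(x = as.numeric(x), P = (P + t(P)) / 2), class = "kalman_state")
}

#' Kalman prediction step
#'
#' Time update: `x_pred = A x` (the control input is identically zero for
#' this sensor model) and `P_pred = A P A' + Q`.
#'
#' @param state A [kalman_state()].
#' @param params A [kalman_params()].
#' @return List with `x_pred` (length 3) and `P_pred` (3x3, symmetric PSD).
#' @export
kalman_predict <- function(state, params) {
  if (length(state$x) != nrow(params$A)) stop("shape error: state/params dimension mismatch")
  P_pred <- params$A %*% state$P %*% t(params$A) + params$Q
  list(x_pred = as.numeric(params$A %*% state$x),
       P_pred = (P_pred + t(P_pred)) / 2)
}

#' Kalman measurement update
#'
#' Measurement update: gain `Kg = P_pred H' (H P_pred H' + R)^{-1}`, estimate
#' `x = x_pred + Kg (z - H x_pred)`, covariance `P = (I - Kg H) P_pred`.
#' With `H = I` and diagonal covariances every diagonal gain entry lies in
#' `[0, 1)`.  The covariance is re-symmetrised after the update.
#'
#' @param x_pred,P_pred Output of [kalman_predict()].
#' @param z Length-3 measurement.
#' @param params A [kalman_params()].
#' @return A [kalman_state()]; the gain used is attached as attribute
#'   `"gain"`.
#' @export
kalman_update <- function(x_pred, P_pred, z, params) {
  if (length(z) != length(x_pred)) stop("shape error: measurement dimension mismatch")
  H <- params$H
  S <- H %*% P_pred %*% t(H) + params$R
  Kg <- t(solve(S, H %*% t(P_pred)))
  x <- as.numeric(x_pred + Kg %*% (z - H %*% x_pred))
  P <- (diag(nrow(P_pred)) - Kg %*% H) %*% P_pred
  st <- kalman_state(x, (P + t(P)) / 2)
  attr(st, "gain") <- Kg
  st
}

# Scalar Kalman recursion for one axis.  Because A, Q, R and H are all
# diagonal, the 3-axis filter decouples into three of these; the matrix-form
# predict/update operations above are the reference path used in tests.
scalar_kalman <- function(z, a, q, r, x0 = z[1L], p0 = r) {
  n <- length(z)
  out <- numeric(n)
  x <- x0
  p <- p0
  out[1L] <- x
  if (n > 1L) {
    for (k in 2:n) {
      xp <- a * x
      pp <- a * a * p + q
      kg <- pp / (pp + r)
      x <- xp + kg * (z[k] - xp)
      p <- (1 - kg) * pp
      out[k] <- x
    }
  }
  out
}

#' Kalman-filter an IMU stream
#'
#' Runs two independent 3-state Kalman filters over a stream: one on the
#' acceleration triple, one on the angular-velocity triple (the two channels
#' have separate A/Q/R sets and no cross-covariance is modelled).  The filter
#' is initialised from the data, `x_0` = first measurement and `P_0 = R`, so
#' a constant stream is reproduced exactly and no transient divergence
#' occurs.
#'
#' When a channel's `mean` offset is `NULL` (the default parameters), the
#' filter removes that stream's own per-axis means before filtering and adds
#' them back on output; the AR state model is identified about the
#' calibration mean, and near-unit-root AR dynamics on an uncentred series
#' are otherwise ill-posed.  A fixed offset (e.g. the calibration means) can
#' be supplied through [kalman_params()].
#'
#' @param stream An [imu_stream()].
#' @param accel_params,gyro_params [kalman_params()] for the two channels;
#'   defaults are the reference calibration of [default_kalman_params()].
#' @return An `imu_stream` of identical length, timestamps and metadata with
#'   the six channels replaced by their filtered estimates.
#' @examples
#' s <- imu_stream(t = (0:99) / 100, ax = 1 + rnorm(100, sd = 0.01),
#'                 ay = 0, az = 0, gx = 0, gy = 0, gz = 0)
#' f <- filter_stream(s)
#' var(f$ax) < var(s$ax)
#' @export
filter_stream <- function(stream,
                          accel_params = default_kalman_params("accel"),
                          gyro_params = default_kalman_params("gyro")) {
  if (nrow(stream) == 0L) stop("empty stream: nothing to filter")
  validate_imu_stream(stream)
  out <- stream
  filt_triple <- function(cols, params) {
    mu <- params$mean
    if (is.null(mu)) mu <- vapply(cols, function(ch) mean(stream[[ch]]), numeric(1))
    for (i in seq_along(cols)) {
      ch <- cols[i]
      z <- stream[[ch]] - mu[i]
      out[[ch]] <<- scalar_kalman(z, a = params$A[i, i], q = params$Q[i, i],
                                  r = params$R[i, i]) + mu[i]
    }
  }
  filt_triple(c("ax", "ay", "az"), accel_params)
  filt_triple(c("gx", "gy", "gz"), gyro_params)
  out
}

#' Steady-state filter covariance
#'
#' Iterates the covariance recursion `P_pred = A P A' + Q`,
#' `P = (I - Kg H) P_pred` to its fixed point.  For stationary parameters
#' with `|a_ii| <= 1` and positive definite Q and R the iteration converges;
#' the fixed point of the predicted covariance satisfies the discrete
#' algebraic Riccati equation
#' `P = A P A' + Q - A P H' (H P H' + R)^{-1} H P A'`.
#'
#' @param params A [kalman_params()].
#' @param tol Convergence tolerance on successive iterates (default 1e-14).
#' @param max_iter Iteration cap.
#' @return List with `P_pred` and `P_filt` fixed points, the steady-state
#'   `gain`, the `riccati_residual` (max abs entry of the DARE defect of
#'   `P_pred`), and `iterations` used.
#' @export
kalman_steady_state <- function(params, tol = 1e-14, max_iter = 100000L) {
  A <- params$A; Q <- params$Q; R <- params$R; H <- params$H
  P <- R
  for (it in seq_len(max_iter)) {
    P_pred <- A %*% P %*% t(A) + Q
    S <- H %*% P_pred %*% t(H) + R
    Kg <- t(solve(S, H %*% t(P_pred)))
    P_new <- (diag(3) - Kg %*% H) %*% P_pred
    P_new <- (P_new + t(P_new)) / 2
    if (max(abs(P_new - P)) < tol) {
      P <- P_new
      break
    }
    P <- P_new
  }
  P_pred <- A %*% P %*% t(A) + Q
  S <- H %*% P_pred %*% t(H) + R
  Kg <- t(solve(S, H %*% t(P_pred)))
  defect <- A %*% P_pred %*% t(A) + Q -
    A %*% P_pred %*% t(H) %*% solve(S, H %*% t(P_pred)) %*% t(A) - P_pred
  list(P_pred = P_pred,
       P_filt = P,
       gain = Kg,
       riccati_residual = max(abs(defect)),
       iterations = it)
}
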