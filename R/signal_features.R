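#' Resultant acceleration
#'
#' Euclidean norm of the tri-axial acceleration vector,
#' \eqn{a(t) = \sqrt{a_x^2 + a_y^2 + a_z^2}}, in g.  For a subject at rest
#' the resultant reads approximately 1 g regardless of posture; fall impacts
#' drive it towards 2 g and beyond.
#'
#' @param ax,ay,az Acceleration components in g (vectorised).
#' @return Resultant acceleration in g, same length as the inputs.
#' @examples
#' resultant_acceleration(0.6, 0.8, 0)  # 1
#' @export
resultant_acceleration <- function(ax, ay, az) {
  check_finite_channels(ax = ax, ay = ay, az = az)
  sqrt(ax^2 + ay^2 + az^2)
}

#' Trunk angle
#'
#' Angle between the trunk longitudinal (X) axis and the measured,
#' gravity-dominated acceleration vector:
#' \eqn{\theta(t) = \cos^{-1}(a_x / \sqrt{a_x^2 + a_y^2 + a_z^2})},
#' reported in degrees in \[0, 180\].  Standing reads about 0 degrees, lying
#' about 90; a fall is a rapid transition between the two.
#'
#' A zero-magnitude acceleration vector has no defined orientation and is
#' rejected: a working accelerometer at rest always reads about 1 g, so a
#' zero vector signals corrupt data rather than a posture.
#'
#' @inheritParams resultant_acceleration
#' @return Trunk angle in degrees, same length as the inputs.
#' @examples
#' trunk_angle(1, 0, 0)  # standing: 0
#' trunk_angle(0, 1, 0)  # lying: 90
#' @export
trunk_angle <- function(ax, ay, az) {
  check_finite_channels(ax = ax, ay = ay, az = az)
  mag <- sqrt(ax^2 + ay^2 + az^2)
  bad <- which(mag == 0)
  if (length(bad)) {
    stop(sprintf("degenerate orientation: zero-magnitude acceleration vector at sample %d (trunk angle undefined)",
                 bad[1L]))
  }
  # clamp guards acos against |ratio| = 1 + eps from floating-point rounding
  ratio <- pmin(1, pmax(-1, ax / mag))
  acos(ratio) * 180 / pi
}

#' Resultant angular velocity
#'
#' Euclidean norm of the tri-axial gyroscope reading,
#' \eqn{\omega(t) = \sqrt{\omega_x^2 + \omega_y^2 + \omega_z^2}}, in deg/s.
#'
#' @param wx,wy,wz Angular velocity components in deg/s (vectorised).
#' @return Resultant angular velocity in deg/s.
#' @examples
#' resultant_angular_velocity(3, 4, 0)  # 5
#' @export
resultant_angular_velocity <- function(wx, wy, wz) {
  check_finite_channels(wx = wx, wy = wy, wz = wz)
  sqrt(wx^2 + wy^2 + wz^2)
}

#' Derive the per-sample activity features of a stream
#'
#' Computes the three derived features -- resultant acceleration `a`, trunk
#' angle `theta` and resultant angular velocity `w` -- for every sample of an
#' IMU stream.
#'
#' @param stream An [imu_stream()].
#' @return A data frame with columns `t`, `a` (g), `theta` (degrees) and `w`
#'   (deg/s), one row per input sample.
#' @export
derive_features <- function(stream) {
  if (nrow(stream) == 0L) stop("empty stream: no samples to derive features from")
  validate_imu_stream(stream)
  data.frame(
    t = stream$t,
    a = resultant_acceleration(stream$ax, stream$ay, stream$az),
    theta = trunk_angle(stream$ax, stream$ay, stream$az),
    w = resultant_angular_velocity(stream$gx, stream$gy, stream$gz)
  )
}

# Shared error path: every feature operation rejects non-finite samples,
# naming the channel and the first offending index.
check_finite_channels <- function(...) {
  chans <- list(...)
  for (nm in names(chans)) {
    bad <- which(!is.finite(chans[[nm]]))
    if (length(bad)) {
      stop(sprintf("invalid sample: non-finite value in channel '%s' at sample %d",
                   nm, bad[1L]))
    }
  }
  invisible(NULL)
}
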