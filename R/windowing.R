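#' Per-sample feature sets
#'
#' The three configured feature sets over one IMU sample:
#' * `FS9`: `ax, ay, az, a, gx, gy, gz, w, theta` (all raw axes plus the
#'   three derived features);
#' * `FS7`: `ax, ay, az, gx, gy, gz, theta` (raw axes plus trunk angle);
#' * `FS3`: `a, w, theta` (derived features only).
#'
#' @param name Feature-set name.
#' @return `feature_set()`: character vector of feature names;
#'   `feature_set_names()`: the available set names.
#' @export
feature_set <- function(name) {
  sets <- list(
    FS9 = c("ax", "ay", "az", "a", "gx", "gy", "gz", "w", "theta"),
    FS7 = c("ax", "ay", "az", "gx", "gy", "gz", "theta"),
    FS3 = c("a", "w", "theta")
  )
  if (!name %in% names(sets)) {
    stop(sprintf("unknown feature set '%s' (expected one of %s)",
                 name, paste(names(sets), collapse = ", ")))
  }
  sets[[name]]
}

#' @rdname feature_set
#' @export
feature_set_names <- function() c("FS9", "FS7", "FS3")

#' Build per-sample feature vectors from a stream
#'
#' Computes one feature vector per sample of a (typically Kalman-filtered)
#' stream, with columns given by the active feature set.  Derived features
#' `a`, `w`, `theta` come from [resultant_acceleration()],
#' [resultant_angular_velocity()] and [trunk_angle()].
#'
#' @param stream An [imu_stream()].
#' @param set Feature-set name, see [feature_set()].
#' @return A numeric matrix, one row per sample, columns named exactly by the
#'   active feature set; the stream's label (if any) is carried in attribute
#'   `"label"` and `fs` in attribute `"fs"`.
#' @export
make_feature_vectors <- function(stream, set = "FS9") {
  if (nrow(stream) == 0L) stop("empty stream: no samples to featurise")
  cols <- feature_set(set)
  full <- cbind(as.matrix(as.data.frame(stream)[c("ax", "ay", "az",
                                                  "gx", "gy", "gz")]),
                a = resultant_acceleration(stream$ax, stream$ay, stream$az),
                w = resultant_angular_velocity(stream$gx, stream$gy, stream$gz),
                theta = trunk_angle(stream$ax, stream$ay, stream$az))
  m <- full[, cols, drop = FALSE]
  attr(m, "label") <- stream_label(stream)
  attr(m, "fs") <- stream_fs(stream)
  m
}

#' Window length for a sampling rate and duration
#'
#' Number of samples a sliding window of `n_seconds` spans at `fs` Hz.  At
#' the system's 100 Hz and the 2 s fall-duration bound this is the default
#' window length of 200 samples.
#'
#' @param fs Sampling frequency in Hz, > 0.
#' @param n_seconds Window duration in seconds, > 0.
#' @return Integer sample count, `round(fs * n_seconds)`.
#' @export
window_duration <- function(fs, n_seconds) {
  if (!is.finite(fs) || fs <= 0) stop("invalid config: fs must be > 0")
  if (!is.finite(n_seconds) || n_seconds <= 0) {
    stop("invalid config: n_seconds must be > 0")
  }
  as.integer(round(fs * n_seconds))
}

#' Slide a fixed-width window over a feature-vector sequence
#'
#' Cuts contiguous windows of `width` rows starting at 0-based indices
#' `0, step, 2 step, ...`; each window covers the half-open row range
#' `[start, start + width)`.  Input shorter than one window yields an empty
#' list.  Windows inherit the sequence's label.
#'
#' @param vectors Matrix from [make_feature_vectors()] (or any matrix with
#'   one row per sample).
#' @param width Window length in samples (default 200 = 2 s at 100 Hz).
#' @param step Slide step in samples (default 1, per-arrival sliding).
#' @return List of `imu_window` objects, each with `start_index` (0-based),
#'   `elements` (a `width` x features matrix) and `label`.
#' @examples
#' m <- matrix(rnorm(300 * 3), ncol = 3)
#' length(slide(m, width = 200, step = 1))  # 101
#' @export
slide <- function(vectors, width = 200L, step = 1L) {
  if (width < 1L) stop("invalid config: width must be >= 1")
  if (step < 1L) stop("invalid config: step must be >= 1")
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (n < width) return(list())
  starts <- seq(0L, n - width, by = step)
  lab <- attr(vectors, "label", exact = TRUE)
  lapply(starts, function(s) {
    structure(list(start_index = as.integer(s),
                   elements = vectors[(s + 1L):(s + width), , drop = FALSE],
                   label = lab),
              class = "imu_window")
  })
}

#' @export
print.imu_window <- function(x, ...) {
  cat(sprintf("<imu_window> start %d, %d x %d%s\n", x$start_index,
              nrow(x$elements), ncol(x$elements),
              if (is.null(x$label)) "" else paste0(", label = ", x$label)))
  invisible(x)
}
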