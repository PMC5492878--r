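#' Activity class labels
#'
#' The six activity classes recognised by the pipeline: four activities of
#' daily living (ADLs) -- walking (`Wk`), sitting down (`Sd`), squatting down
#' (`Sq`), bowing (`Bw`) -- and two falls -- sideward fall (`Sd-Fall`) and
#' backward fall (`Bw-Fall`).
#'
#' @return Character vector of the six class labels, ADLs first.
#' @export
activity_classes <- function() {
  c("Wk", "Sd", "Sq", "Bw", "Sd-Fall", "Bw-Fall")
}

#' @rdname activity_classes
#' @return `fall_classes()`: the two fall labels.
#' @export
fall_classes <- function() {
  c("Sd-Fall", "Bw-Fall")
}

#' @rdname activity_classes
#' @return `adl_classes()`: the four ADL labels.
#' @export
adl_classes <- function() {
  setdiff(activity_classes(), fall_classes())
}

#' Construct an IMU stream
#'
#' An `imu_stream` is a data frame with one row per 100 Hz sample and columns
#' `t` (seconds), `ax`, `ay`, `az` (acceleration in g along the trunk X/Y/Z
#' axes) and `gx`, `gy`, `gz` (angular velocity in deg/s).  The X axis is the
#' trunk longitudinal axis, parallel to gravity when standing, so a standing
#' subject reads approximately (1, 0, 0) g at rest.  The sampling frequency,
#' an optional activity label and an optional subject identifier are carried
#' as attributes.
#'
#' @param t Time in seconds, strictly increasing at a fixed rate `1/fs`.
#' @param ax,ay,az Acceleration components in g.
#' @param gx,gy,gz Angular velocity components in deg/s.
#' @param fs Sampling frequency in Hz (default 100).
#' @param label Optional activity label, one of [activity_classes()].
#' @param subject Optional subject identifier.
#' @return A data frame of class `imu_stream`.
#' @examples
#' s <- imu_stream(t = (0:9) / 100, ax = rep(1, 10), ay = 0, az = 0,
#'                 gx = 0, gy = 0, gz = 0)
#' stream_fs(s)
#' @export
imu_stream <- function(t, ax, ay, az, gx, gy, gz, fs = 100,
                       label = NULL, subject = NULL) {
  df <- data.frame(t = t, ax = ax, ay = ay, az = az,
                   gx = gx, gy = gy, gz = gz)
  attr(df, "fs") <- fs
  attr(df, "label") <- label
  attr(df, "subject") <- subject
  class(df) <- c("imu_stream", "data.frame")
  validate_imu_stream(df)
  df
}

#' Validate an IMU stream
#'
#' Checks the `imu_stream` invariants: all six channel values finite,
#' timestamps non-negative and advancing by exactly `1/fs` (within rounding),
#' and any label drawn from the known class set.
#'
#' @param stream An `imu_stream`.
#' @return The stream, invisibly, if valid; otherwise an error is signalled
#'   naming the offending channel and sample index.
#' @export
validate_imu_stream <- function(stream) {
  if (nrow(stream) == 0L) {
    stop("empty stream: an imu_stream must contain at least one sample")
  }
  for (ch in c("t", "ax", "ay", "az", "gx", "gy", "gz")) {
    bad <- which(!is.finite(stream[[ch]]))
    if (length(bad)) {
      stop(sprintf("invalid sample: non-finite value in channel '%s' at sample %d",
                   ch, bad[1L]))
    }
  }
  if (stream$t[1L] < 0) stop("invalid sample: negative timestamp at sample 1")
  fs <- stream_fs(stream)
  if (nrow(stream) > 1L) {
    dt <- diff(stream$t)
    if (any(abs(dt - 1 / fs) > 1e-6)) {
      stop(sprintf("timestamps are not uniform at fs = %g Hz", fs))
    }
  }
  lab <- stream_label(stream)
  if (!is.null(lab) && !lab %in% c(activity_classes(), "Up", "Down", "static")) {
    stop(sprintf("unknown activity label '%s'", lab))
  }
  invisible(stream)
}

#' @rdname imu_stream
#' @param stream An `imu_stream`.
#' @export
stream_fs <- function(stream) {
  fs <- attr(stream, "fs", exact = TRUE)
  if (is.null(fs)) 100 else fs
}

#' @rdname imu_stream
#' @export
stream_label <- function(stream) attr(stream, "label", exact = TRUE)

#' @rdname imu_stream
#' @export
stream_subject <- function(stream) attr(stream, "subject", exact = TRUE)

#' @export
print.imu_stream <- function(x, ...) {
  lab <- stream_label(x)
  cat(sprintf("<imu_stream> %d samples @ %g Hz (%.2f s)%s\n",
              nrow(x), stream_fs(x), nrow(x) / stream_fs(x),
              if (is.null(lab)) "" else paste0(", label = ", lab)))
  utils::str(as.data.frame(utils::head(x, 3)))
  invisible(x)
}

#' Read and write IMU stream CSV files
#'
#' The on-disk format is a plain CSV with header `t,ax,ay,az,gx,gy,gz`
#' (times in seconds, accelerations in g, angular velocities in deg/s),
#' optionally preceded by comment lines `# fs=<Hz>`, `# label=<class>` and
#' `# subject=<id>`.  Bare files without comments are accepted and read at
#' the default 100 Hz.
#'
#' @param path File path.
#' @return `read_imu_csv()` returns an `imu_stream`.
#' @export
read_imu_csv <- function(path) {
  head_lines <- readLines(path, n = 10L)
  meta <- list(fs = 100, label = NULL, subject = NULL)
  for (ln in grep("^#", head_lines, value = TRUE)) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub("=.*$", "", kv)
    val <- sub("^[^=]*=", "", kv)
    if (key == "fs") meta$fs <- as.numeric(val)
    if (key == "label") meta$label <- trimws(val)
    if (key == "subject") meta$subject <- trimws(val)
  }
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  if (!all(need %in% names(df))) {
    stop(sprintf("stream CSV must have columns %s", paste(need, collapse = ",")))
  }
  imu_stream(df$t, df$ax, df$ay, df$az, df$gx, df$gy, df$gz,
             fs = meta$fs, label = meta$label, subject = meta$subject)
}

#' @rdname read_imu_csv
#' @param stream An `imu_stream` to write.
#' @param digits Number of significant digits written per value (default 7;
#'   round-trips are lossless at this precision for signals of magnitude
#'   0.001--2000 typical of these sensors).
#' @return `write_imu_csv()` returns `path` invisibly.
#' @export
write_imu_csv <- function(stream, path, digits = 7) {
  validate_imu_stream(stream)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g", stream_fs(stream)), con)
  lab <- stream_label(stream)
  if (!is.null(lab)) writeLines(sprintf("# label=%s", lab), con)
  sub <- stream_subject(stream)
  if (!is.null(sub)) writeLines(sprintf("# subject=%s", sub), con)
  df <- as.data.frame(stream)
  df[] <- lapply(df, function(col) signif(col, digits))
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
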