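#' AR(1) sensor-noise model
#'
#' Stationary first-order autoregressive noise per sensor axis, the noise
#' structure identified from static calibration recordings of this sensor
#' class.  Defaults take the per-axis AR coefficients from the reference
#' calibration transition matrices and the innovation variances from the
#' matching process-noise (FPE) diagonals; exact unit-root coefficients are
#' nudged to 0.999 so the generated noise is stationary over arbitrarily
#' long recordings.
#'
#' @param accel_coef,gyro_coef Length-3 AR(1) coefficients, `|coef| <= 1`.
#' @param accel_sd,gyro_sd Length-3 innovation standard deviations (g,
#'   deg/s); must be > 0.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(accel_coef = c(0.9974, 0.999, 0.9953),
                        accel_sd = sqrt(c(4.3e-5, 3.29e-5, 5.38e-5)),
                        gyro_coef = c(0.999, 0.9269, 0.9997),
                        gyro_sd = sqrt(c(0.0012, 0.0010, 0.0011))) {
  stopifnot(length(accel_coef) == 3, length(gyro_coef) == 3,
            length(accel_sd) == 3, length(gyro_sd) == 3)
  if (any(abs(c(accel_coef, gyro_coef)) > 1)) {
    stop("invalid config: AR(1) coefficients must satisfy |coef| <= 1")
  }
  if (any(c(accel_sd, gyro_sd) <= 0)) {
    stop("invalid config: innovation standard deviations must be > 0")
  }
  structure(list(accel_coef = accel_coef, accel_sd = accel_sd,
                 gyro_coef = gyro_coef, gyro_sd = gyro_sd),
            class = "noise_model")
}

# Stationary AR(1) sample path (random-walk when coef == 1).
ar1_noise <- function(n, coef, sd) {
  e <- stats::rnorm(n, 0, sd)
  init <- if (abs(coef) < 1) stats::rnorm(1, 0, sd / sqrt(1 - coef^2)) else 0
  as.numeric(stats::filter(e, coef, method = "recursive", init = init))
}

#' Generate a static calibration recording
#'
#' Simulates the sensor board lying flat: acceleration (1, 0, 0) g plus
#' per-axis AR(1) noise, angular velocity 0 plus AR(1) noise.  This is the
#' input the AR-identification stage expects (recommended duration 2 min).
#'
#' @param noise A [noise_model()].
#' @param duration_s Recording length in seconds (> 0), default 120.
#' @param fs Sampling frequency in Hz, default 100.
#' @param seed Integer seed; the recording is reproducible given the seed.
#' @return A labelled [imu_stream()] of `round(duration_s * fs)` samples.
#' @export
generate_static_calibration <- function(noise = noise_model(),
                                        duration_s = 120, fs = 100,
                                        seed = 17) {
  if (!is.finite(duration_s) || duration_s <= 0) {
    stop("invalid config: duration_s must be > 0")
  }
  if (!inherits(noise, "noise_model")) stop("invalid config: need a noise_model")
  n <- as.integer(round(duration_s * fs))
  set.seed(mix_seed(seed, 0L))
  imu_stream(
    t = (seq_len(n) - 1L) / fs,
    ax = 1 + ar1_noise(n, noise$accel_coef[1], noise$accel_sd[1]),
    ay = ar1_noise(n, noise$accel_coef[2], noise$accel_sd[2]),
    az = ar1_noise(n, noise$accel_coef[3], noise$accel_sd[3]),
    gx = ar1_noise(n, noise$gyro_coef[1], noise$gyro_sd[1]),
    gy = ar1_noise(n, noise$gyro_coef[2], noise$gyro_sd[2]),
    gz = ar1_noise(n, noise$gyro_coef[3], noise$gyro_sd[3]),
    fs = fs, label = "static"
  )
}

#' Activity template
#'
#' Deterministic envelope of one activity class: a trunk-angle trajectory
#' `theta*(t)`, the gravity projection it implies (`a_x = cos theta*`, with
#' the in-plane component `sin theta*` routed to Y for sideward falls and to
#' Z for backward movements), class-specific dynamic acceleration bursts, and
#' angular-velocity envelopes whose dominant axis carries `d theta*/dt` plus,
#' for falls, an impact spike.  Fall templates end lying (`theta* = 90`
#' degrees) and place a half-sine impact transient along the instantaneous
#' gravity direction so the peak resultant acceleration equals `impact_g`;
#' activity transitions are centred in the recording.
#'
#' All template numbers (durations, burst amplitudes, the roughly 1 Hz gait
#' period, fall transitions well under 2 s, the roughly 2 g impact peak) are
#' phenomenological design parameters of the simulator, chosen to mirror the
#' qualitative signatures of trunk-worn recordings of these six activities.
#'
#' @param class One of [activity_classes()].
#' @param duration_s Recording duration in seconds, default 4.
#' @param fs Sampling frequency in Hz, default 100.
#' @param impact_g Peak resultant acceleration at fall impact, in g
#'   (default 2).
#' @return An object of class `activity_template`.
#' @export
activity_template <- function(class, duration_s = 4, fs = 100, impact_g = 2) {
  if (!class %in% activity_classes()) {
    stop(sprintf("unknown activity class '%s'", class))
  }
  if (duration_s <= 0 || fs <= 0) stop("invalid config: non-positive duration or fs")
  if (impact_g <= 1) stop("invalid config: impact_g must exceed 1 g")
  structure(list(class = class, duration_s = duration_s, fs = fs,
                 impact_g = impact_g),
            class = "activity_template")
}

# Burst primitives -----------------------------------------------------------

# half-sine burst, peak 1 at `center`, support width `width`
half_sine <- function(t, center, width) {
  u <- (t - center) / width + 0.5
  ifelse(u > 0 & u < 1, sin(pi * u), 0)
}

# smooth 0 -> 1 -> 0 bump (sin^2), support width `width`
bump <- function(t, center, width) half_sine(t, center, width)^2

# logistic 0 -> 1 transition at t0, effective width `dur`
ramp <- function(t, t0, dur) stats::plogis((t - t0) / (dur / 8))

#' Evaluate a template's noiseless signals
#'
#' @param template An [activity_template()].
#' @param jitter Optional per-subject jitter list with elements `amp`
#'   (dynamic-amplitude scale), `shift` (timing shift, s), `freq` (gait
#'   frequency scale), `phase` (gait phase, rad) and `thamp` (ADL
#'   trunk-angle amplitude scale); defaults are the identity jitter.
#' @return List with `t` (s), `accel` (n x 3, g), `gyro` (n x 3, deg/s) and
#'   `theta` (degrees), the noiseless trajectory.
#' @export
template_signals <- function(template, jitter = NULL) {
  if (is.null(jitter)) {
    jitter <- list(amp = 1, shift = 0, freq = 1, phase = 0, thamp = 1)
  }
  fs <- template$fs
  n <- as.integer(round(template$duration_s * fs))
  t <- (seq_len(n) - 1L) / fs
  tt <- t - jitter$shift
  amp <- jitter$amp
  tha <- jitter$thamp
  fr <- jitter$freq
  ph <- jitter$phase
  cls <- template$class

  dyn <- matrix(0, n, 3)  # dynamic acceleration bursts (g)
  gyro <- matrix(0, n, 3) # deg/s
  fy <- 0; fz <- 1        # in-plane gravity split (Y vs Z)
  dom <- NULL             # gyro axis carrying d(theta)/dt
  impact <- NULL          # time of impact burst (falls only)

  if (cls == "Wk") {
    theta <- 5 + 2 * tha * sin(2 * pi * fr * tt + ph)
    dyn[, 1] <- 0.18 * amp * (0.55 + 0.5 * sin(2 * pi * fr * tt + ph))
    dyn[, 2] <- 0.05 * amp * sin(2 * pi * fr * tt + ph + pi / 3)
    dyn[, 3] <- 0.07 * amp * sin(2 * pi * 2 * fr * tt + ph)
    gyro[, 1] <- 18 * amp * sin(2 * pi * fr * tt + ph)
    gyro[, 2] <- 15 * amp * sin(2 * pi * fr * tt + ph + pi / 2)
    gyro[, 3] <- 8 * amp * sin(2 * pi * fr * tt + ph + pi / 4)
  } else if (cls == "Sd") {
    theta <- 12 * tha * ramp(tt, 2, 1)
    dyn[, 1] <- amp * (-0.30 * half_sine(tt, 1.9, 0.5) +
                         0.40 * half_sine(tt, 2.35, 0.35))
    dyn[, 3] <- amp * 0.30 * half_sine(tt, 2.0, 0.6)
    gyro[, 2] <- 5 * amp * bump(tt, 2, 1)
    gyro[, 3] <- 3 * amp * bump(tt, 2, 1)
    dom <- 1L
  } else if (cls == "Sq") {
    theta <- 8 * tha * bump(tt, 2, 1.6)
    dyn[, 1] <- amp * (-0.35 * half_sine(tt, 1.8, 0.6) +
                         0.45 * half_sine(tt, 2.4, 0.4))
    dyn[, 3] <- amp * 0.25 * half_sine(tt, 2.1, 0.6)
    gyro[, 2] <- 8 * amp * bump(tt, 2, 1.2)
    gyro[, 3] <- 4 * amp * bump(tt, 2, 1.2)
    dom <- 1L
  } else if (cls == "Bw") {
    theta <- 5 + 55 * tha * bump(tt, 2, 2)
    dyn[, 1] <- amp * (-0.15 * half_sine(tt, 1.7, 0.5) +
                         0.15 * half_sine(tt, 2.3, 0.5))
    dyn[, 2] <- amp * 0.20 * half_sine(tt, 2.0, 1.0)
    dyn[, 3] <- amp * 0.30 * half_sine(tt, 1.9, 0.8)
    gyro[, 2] <- 10 * amp * bump(tt, 2, 1.5)
    gyro[, 3] <- 5 * amp * bump(tt, 2, 1.5)
    dom <- 1L
  } else if (cls == "Sd-Fall") {
    theta <- 90 * ramp(tt, 2, 0.7)
    fy <- 1; fz <- 0
    dyn[, 1] <- amp * 0.15 * half_sine(tt, 2.1, 0.3)
    gyro[, 1] <- 30 * amp * half_sine(tt, 2.2, 0.4)
    gyro[, 3] <- 40 * amp * half_sine(tt, 2.2, 0.5)
    gyro[, 2] <- 150 * amp * half_sine(tt, 2.45, 0.15)
    dom <- 2L
    impact <- 2.45
  } else { # Bw-Fall
    theta <- 90 * ramp(tt, 2, 0.65)
    fy <- 0; fz <- 1
    dyn[, 1] <- amp * 0.15 * half_sine(tt, 2.1, 0.3)
    gyro[, 2] <- 40 * amp * half_sine(tt, 2.2, 0.4)
    gyro[, 3] <- 35 * amp * half_sine(tt, 2.2, 0.5)
    gyro[, 1] <- 180 * amp * half_sine(tt, 2.42, 0.15)
    dom <- 1L
    impact <- 2.42
  }

  theta <- pmin(pmax(theta, 0), 180)
  rad <- theta * pi / 180
  grav <- cbind(cos(rad), fy * sin(rad), fz * sin(rad))
  accel <- grav + dyn
  if (!is.null(impact)) {
    # impact transient along the instantaneous gravity direction: peak
    # resultant acceleration equals impact_g exactly in the noiseless limit
    burst <- (template$impact_g - 1) * half_sine(tt, impact, 0.12)
    accel <- accel + grav * burst
  }
  if (!is.null(dom)) {
    dtheta <- c(0, diff(theta)) * fs
    gyro[, dom] <- gyro[, dom] + dtheta
  }
  list(t = t, accel = accel, gyro = gyro, theta = theta)
}

# Per-subject execution-style jitter, reproducible in (seed, subject).
subject_jitter <- function(seed, subject) {
  set.seed(mix_seed(seed, 10000L + subject))
  list(amp = max(0.5, stats::rnorm(1, 1, 0.08)),
       shift = stats::rnorm(1, 0, 0.08),
       freq = max(0.7, stats::rnorm(1, 1, 0.05)),
       phase = stats::runif(1, 0, 2 * pi),
       thamp = max(0.7, stats::rnorm(1, 1, 0.05)))
}

#' Generate one labelled activity recording
#'
#' Evaluates the class template under a per-subject jitter and adds AR(1)
#' sensor noise to all six channels.  Reproducible: the same class, noise
#' model, seed and subject always yield an identical stream.
#'
#' @param class Activity class, or an [activity_template()].
#' @param noise A [noise_model()]; pass innovation SDs near zero for the
#'   noiseless envelope.
#' @param seed Integer seed.
#' @param subject Subject index (drives the execution jitter).
#' @param jitter Optional explicit jitter list (overrides `subject`); see
#'   [template_signals()].
#' @param duration_s,fs,impact_g Template parameters, used when `class` is a
#'   label.
#' @return A labelled [imu_stream()].
#' @export
generate_activity <- function(class, noise = noise_model(), seed = 17,
                              subject = 1L, jitter = NULL,
                              duration_s = 4, fs = 100, impact_g = 2) {
  template <- if (inherits(class, "activity_template")) class
              else activity_template(class, duration_s, fs, impact_g)
  if (!inherits(noise, "noise_model")) stop("invalid config: need a noise_model")
  if (is.null(jitter)) jitter <- subject_jitter(seed, subject)
  sig <- template_signals(template, jitter)
  n <- length(sig$t)
  set.seed(mix_seed(seed, 1L))
  na <- sapply(1:3, function(i) ar1_noise(n, noise$accel_coef[i], noise$accel_sd[i]))
  ng <- sapply(1:3, function(i) ar1_noise(n, noise$gyro_coef[i], noise$gyro_sd[i]))
  imu_stream(t = sig$t,
             ax = sig$accel[, 1] + na[, 1],
             ay = sig$accel[, 2] + na[, 2],
             az = sig$accel[, 3] + na[, 3],
             gx = sig$gyro[, 1] + ng[, 1],
             gy = sig$gyro[, 2] + ng[, 2],
             gz = sig$gyro[, 3] + ng[, 3],
             fs = template$fs, label = template$class,
             subject = as.character(subject))
}

#' Generate a labelled synthetic corpus
#'
#' Builds `n_per_class` recordings of each activity class, cycling subjects
#' so each subject contributes the same number of recordings per class; the
#' default shape (100 per class over 20 subjects, i.e. 5 repetitions each,
#' 600 recordings in all) mirrors a realistic six-activity acquisition
#' campaign.
#'
#' @param n_per_class Recordings per class (>= 1), default 100.
#' @param subjects Number of subjects, default 20.
#' @param noise A [noise_model()].
#' @param seed Integer seed; the corpus is reproducible given the seed.
#' @param classes Classes to generate, default all six.
#' @param duration_s,fs,impact_g Passed to [activity_template()].
#' @return List of labelled [imu_stream()]s, grouped by class.
#' @export
generate_dataset <- function(n_per_class = 100L, subjects = 20L,
                             noise = noise_model(), seed = 17,
                             classes = activity_classes(),
                             duration_s = 4, fs = 100, impact_g = 2) {
  if (n_per_class < 1L) stop("invalid config: n_per_class must be >= 1")
  streams <- vector("list", n_per_class * length(classes))
  idx <- 0L
  for (cls in classes) {
    for (j in seq_len(n_per_class)) {
      idx <- idx + 1L
      subject <- ((j - 1L) %% subjects) + 1L
      streams[[idx]] <- generate_activity(
        cls, noise = noise, seed = mix_seed(seed, 100L + idx),
        subject = subject, duration_s = duration_s, fs = fs,
        impact_g = impact_g
      )
    }
  }
  streams
}

#' Write a corpus directory with a manifest
#'
#' Writes each stream of a corpus as a CSV (see [write_imu_csv()]) plus a
#' `manifest.csv` recording file name, class and subject per recording.
#'
#' @param streams List of labelled [imu_stream()]s.
#' @param dir Output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_dataset <- function(streams, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(file = character(0), class = character(0),
                         subject = character(0))
  for (i in seq_along(streams)) {
    s <- streams[[i]]
    fn <- sprintf("rec_%04d.csv", i)
    write_imu_csv(s, file.path(dir, fn))
    manifest <- rbind(manifest,
                      data.frame(file = fn,
                                 class = stream_label(s) %||% NA_character_,
                                 subject = stream_subject(s) %||% NA_character_))
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_dataset
#' @param dir Corpus directory containing `manifest.csv`.
#' @return `read_dataset()`: the list of streams.
#' @export
read_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  lapply(manifest$file, function(fn) read_imu_csv(file.path(dir, fn)))
}

# deterministic small-integer seed mixing, kept inside 32-bit range
mix_seed <- function(seed, k) {
  (as.numeric(seed) %% 65011 * 33013 + as.numeric(k) * 97) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
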