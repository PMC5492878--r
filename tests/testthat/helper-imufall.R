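# Shared fixtures, built in code.

# A stream with constant channel values.
constant_stream <- function(n, ax = 1, ay = 0, az = 0,
                            gx = 0, gy = 0, gz = 0, fs = 100, label = NULL) {
  imu_stream(t = (seq_len(n) - 1) / fs,
             ax = rep(ax, n), ay = rep(ay, n), az = rep(az, n),
             gx = rep(gx, n), gy = rep(gy, n), gz = rep(gz, n),
             fs = fs, label = label)
}

# Identity subject jitter (no amplitude/timing variation).
identity_jitter <- function() {
  list(amp = 1, shift = 0, freq = 1, phase = 0, thamp = 1)
}

# Near-noiseless sensor model for template-readback checks.
tiny_noise <- function(sd = 1e-12) {
  noise_model(accel_sd = rep(sd, 3), gyro_sd = rep(sd, 3))
}

# Small labelled corpus shared across evaluation tests (built once per run).
local({
  cache <- new.env(parent = emptyenv())
  small_corpus <<- function() {
    if (is.null(cache$ds)) {
      cache$ds <- generate_dataset(n_per_class = 12, subjects = 6, seed = 101)
    }
    cache$ds
  }
})

# Independent discrete naive-Bayes oracle: equal-frequency bins, Laplace
# smoothing, direct probability arithmetic (no log space, no shared code).
oracle_discrete_nb <- function(x, y, v, bins = 10, alpha = 0.5) {
  classes <- sort(unique(y))
  post <- sapply(classes, function(cl) {
    p <- (sum(y == cl) + alpha) / (length(y) + alpha * length(classes))
    for (f in colnames(x)) {
      br <- unique(quantile(x[, f], probs = seq_len(bins - 1) / bins,
                            names = FALSE, type = 7))
      nb <- length(br) + 1
      b <- findInterval(v[f], br) + 1
      bc <- findInterval(x[y == cl, f], br) + 1
      p <- p * (sum(bc == b) + alpha) / (sum(y == cl) + alpha * nb)
    }
    p
  })
  post / sum(post)
}

# Independent scalar Kalman recursion used as an oracle against the
# matrix-form implementation.
oracle_scalar_kalman <- function(z, a, q, r, x0 = z[1], p0 = r) {
  x <- x0; p <- p0
  out <- numeric(length(z))
  out[1] <- x
  for (k in seq_along(z)[-1]) {
    xp <- a * x
    pp <- a^2 * p + q
    kg <- pp / (pp + r)
    x <- xp + kg * (z[k] - xp)
    p <- (1 - kg) * pp
    out[k] <- x
  }
  out
}
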