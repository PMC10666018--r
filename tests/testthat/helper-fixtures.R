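# Shared helpers: tiny in-code fixtures and measurement utilities.

# a uniform skeleton sequence of n identical (or slightly perturbed) frames
static_sequence <- function(n = 30, fs = 30, distance = 2.5, pose = NULL) {
  if (is.null(pose)) pose <- neutral_pose(distance)
  xyz <- array(rep(pose, each = n), dim = c(n, 25, 3))
  skeleton_sequence((seq_len(n) - 1) / fs, xyz, nominal_fs = fs)
}

# steady-state amplitude of a sinusoid in y at frequency f, by sin/cos
# regression over the tail (transient dropped)
measure_amplitude <- function(y, f, fs, drop_s = 2) {
  t <- (seq_along(y) - 1) / fs
  keep <- t >= drop_s
  X <- cbind(1, sin(2 * pi * f * t[keep]), cos(2 * pi * f * t[keep]))
  cf <- stats::lm.fit(X, y[keep])$coefficients
  unname(sqrt(cf[2]^2 + cf[3]^2))
}

# single-joint sinusoidal template over one period
sin_template <- function(A = 30, theta0 = 90, n = 201, duration_s = 2,
                         threshold = 5) {
  u <- seq(0, 1, length.out = n)
  gesture_template("sin_test", theta0 + A * sin(2 * pi * u), list("knee_left"),
                   threshold = threshold, duration_s = duration_s)
}

# random rigid transform applied to a 25 x 3 position matrix
random_rigid <- function(pos, seed) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  shift <- rnorm(3)
  sweep(pos %*% Q, 2, shift, `+`)
}

# two-pass brute-force mean/sd oracle (independent of item_stats)
brute_stats <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  ss <- sum((x - m)^2)
  c(mean = m, sd = sqrt(ss / (n - 1)))
}
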