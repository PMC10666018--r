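# Synthetic articulated skeleton streams with known ground truth. Scored
# joints are driven sinusoidally in angle space; the forward model rotates
# the distal subtree rigidly in the plane of the joint, so the generated
# interior angle equals the commanded angle exactly (up to injected noise).

#' Neutral standing pose
#'
#' Fixed-anthropometry skeleton (default stature 1.70 m, standard segment
#' proportions), standing upright facing the sensor with the arms along the
#' body, feet pointing toward the camera.
#'
#' @param distance Subject distance from the sensor (SpineBase z), meters.
#' @param stature Body height scale, meters.
#' @return 25 x 3 position matrix (joints x x/y/z).
#' @export
neutral_pose <- function(distance = 2.5, stature = 1.70) {
  s <- stature / 1.70
  p <- matrix(0, N_JOINTS, 3, dimnames = list(joint_names(), c("x", "y", "z")))
  set <- function(j, x, y, dz = 0) p[j, ] <<- c(x * s, y * s, distance + dz * s)
  set("SpineBase",      0.00, 1.00)
  set("SpineMid",       0.00, 1.20)
  set("SpineShoulder",  0.00, 1.40)
  set("Neck",           0.00, 1.46)
  set("Head",           0.00, 1.60)
  for (side in c(-1, 1)) {
    sfx <- if (side < 0) "Left" else "Right"
    set(paste0("Shoulder", sfx), side * 0.19, 1.40)
    set(paste0("Elbow", sfx),    side * 0.21, 1.10)
    set(paste0("Wrist", sfx),    side * 0.22, 0.84)
    set(paste0("Hand", sfx),     side * 0.22, 0.76)
    set(paste0("HandTip", sfx),  side * 0.22, 0.69)
    set(paste0("Thumb", sfx),    side * 0.18, 0.80, -0.03)
    set(paste0("Hip", sfx),      side * 0.10, 0.95)
    set(paste0("Knee", sfx),     side * 0.10, 0.50)
    set(paste0("Ankle", sfx),    side * 0.10, 0.08)
    set(paste0("Foot", sfx),     side * 0.10, 0.03, -0.15)
  }
  p
}

# joints strictly distal to `center` in the skeleton hierarchy
subtree_of <- function(center) {
  children <- list()
  for (b in skeleton_bones()) children[[b[1]]] <- c(children[[b[1]]], b[2])
  out <- character(0)
  frontier <- children[[center]]
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- unlist(lapply(frontier, function(j) children[[j]]))
  }
  out
}

rotation_matrix <- function(u, angle_deg) {
  th <- angle_deg * pi / 180
  u <- u / sqrt(sum(u^2))
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) * cos(th) + sin(th) * ux + (1 - cos(th)) * (u %o% u)
}

# rotate the subtree distal to the triple's center so the interior angle
# becomes theta_deg; in-plane rotation, exact
pose_triple_angle <- function(pos, triple, theta_deg) {
  tr <- as_triple(triple)
  cen <- pos[tr[2], ]
  v <- pos[tr[1], ] - cen
  w <- pos[tr[3], ] - cen
  cross <- c(v[2] * w[3] - v[3] * w[2],
             v[3] * w[1] - v[1] * w[3],
             v[1] * w[2] - v[2] * w[1])
  if (sqrt(sum(cross^2)) < 1e-9 * sqrt(sum(v^2)) * sqrt(sum(w^2))) {
    # collinear bones: bend in the sagittal plane (axis = x unless v is x)
    u <- if (abs(v[1]) < 0.9 * sqrt(sum(v^2))) c(1, 0, 0) else c(0, 0, 1)
    u <- u - v * sum(u * v) / sum(v^2)
  } else u <- cross
  theta_now <- joint_angle(pos, tr)
  R <- rotation_matrix(u, theta_deg - theta_now)
  moved <- c(tr[3], subtree_of(tr[2]))
  moved <- intersect(unique(moved), rownames(pos))
  pos[moved, ] <- sweep(sweep(pos[moved, , drop = FALSE], 2, cen) %*% t(R),
                        2, cen, `+`)
  pos
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Parameters for the synthetic gesture generator
#'
#' @param exercise_id An id from the exercise catalog (defines the scored
#'   joint triples).
#' @param amplitude Angular amplitude A in degrees (default 30); each scored
#'   joint swings `neutral_angle +/- A`.
#' @param neutral_angle Midpoint angle theta0 in degrees (default 140).
#' @param period Repetition period T in seconds (default 2).
#' @param n_reps Number of repetitions (default 5).
#' @param fs Sampling rate, Hz (default 30, the sensor rate).
#' @param distance Subject distance from the sensor, meters (default 2.5,
#'   mid recommended band).
#' @param seed RNG seed for any stochastic perturbation.
#' @return List of validated generator parameters.
#' @export
generator_params <- function(exercise_id = "side_to_side_1", amplitude = 30,
                             neutral_angle = 140, period = 2, n_reps = 5,
                             fs = 30, distance = 2.5, seed = 1) {
  stopifnot(amplitude > 0, period > 0, fs > 0, n_reps >= 1)
  if (neutral_angle - amplitude <= 0 || neutral_angle + amplitude >= 180)
    stop("neutral_angle +/- amplitude must stay inside (0, 180) degrees")
  list(exercise_id = exercise_id, amplitude = amplitude,
       neutral_angle = neutral_angle, period = period, n_reps = n_reps,
       fs = fs, distance = distance, seed = seed)
}

# the commanded angle trajectory: repetitions start and end at the minimum
# (rest) excursion, so segmentation boundaries coincide with rep boundaries
drive_angle <- function(tt, theta0, A, period) {
  theta0 - A * cos(2 * pi * tt / period)
}

synth_stream <- function(p, triples, amplitude_scale = 1, phase_jitter_sd = 0,
                         noise_sd = 0, seed = p$seed) {
  n <- round(p$n_reps * p$period * p$fs) + 1L
  t <- (seq_len(n) - 1) / p$fs
  base <- neutral_pose(p$distance)
  with_seed(seed, {
    rep_offsets <- if (phase_jitter_sd > 0)
      stats::rnorm(p$n_reps, 0, phase_jitter_sd) else numeric(p$n_reps)
    xyz <- array(0, dim = c(n, N_JOINTS, 3))
    for (i in seq_len(n)) {
      rep_i <- min(p$n_reps, 1L + floor(t[i] / p$period))
      tt <- t[i] - rep_offsets[rep_i]
      th <- drive_angle(tt, p$neutral_angle, amplitude_scale * p$amplitude,
                        p$period)
      th <- min(179.5, max(0.5, th))
      pos <- base
      for (tr in triples) pos <- pose_triple_angle(pos, tr, th)
      xyz[i, , ] <- pos
    }
    if (noise_sd > 0)
      xyz <- xyz + array(stats::rnorm(length(xyz), 0, noise_sd), dim = dim(xyz))
    skeleton_sequence(t, xyz, nominal_fs = p$fs)
  })
}

#' Generate a reference gesture: template plus ideal skeleton stream
#'
#' Drives the exercise's scored joints with
#' `theta(t) = theta0 - A cos(2 pi t / T)` (repetitions start at the rest
#' posture) through the articulated model, and returns both the ideal
#' skeleton stream and the matching [gesture_template()].
#'
#' @param params A [generator_params()] list.
#' @param catalog Exercise catalog (default built-in).
#' @return List: `template` (a `gesture_template`), `stream` (a
#'   `skeleton_sequence`), `params`, and `rep_boundaries` (ground-truth frame
#'   indices delimiting repetitions).
#' @export
generate_template <- function(params = generator_params(),
                              catalog = default_catalog()) {
  row <- which(catalog$id == params$exercise_id)
  if (length(row) != 1) stop("unknown exercise: ", params$exercise_id)
  triples <- lapply(catalog$triples[[row]], as_triple)
  n_samples <- max(8L, round(params$period * params$fs))
  grid <- seq(0, 1, length.out = n_samples)
  ref <- sapply(triples, function(tr)
    drive_angle(grid * params$period, params$neutral_angle,
                params$amplitude, params$period))
  colnames(ref) <- vapply(seq_along(triples), function(k)
    paste0(triples[[k]][2], if (sum(vapply(triples, function(x) x[2], character(1)) == triples[[k]][2]) > 1) k else ""),
    character(1))
  template <- gesture_template(params$exercise_id, ref, triples,
                               duration_s = params$period)
  stream <- synth_stream(params, triples)
  frames_per_rep <- round(params$period * params$fs)
  list(template = template, stream = stream, params = params,
       rep_boundaries = 1L + frames_per_rep * (0:params$n_reps))
}

#' Generate a perturbed execution of a reference gesture
#'
#' The template's angular drive with amplitude multiplied by
#' `amplitude_scale`, per-repetition phase offsets drawn from
#' `N(0, phase_jitter_sd^2)` seconds, and isotropic Gaussian position noise
#' `N(0, noise_sd^2)` meters added to every joint in every frame.
#'
#' @param bundle Result of [generate_template()].
#' @param amplitude_scale Multiplier s on the angular amplitude (default 1).
#' @param phase_jitter_sd SD of per-repetition phase offsets, seconds.
#' @param noise_sd SD of position noise, meters.
#' @param seed RNG seed (default: the bundle's).
#' @return A `skeleton_sequence`.
#' @export
generate_execution <- function(bundle, amplitude_scale = 1,
                               phase_jitter_sd = 0, noise_sd = 0,
                               seed = bundle$params$seed) {
  synth_stream(bundle$params, bundle$template$triples,
               amplitude_scale = amplitude_scale,
               phase_jitter_sd = phase_jitter_sd, noise_sd = noise_sd,
               seed = seed)
}

#' Generate a deterministic synthetic session log
#'
#' `sessions_per_day` sessions on each of `n_days` consecutive days, each
#' `minutes_per_session` long, with seeded minute-level jitter on start
#' times. Feeds mission and adherence logic in tests.
#'
#' @param n_days Number of consecutive days (0 gives an empty log).
#' @param sessions_per_day Sessions per calendar day.
#' @param minutes_per_session Session duration, minutes.
#' @param seed RNG seed.
#' @param start_date First day (default `"2023-01-02"`, a Monday, so a
#'   5-day block stays inside one ISO week).
#' @return Session-log data frame.
#' @export
generate_session_log <- function(n_days, sessions_per_day = 2,
                                 minutes_per_session = 30, seed = 1,
                                 start_date = "2023-01-02") {
  if (n_days == 0) return(empty_session_log())
  stopifnot(n_days >= 1, sessions_per_day >= 1, minutes_per_session > 0)
  slots <- c(9, 18, 12, 15, 20)  # hours; first `sessions_per_day` used
  if (sessions_per_day > length(slots))
    stop("at most ", length(slots), " sessions per day supported")
  day0 <- as.Date(start_date)
  with_seed(seed, {
    recs <- list()
    for (d in seq_len(n_days)) for (k in seq_len(sessions_per_day)) {
      start <- as.POSIXct(day0 + (d - 1), tz = "UTC") +
        slots[k] * 3600 + round(stats::runif(1, 0, 30)) * 60
      perf <- data.frame(exercise_id = "side_to_side_1", n_reps = 10L,
                         n_correct = 9L, mean_error_pct = 3.2)
      recs[[length(recs) + 1L]] <-
        session_record(start, minutes_per_session, performed = perf)
    }
    do.call(rbind, recs)
  })
}
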