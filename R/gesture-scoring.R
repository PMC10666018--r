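#' Construct a gesture template
#'
#' The reference ("teacher avatar") angle trajectories an execution is scored
#' against. One column per scored joint triple, sampled on a normalized time
#' grid over a single repetition.
#'
#' @param exercise_id Identifier string.
#' @param ref Numeric matrix `n_samples x n_joints` of reference angles
#'   (degrees); column names identify the scored triples. A vector is treated
#'   as a single-joint template.
#' @param triples List of joint triples (character 3-vectors or default-triple
#'   names), one per column of `ref`.
#' @param weights Nonnegative per-joint weights; normalized to sum to 1.
#'   Default uniform.
#' @param threshold Correctness threshold on the percentage error; strictly
#'   below counts as correct. Default 5.
#' @param duration_s Nominal duration of one repetition in seconds (used by
#'   the repetition segmenter). Default 2.
#' @return A `gesture_template`.
#' @export
gesture_template <- function(exercise_id, ref, triples, weights = NULL,
                             threshold = 5, duration_s = 2) {
  if (is.vector(ref)) ref <- matrix(ref, ncol = 1)
  if (nrow(ref) < 8) stop("template needs at least 8 samples per repetition")
  if (!is.list(triples)) triples <- list(triples)
  triples <- lapply(triples, as_triple)
  if (length(triples) != ncol(ref))
    stop("one triple per reference column required")
  if (is.null(colnames(ref)))
    colnames(ref) <- vapply(triples, function(tr) tr[2], character(1))
  if (is.null(weights)) weights <- rep(1, ncol(ref))
  if (any(weights < 0) || sum(weights) == 0) stop("weights must be >= 0, not all 0")
  weights <- weights / sum(weights)
  rom <- apply(ref, 2, function(col) diff(range(col)))
  if (any(rom <= 0))
    stop("template range of motion must be > 0 for every scored joint")
  structure(list(exercise_id = exercise_id, ref = ref, triples = triples,
                 weights = weights, rom = rom, threshold = threshold,
                 duration_s = duration_s),
            class = "gesture_template")
}

#' @export
print.gesture_template <- function(x, ...) {
  cat(sprintf("<gesture_template> %s: %d scored joint(s), %d samples/rep, ROM %s deg, threshold < %g%%\n",
              x$exercise_id, ncol(x$ref), nrow(x$ref),
              paste(sprintf("%.0f", x$rom), collapse = "/"), x$threshold))
  invisible(x)
}

# map a user series onto the template grid (values at n_ref normalized times)
align_series <- function(user, n_ref, alignment) {
  nu <- length(user)
  if (nu < 2) stop("user series too short to score")
  if (alignment == "linear") {
    stats::approx(seq(0, 1, length.out = nu), user,
                  xout = seq(0, 1, length.out = n_ref))$y
  } else {
    user
  }
}

# classic O(nm) DTW with unit step costs; returns for each reference index the
# mean of the user samples matched to it along the optimal path
dtw_map <- function(user, ref) {
  n <- length(user); m <- length(ref)
  cost <- abs(outer(user, ref, "-"))
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) for (j in seq_len(m))
    D[i + 1, j + 1] <- cost[i, j] + min(D[i, j + 1], D[i + 1, j], D[i, j])
  # backtrack
  i <- n; j <- m
  sums <- numeric(m); cnts <- numeric(m)
  while (i > 1 || j > 1) {
    sums[j] <- sums[j] + user[i]; cnts[j] <- cnts[j] + 1
    step <- which.min(c(D[i, j], D[i, j + 1], D[i + 1, j]))
    if (step == 1) { i <- i - 1; j <- j - 1 }
    else if (step == 2) i <- i - 1
    else j <- j - 1
  }
  sums[1] <- sums[1] + user[1]; cnts[1] <- cnts[1] + 1
  sums / pmax(cnts, 1)
}

#' Score one gesture repetition against a template
#'
#' The correctness metric: each user angle series is time-normalized onto the
#' template grid (linear by default, dynamic time warping optionally), the
#' per-joint error is the mean absolute angle deviation normalized by the
#' template's range of motion, in percent, and the overall percentage error is
#' the weight-averaged per-joint error. A repetition is correct when the error
#' is strictly below the threshold (default 5 percent).
#'
#' @param user Named list of numeric angle vectors (or `angle_series`), one
#'   per scored joint, names matching `colnames(template$ref)`; a single
#'   vector is accepted for single-joint templates.
#' @param template A [gesture_template()].
#' @param alignment `"linear"` (default) or `"dtw"`.
#' @return A `gesture_score`: list with `error_pct`, `per_joint_error`,
#'   `correct`.
#' @export
gesture_error <- function(user, template, alignment = c("linear", "dtw")) {
  alignment <- match.arg(alignment)
  stopifnot(inherits(template, "gesture_template"))
  cols <- colnames(template$ref)
  if (inherits(user, "angle_series")) user <- list(user)
  if (is.numeric(user)) user <- list(user)
  user <- lapply(user, function(u) if (inherits(u, "angle_series")) u$angles else u)
  if (is.null(names(user)) && length(user) == length(cols)) names(user) <- cols
  missing <- setdiff(cols, names(user))
  if (length(missing))
    stop("missing scored joint series: ", paste(missing, collapse = ", "))
  n_ref <- nrow(template$ref)
  per_joint <- vapply(cols, function(jn) {
    u <- user[[jn]]
    u <- u[is.finite(u)]
    if (length(u) < 2) stop("user series for ", jn, " too short after dropping flagged frames")
    ref <- template$ref[, jn]
    if (alignment == "dtw") {
      mapped <- dtw_map(u, ref)
    } else {
      mapped <- align_series(u, n_ref, "linear")
    }
    mean(abs(mapped - ref)) / template$rom[[jn]] * 100
  }, numeric(1))
  err <- sum(template$weights * per_joint)
  structure(list(error_pct = err, per_joint_error = per_joint,
                 correct = err < template$threshold,
                 threshold = template$threshold),
            class = "gesture_score")
}

#' @export
print.gesture_score <- function(x, ...) {
  cat(sprintf("<gesture_score> error %.2f%% -> %s (threshold < %g%%)\n",
              x$error_pct, if (x$correct) "correct" else "incorrect",
              x$threshold))
  invisible(x)
}

#' Segment a series into repetitions
#'
#' Repetitions are delimited at successive minima of the dominant scored
#' joint's angle (the highest-weight column), located after low-pass
#' smoothing. The series start and end also act as boundaries, and candidate
#' segments are kept only when their duration lies between half and double the
#' template repetition duration. A flat series (excursion below
#' `min_excursion`) yields no segments.
#'
#' @param series An `angle_series`, or a numeric vector with `fs` given.
#' @param template A [gesture_template()] (provides the nominal repetition
#'   duration).
#' @param fs Sampling rate when `series` is a bare vector.
#' @param min_excursion Minimum peak-to-peak excursion (degrees) for the
#'   series to count as moving at all. Default 1.
#' @return List of `c(start, end)` frame-index pairs (possibly empty).
#' @export
segment_repetitions <- function(series, template, fs = NULL,
                                min_excursion = 1) {
  if (inherits(series, "angle_series")) {
    fs <- series$fs; x <- series$angles
  } else x <- series
  if (is.null(fs)) stop("fs required for a bare numeric series")
  x <- ifelse(is.finite(x), x, NA)
  if (all(is.na(x))) return(list())
  x[is.na(x)] <- stats::approx(which(!is.na(x)), x[!is.na(x)],
                               xout = seq_along(x), rule = 2)$y[is.na(x)]
  n <- length(x)
  Tn <- template$duration_s
  if (n < 3 || diff(range(x)) < min_excursion) return(list())
  # smooth relative to the gesture period for boundary detection: keep the
  # first few harmonics of 1/Tn, discard faster noise
  cut <- max(0.75, min(5, 3 / Tn, fs / 3))
  sm <- if (n >= 9 && cut < fs / 2.2) {
    compensate_delay(butterworth_lowpass(x, fs, cutoff = cut), fs,
                     butter_group_delay(3, cut, fs))
  } else x
  r <- max(1L, floor(0.35 * Tn * fs))
  is_min <- vapply(seq_len(n), function(i) {
    win <- sm[max(1, i - r):min(n, i + r)]
    sm[i] <= min(win) + 1e-12
  }, logical(1))
  cand <- which(is_min)
  # the series start and end are boundaries themselves; edge-hold plateaus
  # must not spawn extra boundaries next to them
  cand <- cand[cand > 1 + r & cand < n - r]
  # collapse plateaus / near-duplicates closer than half a period
  bounds <- integer(0)
  for (i in cand) {
    if (length(bounds) == 0L || i - bounds[length(bounds)] > r) bounds <- c(bounds, i)
  }
  bounds <- sort(unique(c(1L, bounds, n)))
  segs <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    a <- bounds[k]; b <- bounds[k + 1L]
    dur <- (b - a) / fs
    if (dur >= Tn / 2 && dur <= 2 * Tn) segs[[length(segs) + 1L]] <- c(a, b)
  }
  segs
}

#' Score every repetition of an exercise in a skeleton stream
#'
#' Full scoring pipeline: low-pass filter joint positions, compute the scored
#' angle series, segment into repetitions on the dominant joint, and score
#' each repetition against the template.
#'
#' @param seq A `skeleton_sequence`.
#' @param template A [gesture_template()].
#' @param alignment Passed to [gesture_error()].
#' @param filter_order,filter_cutoff Butterworth parameters for the position
#'   prefilter (defaults: order 3, 5 Hz).
#' @return List of `gesture_score`, one per detected repetition, with the
#'   segment indices attached as attribute `"segments"`.
#' @export
score_session_exercise <- function(seq, template,
                                   alignment = c("linear", "dtw"),
                                   filter_order = 3, filter_cutoff = 5) {
  alignment <- match.arg(alignment)
  if (n_frames(seq) == 0L) return(list())
  fseq <- filter_positions(seq, order = filter_order, cutoff = filter_cutoff)
  fs <- if (n_frames(seq) >= 2) estimate_frame_rate(seq) else seq$nominal_fs
  tau <- if (filter_cutoff < fs / 2 && n_frames(seq) >= 3 * filter_order)
    butter_group_delay(filter_order, filter_cutoff, fs) else 0
  cols <- colnames(template$ref)
  series <- lapply(seq_along(template$triples), function(k) {
    s <- angle_series(fseq, template$triples[[k]])
    # undo the causal prefilter's constant in-band latency
    s$angles <- compensate_delay(s$angles, fs, tau)
    s
  })
  names(series) <- cols
  dominant <- series[[which.max(template$weights)]]
  segs <- segment_repetitions(dominant, template)
  lapply(segs, function(sg) {
    idx <- sg[1]:sg[2]
    user <- lapply(series, function(s) s$angles[idx])
    gesture_error(user, template, alignment = alignment)
  }) -> scores
  attr(scores, "segments") <- segs
  scores
}

#' Low-pass filter every joint coordinate of a sequence
#'
#' @param seq A `skeleton_sequence` (at least `3 * order` frames).
#' @inheritParams butterworth_lowpass
#' @return A filtered `skeleton_sequence`.
#' @export
filter_positions <- function(seq, order = 3, cutoff = 5, zero_phase = FALSE) {
  n <- n_frames(seq)
  if (n < 3 * order) return(seq)
  fs <- if (n >= 2) estimate_frame_rate(seq) else seq$nominal_fs
  if (cutoff >= fs / 2) return(seq)  # nothing below Nyquist to remove
  xyz <- seq$xyz
  for (j in seq_len(dim(xyz)[2])) for (k in 1:3)
    xyz[, j, k] <- butterworth_lowpass(xyz[, j, k], fs, order, cutoff,
                                       zero_phase)
  skeleton_sequence(seq$t, xyz, seq$tracked, seq$nominal_fs)
}

#' Estimate the amplitude scale of an execution relative to a template
#'
#' For one repetition's angle series. `method = "regression"` (default)
#' regresses the aligned, centered user trajectory on the centered reference
#' trajectory of the dominant joint — unbiased under additive measurement
#' noise. `method = "rom"` is the naive ratio of peak-to-peak ranges, which
#' is simpler but biased upward by noise extremes.
#'
#' @inheritParams gesture_error
#' @param method `"regression"` or `"rom"`.
#' @return Scalar estimate of the amplitude scale.
#' @export
estimate_amplitude_scale <- function(user, template,
                                     method = c("regression", "rom")) {
  method <- match.arg(method)
  cols <- colnames(template$ref)
  if (inherits(user, "angle_series") || is.numeric(user)) user <- list(user)
  user <- lapply(user, function(u) if (inherits(u, "angle_series")) u$angles else u)
  if (is.null(names(user)) && length(user) == length(cols)) names(user) <- cols
  jn <- cols[which.max(template$weights)]
  u <- user[[jn]]; u <- u[is.finite(u)]
  ref <- template$ref[, jn]
  if (method == "rom") return(diff(range(u)) / template$rom[[jn]])
  mapped <- align_series(u, nrow(template$ref), "linear")
  rc <- ref - mean(ref)
  # include the reference slope as a nuisance regressor: it absorbs residual
  # sub-frame misalignment (first-order Taylor term), deb iasing the scale
  dc <- c(0, diff(ref)); dc <- dc - mean(dc)
  fit <- stats::lm.fit(cbind(1, rc, dc), mapped)
  unname(fit$coefficients[2])
}

#' Recover the amplitude scale from a full skeleton stream
#'
#' Runs the scoring pipeline (position filter, delay compensation, repetition
#' segmentation) and returns the mean per-repetition amplitude-scale estimate
#' for the dominant scored joint.
#'
#' @param seq A `skeleton_sequence`.
#' @param template A [gesture_template()].
#' @param method Passed to [estimate_amplitude_scale()].
#' @return Scalar estimate (NA when no repetitions are detected).
#' @export
recover_amplitude_scale <- function(seq, template,
                                    method = c("regression", "rom")) {
  method <- match.arg(method)
  fseq <- filter_positions(seq)
  fs <- if (n_frames(seq) >= 2) estimate_frame_rate(seq) else seq$nominal_fs
  tau <- butter_group_delay(3, 5, fs)
  jn <- which.max(template$weights)
  s <- angle_series(fseq, template$triples[[jn]])
  s$angles <- compensate_delay(s$angles, fs, tau)
  segs <- segment_repetitions(s, template)
  if (length(segs) == 0) return(NA_real_)
  ests <- vapply(segs, function(sg) {
    u <- stats::setNames(list(s$angles[sg[1]:sg[2]]),
                         colnames(template$ref)[jn])
    estimate_amplitude_scale(u, template, method = method)
  }, numeric(1))
  mean(ests)
}
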