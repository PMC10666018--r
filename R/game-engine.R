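#' Default travel itinerary
#'
#' Cities visited along the travel, in unlock order, each with a coin cost.
#' The branching shown in the original travel map is flattened to a linear
#' order; alternative orders are plain data frames and can be supplied
#' anywhere an itinerary is accepted.
#'
#' @param unlock_cost Coins required to unlock each city after the first
#'   (default 50; the award schedule is a configuration choice, not a
#'   published constant).
#' @return A `data.frame` with `name`, `region`, `unlock_cost`.
#' @export
default_itinerary <- function(unlock_cost = 50) {
  cities <- c("Rome", "Florence", "Bologna", "Venice", "Milan", "Athens",
              "Paris", "London", "Barcelona", "Berlin", "Vienna", "Prague",
              "Lisbon", "Amsterdam", "Dublin", "Copenhagen", "Stockholm",
              "Helsinki", "Budapest", "Warsaw")
  data.frame(name = cities,
             region = c(rep("Italy", 5), "Greece", "France", "UK", "Spain",
                        "Germany", "Austria", "Czechia", "Portugal",
                        "Netherlands", "Ireland", "Denmark", "Sweden",
                        "Finland", "Hungary", "Poland"),
             unlock_cost = c(0, rep(unlock_cost, length(cities) - 1)),
             stringsAsFactors = FALSE)
}

#' Create a fresh player state
#'
#' @param itinerary Itinerary data frame (see [default_itinerary()]). The
#'   first city is always unlocked.
#' @return A `player_state`: `coins`, `unlocked_cities` (itinerary prefix),
#'   `completed_missions`, `session_log` (data frame), `calibrated`,
#'   `calibration` (reference measurements once calibrated).
#' @export
new_player_state <- function(itinerary = default_itinerary()) {
  structure(list(coins = 0,
                 unlocked_cities = itinerary$name[1],
                 completed_missions = character(0),
                 session_log = empty_session_log(),
                 calibrated = FALSE,
                 calibration = NULL),
            class = "player_state")
}

#' @export
print.player_state <- function(x, ...) {
  cat(sprintf("<player_state> %g coins, %d cities unlocked (%s), %d missions, %s\n",
              x$coins, length(x$unlocked_cities),
              paste(utils::tail(x$unlocked_cities, 1), collapse = ""),
              length(x$completed_missions),
              if (x$calibrated) "calibrated" else "not calibrated"))
  invisible(x)
}

#' Calibrate from a standing-still sequence
#'
#' Succeeds when the stream contains a window of at least `min_duration`
#' seconds in which (a) every joint moves slower than `stillness_threshold`,
#' (b) the posture is standing with the arms along the body (both wrists at
#' or below hip height plus `arm_tolerance_m`, trunk within
#' `trunk_tolerance_deg` of vertical), and (c) the subject is inside the
#' 0.5-4.5 m capture range. On success the reference bone lengths and neutral
#' joint angles measured over that window are stored; the calibration remains
#' valid for later sessions.
#'
#' @param seq A `skeleton_sequence`.
#' @param min_duration Minimum still-window duration in seconds (default 5).
#' @param stillness_threshold Maximum joint speed, m/s (default 0.05).
#' @param arm_tolerance_m Wrist-below-hip tolerance in meters (default 0.15).
#' @param trunk_tolerance_deg Maximum trunk tilt from vertical (default 15).
#' @return List: `success`, `reasons` (character codes among `"duration"`,
#'   `"stillness"`, `"posture"`, `"range"` when failing), and on success
#'   `bone_lengths`, `neutral_angles`, `window` (start/end seconds).
#' @export
calibrate <- function(seq, min_duration = 5, stillness_threshold = 0.05,
                      arm_tolerance_m = 0.15, trunk_tolerance_deg = 15) {
  n <- n_frames(seq)
  if (n == 0) stop("cannot calibrate from an empty sequence")
  if (n < 2 || diff(range(seq$t)) < min_duration)
    return(list(success = FALSE, reasons = "duration"))
  dt <- diff(seq$t)
  disp <- sqrt(apply((seq$xyz[-1, , , drop = FALSE] -
                      seq$xyz[-n, , , drop = FALSE])^2, c(1, 2), sum))
  still <- c(TRUE, apply(disp / dt, 1, max) < stillness_threshold)

  posture <- logical(n); range_ok <- logical(n)
  for (i in seq_len(n)) {
    pos <- seq$xyz[i, , ]
    hip_y <- mean(pos[c("HipLeft", "HipRight"), "y"])
    arms <- all(pos[c("WristLeft", "WristRight"), "y"] <= hip_y + arm_tolerance_m)
    trunk <- pos["SpineShoulder", ] - pos["SpineBase", ]
    tilt <- acos(min(1, max(-1, trunk[["y"]] / sqrt(sum(trunk^2))))) * 180 / pi
    posture[i] <- arms && tilt <= trunk_tolerance_deg
    d <- pos["SpineBase", "z"]
    range_ok[i] <- d >= 0.5 && d <= 4.5
  }
  ok <- still & posture & range_ok
  # longest run of ok frames; does any span >= min_duration?
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- NULL
  for (k in which(runs$values)) {
    if (seq$t[ends[k]] - seq$t[starts[k]] >= min_duration) {
      best <- c(starts[k], ends[k]); break
    }
  }
  if (is.null(best)) {
    reasons <- character(0)
    if (!any(still)) reasons <- c(reasons, "stillness")
    if (!any(posture)) reasons <- c(reasons, "posture")
    if (!any(range_ok)) reasons <- c(reasons, "range")
    if (length(reasons) == 0) {
      # each condition holds somewhere but never jointly long enough
      fails <- c(stillness = mean(!still), posture = mean(!posture),
                 range = mean(!range_ok))
      reasons <- names(fails)[fails > 0]
      if (length(reasons) == 0) reasons <- "duration"
    }
    return(list(success = FALSE, reasons = reasons))
  }
  idx <- best[1]:best[2]
  mean_pos <- apply(seq$xyz[idx, , , drop = FALSE], c(2, 3), mean)
  bones <- skeleton_bones()
  bl <- vapply(bones, function(b)
    sqrt(sum((mean_pos[b[1], ] - mean_pos[b[2], ])^2)), numeric(1))
  neutral <- vapply(default_triples(), function(tr)
    tryCatch(joint_angle(mean_pos, tr), error = function(e) NA_real_),
    numeric(1))
  list(success = TRUE, reasons = character(0), bone_lengths = bl,
       neutral_angles = neutral, window = seq$t[best])
}

#' Mark a player state calibrated with a calibration result
#'
#' @param state A `player_state`.
#' @param calibration Result of [calibrate()] with `success = TRUE`.
#' @return Updated `player_state`.
#' @export
apply_calibration <- function(state, calibration) {
  if (!isTRUE(calibration$success)) stop("calibration did not succeed")
  state$calibrated <- TRUE
  state$calibration <- calibration[c("bone_lengths", "neutral_angles", "window")]
  state
}

#' Award coins for correct gestures
#'
#' Each repetition scored correct earns `coins_per_correct` coins; incorrect
#' repetitions earn nothing.
#'
#' @param state A `player_state`.
#' @param scores List of `gesture_score`.
#' @param coins_per_correct Coins per correct repetition (default 1).
#' @return Updated `player_state`.
#' @export
award_coins <- function(state, scores, coins_per_correct = 1) {
  n_correct <- sum(vapply(scores, function(s) isTRUE(s$correct), logical(1)))
  state$coins <- state$coins + coins_per_correct * n_correct
  state
}

#' Try to unlock the next city in the itinerary
#'
#' Spends `unlock_cost` of the next locked city if the player holds enough
#' coins; otherwise the state is returned unchanged with a report. Unlocked
#' cities always form a prefix of the itinerary.
#'
#' @param state A `player_state`.
#' @param itinerary Itinerary data frame.
#' @return Updated `player_state`; attribute `"unlock_report"` holds one of
#'   `"unlocked"`, `"insufficient_coins"`, `"itinerary_exhausted"`.
#' @export
try_unlock_next_city <- function(state, itinerary = default_itinerary()) {
  k <- length(state$unlocked_cities)
  if (k >= nrow(itinerary)) {
    attr(state, "unlock_report") <- "itinerary_exhausted"
    return(state)
  }
  cost <- itinerary$unlock_cost[k + 1]
  if (state$coins < cost) {
    attr(state, "unlock_report") <- "insufficient_coins"
    return(state)
  }
  state$coins <- state$coins - cost
  state$unlocked_cities <- c(state$unlocked_cities, itinerary$name[k + 1])
  attr(state, "unlock_report") <- "unlocked"
  state
}

# ---- missions ----------------------------------------------------------------

#' Built-in mission set
#'
#' A mission is a predicate over the session log. Only "Methodic" (two
#' sessions per day on five consecutive calendar days) is specified by the
#' game's documentation; further missions are user-definable via
#' [mission()].
#'
#' @return Named list of missions.
#' @export
default_missions <- function() {
  list(methodic = mission(
    "methodic", "Methodic",
    predicate = function(log, params) {
      has_daily_streak(log, sessions_per_day = params$sessions_per_day,
                       consecutive_days = params$consecutive_days)
    },
    params = list(sessions_per_day = 2, consecutive_days = 5)))
}

#' Define a mission
#'
#' @param id,name Identifier and display name.
#' @param predicate `function(log, params) -> logical(1)` evaluated over a
#'   session-log data frame.
#' @param params Named list of positive parameters for the predicate.
#' @return A `mission` object.
#' @export
mission <- function(id, name, predicate, params = list()) {
  if (length(params) && any(unlist(params) <= 0))
    stop("mission parameters must be positive")
  structure(list(id = id, name = name, predicate = predicate,
                 params = params), class = "mission")
}

# >= sessions_per_day sessions on each of >= consecutive_days consecutive
# calendar days (days split at local midnight of the log's timezone)
has_daily_streak <- function(log, sessions_per_day = 2, consecutive_days = 5) {
  if (nrow(log) == 0) return(FALSE)
  days <- as.Date(log$start, tz = attr(log$start, "tzone") %||% "UTC")
  counts <- table(days)
  good <- as.Date(names(counts))[counts >= sessions_per_day]
  if (length(good) < consecutive_days) return(FALSE)
  good <- sort(good)
  streak <- 1
  for (i in seq_along(good)[-1]) {
    streak <- if (as.integer(good[i] - good[i - 1]) == 1L) streak + 1 else 1
    if (streak >= consecutive_days) return(TRUE)
  }
  consecutive_days <= 1
}

#' Evaluate missions over a session log
#'
#' Newly satisfied missions are added to `completed_missions`; completion is
#' monotone (a mission once completed is never removed).
#'
#' @param state A `player_state`.
#' @param session_log Session-log data frame (see [session_record()]);
#'   defaults to the log stored in the state.
#' @param missions Named list of missions (default [default_missions()]).
#' @return Updated `player_state`.
#' @export
evaluate_missions <- function(state, session_log = state$session_log,
                              missions = default_missions()) {
  for (m in missions) {
    if (m$id %in% state$completed_missions) next
    if (isTRUE(m$predicate(session_log, m$params)))
      state$completed_missions <- c(state$completed_missions, m$id)
  }
  state
}

# Kinect skeleton bone list (parent, child) pairs
skeleton_bones <- function() {
  list(c("SpineBase", "SpineMid"), c("SpineMid", "SpineShoulder"),
       c("SpineShoulder", "Neck"), c("Neck", "Head"),
       c("SpineShoulder", "ShoulderLeft"), c("ShoulderLeft", "ElbowLeft"),
       c("ElbowLeft", "WristLeft"), c("WristLeft", "HandLeft"),
       c("HandLeft", "HandTipLeft"), c("WristLeft", "ThumbLeft"),
       c("SpineShoulder", "ShoulderRight"), c("ShoulderRight", "ElbowRight"),
       c("ElbowRight", "WristRight"), c("WristRight", "HandRight"),
       c("HandRight", "HandTipRight"), c("WristRight", "ThumbRight"),
       c("SpineBase", "HipLeft"), c("HipLeft", "KneeLeft"),
       c("KneeLeft", "AnkleLeft"), c("AnkleLeft", "FootLeft"),
       c("SpineBase", "HipRight"), c("HipRight", "KneeRight"),
       c("KneeRight", "AnkleRight"), c("AnkleRight", "FootRight"))
}

#' Persist / restore a player state
#'
#' @param state A `player_state`.
#' @param path JSON file path.
#' @return `path` invisibly / the restored `player_state`.
#' @export
write_player_state <- function(state, path) {
  out <- state
  out$session_log <- session_log_to_list(state$session_log)
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

#' @rdname write_player_state
#' @export
read_player_state <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- new_player_state()
  st$coins <- raw$coins
  st$unlocked_cities <- as.character(raw$unlocked_cities)
  st$completed_missions <- as.character(raw$completed_missions %||% character(0))
  st$session_log <- session_log_from_list(raw$session_log)
  st$calibrated <- isTRUE(raw$calibrated)
  if (!is.null(raw$calibration) && length(raw$calibration))
    st$calibration <- raw$calibration
  st
}
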