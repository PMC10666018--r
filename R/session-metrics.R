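#' An empty session log
#'
#' The session log is a data frame with one row per training session:
#' `start` (POSIXct), `duration_min`, and list-columns
#' `exercises_performed` (data frames with `exercise_id`, `n_reps`,
#' `n_correct`, `mean_error_pct`) and `exercises_skipped` (character
#' vectors). An exercise counts as skipped when it was in the issued protocol
#' but got zero scored repetitions in the session.
#'
#' @return Zero-row session-log data frame.
#' @export
empty_session_log <- function() {
  df <- data.frame(start = as.POSIXct(character(0), tz = "UTC"),
                   duration_min = numeric(0))
  df$exercises_performed <- list()
  df$exercises_skipped <- list()
  df
}

#' Build one session record
#'
#' @param start Session start (POSIXct or parseable string; UTC assumed for
#'   strings).
#' @param duration_min Session duration in minutes (>= 0).
#' @param performed Data frame `(exercise_id, n_reps, n_correct,
#'   mean_error_pct)`; `n_correct <= n_reps` required.
#' @param skipped Character vector of skipped exercise ids.
#' @return One-row session-log data frame; rbind rows to form a log.
#' @export
session_record <- function(start, duration_min, performed = NULL,
                           skipped = character(0)) {
  if (!inherits(start, "POSIXct")) start <- as.POSIXct(start, tz = "UTC")
  if (duration_min < 0) stop("duration_min must be >= 0")
  if (is.null(performed))
    performed <- data.frame(exercise_id = character(0), n_reps = integer(0),
                            n_correct = integer(0),
                            mean_error_pct = numeric(0))
  if (any(performed$n_correct > performed$n_reps))
    stop("n_correct cannot exceed n_reps")
  df <- data.frame(start = start, duration_min = as.numeric(duration_min))
  df$exercises_performed <- list(performed)
  df$exercises_skipped <- list(as.character(skipped))
  df
}

iso_week_of <- function(start) format(as.Date(start, tz = "UTC"), "%G-W%V")

#' Minutes exercised in one ISO week, against the MS activity recommendation
#'
#' MS exercise guidance recommends at least 150 minutes of exercise per week
#' (e.g. 30 minutes per day on 5 days). Weeks are ISO-8601 (Monday-Sunday).
#'
#' @param log Session-log data frame.
#' @param week ISO week label `"YYYY-Www"` (as from `format(date,
#'   "%G-W%V")`), or a Date/POSIXct falling inside the week of interest.
#' @param recommended_min Weekly recommendation in minutes (default 150).
#' @return List: `minutes`, `meets_recommendation`.
#' @export
weekly_adherence <- function(log, week, recommended_min = 150) {
  if (inherits(week, c("Date", "POSIXct"))) week <- iso_week_of(week)
  minutes <- if (nrow(log) == 0) 0 else
    sum(log$duration_min[iso_week_of(log$start) == week])
  list(minutes = minutes, meets_recommendation = minutes >= recommended_min)
}

#' Aggregate use report
#'
#' The metrics shared with the user and clinician: session frequency and
#' duration per ISO week, exercises performed and skipped, progression ratios
#' (unlocked cities / total cities, completed missions / total missions) and
#' mean gesture correctness.
#'
#' @param log Session-log data frame.
#' @param state A `player_state`.
#' @param itinerary Itinerary data frame.
#' @param missions Named list of missions.
#' @return List: `n_sessions`, `total_minutes`, `weekly` (data frame `week`,
#'   `sessions`, `minutes`, `meets_recommendation`), `sessions_per_week`
#'   (mean over active weeks), `total_minutes_per_week` (mean),
#'   `n_exercises_performed`, `n_exercises_skipped`,
#'   `unlocked_cities_ratio`, `completed_missions_ratio`,
#'   `mean_correctness` (correct reps / scored reps; `NA` with no reps).
#' @export
use_report <- function(log, state, itinerary = default_itinerary(),
                       missions = default_missions()) {
  if (nrow(log) == 0) {
    weekly <- data.frame(week = character(0), sessions = integer(0),
                         minutes = numeric(0),
                         meets_recommendation = logical(0))
    n_perf <- n_skip <- 0L
    reps <- corr <- 0
  } else {
    wk <- iso_week_of(log$start)
    weekly <- do.call(rbind, lapply(split(seq_len(nrow(log)), wk), function(i)
      data.frame(week = wk[i[1]], sessions = length(i),
                 minutes = sum(log$duration_min[i]),
                 meets_recommendation = sum(log$duration_min[i]) >= 150)))
    rownames(weekly) <- NULL
    perf <- do.call(rbind, log$exercises_performed)
    n_perf <- nrow(perf)
    n_skip <- length(unlist(log$exercises_skipped))
    reps <- sum(perf$n_reps); corr <- sum(perf$n_correct)
  }
  list(n_sessions = nrow(log),
       total_minutes = sum(log$duration_min),
       weekly = weekly,
       sessions_per_week = if (nrow(weekly)) mean(weekly$sessions) else 0,
       total_minutes_per_week = if (nrow(weekly)) mean(weekly$minutes) else 0,
       n_exercises_performed = n_perf,
       n_exercises_skipped = n_skip,
       unlocked_cities_ratio = length(state$unlocked_cities) / nrow(itinerary),
       completed_missions_ratio =
         if (length(missions)) length(state$completed_missions) / length(missions) else 0,
       mean_correctness = if (reps > 0) corr / reps else NA_real_)
}

# ---- CSV + JSON (de)serialization -------------------------------------------

encode_performed <- function(df) {
  if (nrow(df) == 0) return("")
  paste(sprintf("%s:%d:%d:%.6g", df$exercise_id, df$n_reps, df$n_correct,
                df$mean_error_pct), collapse = ";")
}

decode_performed <- function(s) {
  if (is.na(s) || !nzchar(s))
    return(data.frame(exercise_id = character(0), n_reps = integer(0),
                      n_correct = integer(0), mean_error_pct = numeric(0)))
  parts <- strsplit(strsplit(s, ";")[[1]], ":")
  data.frame(exercise_id = vapply(parts, `[`, character(1), 1),
             n_reps = as.integer(vapply(parts, `[`, character(1), 2)),
             n_correct = as.integer(vapply(parts, `[`, character(1), 3)),
             mean_error_pct = as.numeric(vapply(parts, `[`, character(1), 4)),
             stringsAsFactors = FALSE)
}

#' Read / write a session log as CSV
#'
#' One row per session: `start` (ISO-8601 UTC), `duration_min`, `performed`
#' (`id:reps:correct:error` triples joined by `;`), `skipped` (`;`-joined
#' ids).
#'
#' @param log Session-log data frame.
#' @param path CSV path.
#' @return `path` invisibly / the session-log data frame.
#' @export
write_session_log <- function(log, path) {
  df <- data.frame(
    start = format(log$start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    duration_min = log$duration_min,
    performed = vapply(log$exercises_performed, encode_performed, character(1)),
    skipped = vapply(log$exercises_skipped, paste, character(1), collapse = ";"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "numeric", "character",
                                       "character"))
  if (nrow(df) == 0) return(empty_session_log())
  recs <- lapply(seq_len(nrow(df)), function(i) {
    skipped <- strsplit(df$skipped[i], ";")[[1]]
    session_record(as.POSIXct(df$start[i], format = "%Y-%m-%dT%H:%M:%SZ",
                              tz = "UTC"),
                   df$duration_min[i],
                   performed = decode_performed(df$performed[i]),
                   skipped = skipped[nzchar(skipped)])
  })
  do.call(rbind, recs)
}

session_log_to_list <- function(log) {
  lapply(seq_len(nrow(log)), function(i)
    list(start = format(log$start[i], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
         duration_min = log$duration_min[i],
         performed = encode_performed(log$exercises_performed[[i]]),
         skipped = log$exercises_skipped[[i]]))
}

session_log_from_list <- function(lst) {
  if (is.null(lst) || length(lst) == 0) return(empty_session_log())
  if (is.data.frame(lst)) lst <- split(lst, seq_len(nrow(lst)))
  recs <- lapply(lst, function(e) {
    session_record(as.POSIXct(e$start, format = "%Y-%m-%dT%H:%M:%SZ",
                              tz = "UTC"),
                   e$duration_min, performed = decode_performed(e$performed),
                   skipped = as.character(unlist(e$skipped)))
  })
  do.call(rbind, recs)
}
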