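#' The 25 Kinect V2 joint names
#'
#' Fixed, closed set of joint identifiers in canonical order. All skeleton
#' containers and the stream file format use this order.
#'
#' @return Character vector of length 25.
#' @export
#' @examples
#' joint_names()
joint_names <- function() {
  c("SpineBase", "SpineMid", "SpineShoulder", "Neck", "Head",
    "ShoulderLeft", "ShoulderRight", "ElbowLeft", "ElbowRight",
    "WristLeft", "WristRight", "HandLeft", "HandRight",
    "HandTipLeft", "HandTipRight", "ThumbLeft", "ThumbRight",
    "HipLeft", "HipRight", "KneeLeft", "KneeRight",
    "AnkleLeft", "AnkleRight", "FootLeft", "FootRight")
}

N_JOINTS <- 25L

#' Construct a skeleton sequence
#'
#' A `skeleton_sequence` holds time-stamped frames of 25 named 3D joint
#' positions in camera space (x right, y up, z away from the sensor, meters).
#'
#' @param t Numeric vector of frame timestamps in seconds, strictly increasing.
#' @param xyz Numeric array `n_frames x 25 x 3` (dims: frame, joint, axis) or,
#'   for a single frame, a `25 x 3` matrix.
#' @param tracked Logical matrix `n_frames x 25`; `TRUE` = tracked,
#'   `FALSE` = inferred. Defaults to all tracked.
#' @param nominal_fs Nominal frame rate in Hz (default 30, the Kinect V2 rate).
#'
#' @return An object of class `skeleton_sequence`.
#' @export
skeleton_sequence <- function(t, xyz, tracked = NULL, nominal_fs = 30) {
  t <- as.numeric(t)
  n <- length(t)
  if (n == 0L) {
    xyz <- array(numeric(0), dim = c(0L, N_JOINTS, 3L))
  }
  if (is.matrix(xyz) && n == 1L) {
    xyz <- array(xyz, dim = c(1L, nrow(xyz), ncol(xyz)))
  }
  stopifnot(is.array(xyz), length(dim(xyz)) == 3L)
  if (dim(xyz)[1] != n || dim(xyz)[2] != N_JOINTS || dim(xyz)[3] != 3L)
    stop("xyz must be n_frames x 25 x 3")
  if (n > 0 && !all(is.finite(xyz))) stop("joint coordinates must be finite")
  if (n > 1 && any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  if (!is.numeric(nominal_fs) || nominal_fs <= 0) stop("nominal_fs must be > 0")
  if (is.null(tracked)) tracked <- matrix(TRUE, n, N_JOINTS)
  dimnames(xyz) <- list(NULL, joint_names(), c("x", "y", "z"))
  colnames(tracked) <- joint_names()
  structure(list(t = t, xyz = xyz, tracked = tracked,
                 nominal_fs = as.numeric(nominal_fs)),
            class = "skeleton_sequence")
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  n <- length(x$t)
  cat(sprintf("<skeleton_sequence> %d frames, nominal %g Hz", n, x$nominal_fs))
  if (n >= 2)
    cat(sprintf(", span %.2f s, estimated %.2f Hz",
                diff(range(x$t)), estimate_frame_rate(x)))
  cat("\n")
  invisible(x)
}

#' Number of frames in a skeleton sequence
#' @param seq A `skeleton_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) length(seq$t)

#' Extract one frame from a sequence
#' @param seq A `skeleton_sequence`.
#' @param i Frame index.
#' @return A list with `t` (seconds), `positions` (25 x 3 matrix) and
#'   `tracked` (logical vector).
#' @export
get_frame <- function(seq, i) {
  stopifnot(i >= 1, i <= n_frames(seq))
  pos <- seq$xyz[i, , , drop = TRUE]
  dim(pos) <- c(N_JOINTS, 3L)
  dimnames(pos) <- list(joint_names(), c("x", "y", "z"))
  list(t = seq$t[i], positions = pos, tracked = seq$tracked[i, ])
}

#' Estimate the frame rate of a skeleton sequence
#'
#' Median of reciprocal inter-frame intervals. The median makes the estimate
#' robust to occasional dropped frames, which show up as double-length gaps.
#'
#' @param seq A `skeleton_sequence` with at least 2 frames.
#' @return Estimated rate in Hz.
#' @export
estimate_frame_rate <- function(seq) {
  if (n_frames(seq) < 2)
    stop("cannot estimate a frame rate from fewer than 2 frames")
  stats::median(1 / diff(seq$t))
}

#' Subject distance from the sensor
#'
#' Defined as the z coordinate of SpineBase (depth along the optical axis),
#' not the Euclidean norm; this matches the colloquial "distance from the
#' sensor" and is what the capture-range limits constrain.
#'
#' @param frame A frame as returned by [get_frame()], or a 25 x 3 position
#'   matrix with joint row names.
#' @return Distance in meters.
#' @export
subject_distance <- function(frame) {
  pos <- if (is.list(frame)) frame$positions else frame
  unname(pos["SpineBase", "z"])
}

#' Capture-range and recommended-band placement check
#'
#' The sensor tracks within 0.5--4.5 m; users are advised to stand 2--3 m
#' away. Both intervals are closed.
#'
#' @inheritParams subject_distance
#' @return List with logical flags `in_capture_range` and
#'   `in_recommended_band`, plus `distance_m`.
#' @export
placement_check <- function(frame) {
  d <- subject_distance(frame)
  list(in_capture_range = d >= 0.5 & d <= 4.5,
       in_recommended_band = d >= 2.0 & d <= 3.0,
       distance_m = d)
}

# ---- stream I/O --------------------------------------------------------------

STREAM_HEADER_RE <- "^#msfit-skeleton\\s+v1(\\s+fs=([0-9.]+))?\\s*$"

#' Write a skeleton sequence to a stream file
#'
#' Line-delimited v1 format: header `#msfit-skeleton v1 fs=<Hz>`, then one
#' frame per line: timestamp followed by 75 coordinates (25 joints x, y, z in
#' [joint_names()] order), whitespace separated.
#'
#' @param seq A `skeleton_sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_skeleton_stream <- function(seq, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#msfit-skeleton v1 fs=%.10g", seq$nominal_fs), con)
  n <- n_frames(seq)
  if (n > 0) {
    # frame i row: t, then x,y,z per joint in canonical order
    flat <- matrix(aperm(seq$xyz, c(3L, 2L, 1L)), nrow = n, byrow = TRUE)
    rows <- cbind(seq$t, flat)
    writeLines(apply(rows, 1L, function(r)
      paste(formatC(r, format = "g", digits = 17), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a skeleton stream file
#'
#' Accepts the v1 line format written by [write_skeleton_stream()], or a CSV
#' with named columns `t, <Joint>_x, <Joint>_y, <Joint>_z`.
#'
#' @param path Input file path.
#' @param on_error `"skip"` drops malformed frames (wrong field count or
#'   non-finite values); `"fail"` raises an error. Non-monotone timestamps are
#'   always an error.
#' @return A `skeleton_sequence`.
#' @export
read_skeleton_stream <- function(path, on_error = c("skip", "fail")) {
  on_error <- match.arg(on_error)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  first <- if (length(lines)) lines[[1]] else ""
  if (grepl("^t,", first)) return(read_skeleton_csv(path, on_error))

  fs <- 30
  if (length(lines) && grepl(STREAM_HEADER_RE, lines[1])) {
    m <- regmatches(lines[1], regexec(STREAM_HEADER_RE, lines[1]))[[1]]
    if (length(m) >= 3 && nzchar(m[3])) fs <- as.numeric(m[3])
    lines <- lines[-1]
  }
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L)
    return(skeleton_sequence(numeric(0), NULL, nominal_fs = fs))

  parse_one <- function(ln) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[,[:space:]]+")[[1]]))
    if (length(f) != 1L + 3L * N_JOINTS || any(!is.finite(f))) NULL else f
  }
  parsed <- lapply(lines, parse_one)
  bad <- vapply(parsed, is.null, logical(1))
  if (any(bad) && on_error == "fail")
    stop(sprintf("malformed frame at line %d", which(bad)[1] + 1L))
  parsed <- parsed[!bad]
  if (length(parsed) == 0L)
    return(skeleton_sequence(numeric(0), NULL, nominal_fs = fs))
  mat <- do.call(rbind, parsed)
  t <- mat[, 1]
  if (any(diff(t) <= 0)) stop("non-monotone timestamps in stream")
  xyz <- aperm(array(t(mat[, -1, drop = FALSE]),
                     dim = c(3L, N_JOINTS, nrow(mat))), c(3L, 2L, 1L))
  skeleton_sequence(t, xyz, nominal_fs = fs)
}

read_skeleton_csv <- function(path, on_error) {
  df <- utils::read.csv(path, check.names = FALSE)
  want <- as.vector(t(outer(joint_names(), c("x", "y", "z"),
                            function(j, a) paste0(j, "_", a))))
  missing <- setdiff(c("t", want), names(df))
  if (length(missing))
    stop("CSV stream is missing columns: ", paste(missing, collapse = ", "))
  mat <- as.matrix(df[, want])
  ok <- is.finite(df$t) & apply(is.finite(mat), 1L, all)
  if (any(!ok) && on_error == "fail")
    stop(sprintf("malformed frame at CSV row %d", which(!ok)[1]))
  t <- df$t[ok]
  if (any(diff(t) <= 0)) stop("non-monotone timestamps in stream")
  xyz <- aperm(array(t(mat[ok, , drop = FALSE]),
                     dim = c(3L, N_JOINTS, sum(ok))), c(3L, 2L, 1L))
  skeleton_sequence(t, xyz)
}

#' Summary validation of a skeleton stream
#'
#' @param seq A `skeleton_sequence`.
#' @return List: `n_frames`, `estimated_fs` (NA when < 2 frames),
#'   `frac_in_capture_range`, `frac_in_recommended_band`.
#' @export
validate_stream <- function(seq) {
  n <- n_frames(seq)
  fs <- if (n >= 2) estimate_frame_rate(seq) else NA_real_
  if (n > 0) {
    d <- seq$xyz[, "SpineBase", "z"]
    cap <- mean(d >= 0.5 & d <= 4.5)
    rec <- mean(d >= 2.0 & d <= 3.0)
  } else cap <- rec <- NA_real_
  list(n_frames = n, estimated_fs = fs,
       frac_in_capture_range = cap, frac_in_recommended_band = rec)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
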