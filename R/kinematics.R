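#' Default anatomical joint triples
#'
#' Named (proximal, center, distal) triples for the common clinical angles.
#' The angle is measured at `center` between the two bone vectors. Fully
#' overridable per exercise in the catalog.
#'
#' @return Named list of character triples.
#' @export
default_triples <- function() {
  list(
    knee_left      = c("HipLeft", "KneeLeft", "AnkleLeft"),
    knee_right     = c("HipRight", "KneeRight", "AnkleRight"),
    elbow_left     = c("ShoulderLeft", "ElbowLeft", "WristLeft"),
    elbow_right    = c("ShoulderRight", "ElbowRight", "WristRight"),
    shoulder_left  = c("SpineShoulder", "ShoulderLeft", "ElbowLeft"),
    shoulder_right = c("SpineShoulder", "ShoulderRight", "ElbowRight"),
    hip_left       = c("SpineBase", "HipLeft", "KneeLeft"),
    hip_right      = c("SpineBase", "HipRight", "KneeRight"),
    neck           = c("SpineShoulder", "Neck", "Head"),
    trunk          = c("SpineBase", "SpineMid", "SpineShoulder")
  )
}

as_triple <- function(triple) {
  if (is.character(triple) && length(triple) == 1L) {
    tr <- default_triples()[[triple]]
    if (is.null(tr)) stop("unknown named triple: ", triple)
    return(tr)
  }
  if (!is.character(triple) || length(triple) != 3L)
    stop("a joint triple is 3 joint names (proximal, center, distal)")
  if (anyDuplicated(triple)) stop("joint triple must name 3 distinct joints")
  bad <- setdiff(triple, joint_names())
  if (length(bad)) stop("unknown joint name(s): ", paste(bad, collapse = ", "))
  triple
}

#' Interior joint angle at a frame
#'
#' 3D interior angle at `center` between the vectors center->proximal and
#' center->distal, in degrees within \[0, 180\]. Invariant under rigid
#' rotation/translation of the skeleton.
#'
#' @param frame A frame (from [get_frame()]) or a 25 x 3 position matrix.
#' @param triple A character 3-vector (proximal, center, distal) or the name
#'   of a default triple, e.g. `"knee_left"`.
#' @return Angle in degrees.
#' @export
#' @examples
#' pos <- matrix(0, 25, 3, dimnames = list(joint_names(), c("x", "y", "z")))
#' pos["HipLeft", ] <- c(0, 1, 0); pos["AnkleLeft", ] <- c(1, 0, 0)
#' joint_angle(pos, c("HipLeft", "KneeLeft", "AnkleLeft"))  # 90
joint_angle <- function(frame, triple) {
  pos <- if (is.list(frame)) frame$positions else frame
  tr <- as_triple(triple)
  u <- pos[tr[1], ] - pos[tr[2], ]
  v <- pos[tr[3], ] - pos[tr[2], ]
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("degenerate geometry: zero-length bone at ", tr[2])
  cosang <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Joint-angle time series over a sequence
#'
#' Applies [joint_angle()] frame-wise. Frames with degenerate geometry are
#' flagged `NA`, not fatal.
#'
#' @param seq A `skeleton_sequence`.
#' @param triple As in [joint_angle()].
#' @return An `angle_series`: list with `angles` (degrees, `NA` where
#'   degenerate), `t` (seconds), `fs` (nominal Hz) and `triple`.
#' @export
angle_series <- function(seq, triple) {
  tr <- as_triple(triple)
  n <- n_frames(seq)
  ang <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    pos <- seq$xyz[i, , ]
    ang[i] <- tryCatch(joint_angle(pos, tr), error = function(e) NA_real_)
  }
  structure(list(angles = ang, t = seq$t, fs = seq$nominal_fs, triple = tr),
            class = "angle_series")
}

#' Time derivative of a series
#'
#' Central differences on interior points, one-sided at the edges.
#' Denominators come from the actual timestamps when available, so the result
#' is robust to dropped frames. Units: input unit per second (degrees/s for an
#' angle series; apply twice or use `order = 2` for degrees/s^2).
#'
#' @param x Numeric vector, or an `angle_series`.
#' @param t Timestamps (seconds); defaults to a uniform grid at `fs`.
#' @param fs Sampling rate, used only when `t` is missing.
#' @param order 1 (velocity) or 2 (acceleration).
#' @return Numeric vector of the same length.
#' @export
derivative <- function(x, t = NULL, fs = NULL, order = 1) {
  if (inherits(x, "angle_series")) {
    t <- x$t; x <- x$angles
  }
  if (!order %in% c(1, 2)) stop("order must be 1 or 2")
  n <- length(x)
  if (n < 3) stop("need at least 3 samples to differentiate")
  if (is.null(t)) {
    if (is.null(fs)) stop("supply timestamps t or a rate fs")
    t <- (seq_len(n) - 1) / fs
  }
  d <- numeric(n)
  i <- 2:(n - 1)
  d[i] <- (x[i + 1] - x[i - 1]) / (t[i + 1] - t[i - 1])
  d[1] <- (x[2] - x[1]) / (t[2] - t[1])
  d[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  if (order == 2) d <- derivative(d, t = t) else d
}
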