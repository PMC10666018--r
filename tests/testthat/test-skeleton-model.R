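test_that("joint set is closed with 25 distinct names", {
  jn <- joint_names()
  expect_length(jn, 25)
  expect_false(anyDuplicated(jn) > 0)
})

test_that("stream write/read round-trips field by field", {
  seq <- generate_template(generator_params(n_reps = 1, seed = 3))$stream
  path <- withr::local_tempfile(fileext = ".txt")
  write_skeleton_stream(seq, path)
  back <- read_skeleton_stream(path)
  expect_equal(back$t, seq$t)
  expect_equal(back$xyz, seq$xyz, tolerance = 1e-12)
  expect_equal(back$nominal_fs, seq$nominal_fs)
})

test_that("empty and header-only files give empty sequences", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), path)
  expect_equal(n_frames(read_skeleton_stream(path)), 0L)
  writeLines("#msfit-skeleton v1 fs=30", path)
  s <- read_skeleton_stream(path)
  expect_equal(n_frames(s), 0L)
  expect_equal(s$nominal_fs, 30)
})

test_that("a uniform 90-frame stream at 1/30 s estimates 30 Hz", {
  seq <- static_sequence(n = 90, fs = 30)
  path <- withr::local_tempfile(fileext = ".txt")
  write_skeleton_stream(seq, path)
  expect_equal(estimate_frame_rate(read_skeleton_stream(path)), 30)
})

test_that("frame-rate estimate uses the median interval", {
  pose <- neutral_pose()
  mk <- function(t) skeleton_sequence(
    t, array(rep(pose, each = length(t)), c(length(t), 25, 3)))
  expect_equal(estimate_frame_rate(mk(c(0, 1, 2) / 30)), 30)
  expect_equal(estimate_frame_rate(mk(c(0, 0.1, 0.2))), 10)
  # one dropped frame: intervals 1/30, 2/30, 1/30 -> median 1/30
  expect_equal(estimate_frame_rate(mk(c(0, 1, 3, 4) / 30)), 30)
  expect_error(estimate_frame_rate(mk(0)), "fewer than 2")
})

test_that("subject distance is SpineBase z, including through the generator", {
  pose <- neutral_pose(distance = 2.5)
  expect_equal(subject_distance(pose), 2.5)
  pose2 <- neutral_pose(distance = 0.4)
  expect_equal(subject_distance(pose2), 0.4)
  st <- generate_template(generator_params(n_reps = 1, distance = 3.2))$stream
  expect_equal(subject_distance(get_frame(st, 1)), 3.2, tolerance = 1e-9)
})

test_that("placement checks use closed intervals and nest correctly", {
  at <- function(d) placement_check(neutral_pose(distance = d))
  expect_equal(at(2.5)[1:2], list(in_capture_range = TRUE, in_recommended_band = TRUE))
  expect_equal(at(0.4)[1:2], list(in_capture_range = FALSE, in_recommended_band = FALSE))
  expect_equal(at(4.0)[1:2], list(in_capture_range = TRUE, in_recommended_band = FALSE))
  expect_true(at(0.5)$in_capture_range)
  expect_true(at(4.5)$in_capture_range)
  expect_true(at(2.0)$in_recommended_band)
  expect_true(at(3.0)$in_recommended_band)
  for (d in seq(0.1, 5, by = 0.1)) {
    pc <- at(d)
    if (pc$in_recommended_band) expect_true(pc$in_capture_range)
  }
})

test_that("malformed frames are skipped or fail per on_error", {
  seq <- static_sequence(n = 4)
  path <- withr::local_tempfile(fileext = ".txt")
  write_skeleton_stream(seq, path)
  lines <- readLines(path)
  lines[3] <- paste(strsplit(lines[3], " ")[[1]][1:20], collapse = " ")  # truncated frame
  writeLines(lines, path)
  skipped <- read_skeleton_stream(path, on_error = "skip")
  expect_equal(n_frames(skipped), 3L)
  expect_error(read_skeleton_stream(path, on_error = "fail"), "malformed")
})

test_that("non-monotone timestamps always fail", {
  seq <- static_sequence(n = 3)
  path <- withr::local_tempfile(fileext = ".txt")
  write_skeleton_stream(seq, path)
  lines <- readLines(path)
  writeLines(lines[c(1, 3, 2, 4)], path)
  expect_error(read_skeleton_stream(path), "monotone")
})

test_that("CSV input with named columns is accepted", {
  seq <- static_sequence(n = 5)
  cols <- as.vector(t(outer(joint_names(), c("x", "y", "z"), paste, sep = "_")))
  flat <- matrix(aperm(seq$xyz, c(3, 2, 1)), nrow = 5, byrow = TRUE)
  df <- data.frame(t = seq$t, flat)
  names(df) <- c("t", cols)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  back <- read_skeleton_stream(path)
  expect_equal(back$xyz, seq$xyz, tolerance = 1e-12)
  v <- validate_stream(back)
  expect_equal(v$n_frames, 5L)
  expect_equal(v$frac_in_recommended_band, 1)
})
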