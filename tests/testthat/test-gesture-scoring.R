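test_that("identical execution scores exactly zero and correct", {
  tmpl <- sin_template()
  sc <- gesture_error(list(KneeLeft = tmpl$ref[, 1]), tmpl)
  expect_identical(sc$error_pct, 0)
  expect_true(sc$correct)
})

test_that("the 5% threshold is strict", {
  # dyadic ramp: ROM 80, constant offset 4 -> error exactly 4/80 = 5.0%
  ref <- seq(100, 180, length.out = 41)
  tmpl <- gesture_template("ramp", ref, list("knee_left"))
  sc <- gesture_error(list(KneeLeft = ref + 4), tmpl)
  expect_equal(sc$error_pct, 5)
  expect_false(sc$correct)
  sc2 <- gesture_error(list(KneeLeft = ref + 3.9), tmpl)
  expect_true(sc2$correct)
})

test_that("amplitude-scaled sinusoids match the closed-form error", {
  # independent oracle: dense quadrature of mean|(s-1) A sin| / (2A)
  quad_error <- function(s, n = 20001) {
    u <- seq(0, 1, length.out = n)
    mean(abs((s - 1) * sin(2 * pi * u))) / 2 * 100
  }
  tmpl <- sin_template(A = 30, theta0 = 90)
  theta0 <- 90
  for (s in c(1.05, 1.1, 1.2, 1.5)) {
    user <- theta0 + s * (tmpl$ref[, 1] - theta0)
    err <- gesture_error(list(KneeLeft = user), tmpl)$error_pct
    expect_lt(abs(err - quad_error(s)), 0.5)
    expect_lt(abs(err - (2 / pi) * abs(s - 1) / 2 * 100), 0.5)
  }
  expect_true(gesture_error(list(KneeLeft = theta0 + 1.1 * (tmpl$ref[, 1] - theta0)),
                            tmpl)$correct)   # ~3.18%
  expect_false(gesture_error(list(KneeLeft = theta0 + 1.5 * (tmpl$ref[, 1] - theta0)),
                             tmpl)$correct)  # ~15.9%
})

test_that("error is nondecreasing in pure amplitude scaling", {
  tmpl <- sin_template()
  errs <- vapply(seq(1, 1.5, by = 0.05), function(s)
    gesture_error(list(KneeLeft = 90 + s * (tmpl$ref[, 1] - 90)), tmpl)$error_pct,
    numeric(1))
  expect_true(all(diff(errs) >= -1e-12))
})

test_that("weighted error is convex in the per-joint errors", {
  u <- seq(0, 1, length.out = 64)
  ref <- cbind(90 + 30 * sin(2 * pi * u), 120 + 20 * sin(2 * pi * u))
  tmpl <- gesture_template("two_joint", ref,
                           list("knee_left", "elbow_left"),
                           weights = c(0.3, 0.7))
  user <- list(KneeLeft = 90 + 1.2 * (ref[, 1] - 90),
               ElbowLeft = 120 + 1.05 * (ref[, 2] - 120))
  sc <- gesture_error(user, tmpl)
  pj <- sort(unname(sc$per_joint_error))
  expect_gte(sc$error_pct, pj[1])
  expect_lte(sc$error_pct, pj[2])
  expect_equal(sc$error_pct,
               sum(c(0.3, 0.7) * sc$per_joint_error))
})

test_that("scoring is deterministic and validates inputs", {
  tmpl <- sin_template()
  user <- list(KneeLeft = tmpl$ref[, 1] * 1.02)
  s1 <- gesture_error(user, tmpl)
  s2 <- gesture_error(user, tmpl)
  expect_identical(s1, s2)
  expect_error(gesture_error(list(Wrong = tmpl$ref[, 1]), tmpl), "missing scored joint")
  expect_error(gesture_template("flat", rep(5, 20), list("knee_left")),
               "range of motion")
})

test_that("dtw alignment handles within-repetition speed variation better", {
  tmpl <- sin_template(n = 101)
  # same path traversed at varying speed: monotone time warp of one period
  u <- seq(0, 1, length.out = 151)
  warp <- u + 0.08 * sin(pi * u)^2
  warp <- warp / max(warp)
  user <- 90 + 30 * sin(2 * pi * warp)
  lin <- gesture_error(list(KneeLeft = user), tmpl, alignment = "linear")
  dtw <- gesture_error(list(KneeLeft = user), tmpl, alignment = "dtw")
  expect_lt(dtw$error_pct, lin$error_pct)
  ident <- gesture_error(list(KneeLeft = tmpl$ref[, 1]), tmpl, alignment = "dtw")
  expect_equal(ident$error_pct, 0)
})

test_that("repetition segmentation finds the generator's boundaries", {
  b <- generate_template(generator_params(n_reps = 3, seed = 2))
  s <- angle_series(b$stream, b$template$triples[[1]])
  segs <- segment_repetitions(s, b$template)
  expect_length(segs, 3)
  found <- c(segs[[1]][1], vapply(segs, `[`, numeric(1), 2))
  expect_true(all(abs(found - b$rep_boundaries) <= 2))
})

test_that("degenerate segmentation inputs", {
  tmpl <- sin_template()
  expect_length(segment_repetitions(rep(90, 100), tmpl, fs = 30), 0)
  b1 <- generate_template(generator_params(n_reps = 1))
  s1 <- angle_series(b1$stream, b1$template$triples[[1]])
  expect_length(segment_repetitions(s1, b1$template), 1)
})

test_that("end-to-end session scoring on known ground truth", {
  b <- generate_template(generator_params(n_reps = 5))
  scores <- score_session_exercise(b$stream, b$template)
  expect_length(scores, 5)
  errs <- vapply(scores, `[[`, numeric(1), "error_pct")
  expect_true(all(errs < 1))
  expect_true(all(vapply(scores, `[[`, logical(1), "correct")))

  over <- score_session_exercise(generate_execution(b, amplitude_scale = 1.5),
                                 b$template)
  expect_gt(length(over), 0)
  expect_true(all(vapply(over, `[[`, numeric(1), "error_pct") > 5))
  expect_false(any(vapply(over, `[[`, logical(1), "correct")))

  empty <- skeleton_sequence(numeric(0), NULL)
  expect_length(score_session_exercise(empty, b$template), 0)
})

test_that("templates round-trip through CSV + sidecar", {
  b <- generate_template(generator_params(exercise_id = "one_leg_circle_1"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_gesture_template(b$template, path)
  back <- read_gesture_template(path)
  expect_equal(back$ref, b$template$ref, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$weights, b$template$weights)
  expect_equal(back$threshold, b$template$threshold)
  expect_equal(back$triples, b$template$triples)
})
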