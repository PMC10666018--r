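test_that("calibration succeeds on a 6 s standing-still stream in range", {
  res <- calibrate(static_sequence(n = 181, distance = 2.5))
  expect_true(res$success)
  expect_length(res$reasons, 0)
  expect_true(all(res$bone_lengths > 0))
  expect_equal(unname(res$neutral_angles[["knee_left"]]), 180, tolerance = 1e-6)
  st <- apply_calibration(new_player_state(), res)
  expect_true(st$calibrated)
})

test_that("calibration fails with reason codes", {
  short <- calibrate(static_sequence(n = 91))          # 3 s
  expect_false(short$success)
  expect_true("duration" %in% short$reasons)

  near <- calibrate(static_sequence(n = 181, distance = 0.3))
  expect_false(near$success)
  expect_true("range" %in% near$reasons)

  pose <- neutral_pose()
  pose[c("WristLeft", "WristRight"), "y"] <- 1.55      # arms raised
  up <- calibrate(static_sequence(n = 181, pose = pose))
  expect_false(up$success)
  expect_true("posture" %in% up$reasons)

  moving <- generate_template(generator_params(n_reps = 4))$stream
  mv <- calibrate(moving)
  expect_false(mv$success)
  expect_true("stillness" %in% mv$reasons)

  expect_error(calibrate(skeleton_sequence(numeric(0), NULL)), "empty")
})

fake_scores <- function(flags) lapply(flags, function(f)
  structure(list(error_pct = if (f) 1 else 9, correct = f, threshold = 5),
            class = "gesture_score"))

test_that("coins are awarded per correct gesture only", {
  st <- new_player_state()
  st <- award_coins(st, fake_scores(c(TRUE, TRUE, FALSE, TRUE, FALSE)))
  expect_equal(st$coins, 3)
  expect_equal(award_coins(st, list())$coins, 3)
  expect_equal(award_coins(st, fake_scores(c(FALSE, FALSE)))$coins, 3)
  expect_equal(award_coins(st, fake_scores(TRUE), coins_per_correct = 5)$coins, 8)
  # additive over concatenated score lists
  a <- fake_scores(c(TRUE, FALSE)); b <- fake_scores(c(TRUE, TRUE))
  expect_equal(award_coins(award_coins(st, a), b)$coins,
               award_coins(st, c(a, b))$coins)
})

test_that("city unlocking respects cost boundaries and prefix order", {
  itin <- default_itinerary(unlock_cost = 50)
  st <- new_player_state(itin)
  st$coins <- 49
  st1 <- try_unlock_next_city(st, itin)
  expect_equal(attr(st1, "unlock_report"), "insufficient_coins")
  expect_equal(st1$unlocked_cities, "Rome")
  st$coins <- 50
  st2 <- try_unlock_next_city(st, itin)
  expect_equal(attr(st2, "unlock_report"), "unlocked")
  expect_equal(st2$coins, 0)
  expect_equal(st2$unlocked_cities, c("Rome", "Florence"))
  st$coins <- 100
  st3 <- try_unlock_next_city(try_unlock_next_city(st, itin), itin)
  expect_equal(st3$unlocked_cities, c("Rome", "Florence", "Bologna"))
  expect_equal(st3$coins, 0)
})

test_that("exhausted itineraries are a reported no-op", {
  itin <- default_itinerary()[1:2, ]
  st <- new_player_state(itin)
  st$coins <- 500
  st <- try_unlock_next_city(st, itin)
  st2 <- try_unlock_next_city(st, itin)
  expect_equal(attr(st2, "unlock_report"), "itinerary_exhausted")
  expect_equal(st2$unlocked_cities, st$unlocked_cities)
})

test_that("the Methodic mission needs 2 sessions/day for 5 consecutive days", {
  st <- new_player_state()
  full <- generate_session_log(5, sessions_per_day = 2)
  expect_true("methodic" %in%
              evaluate_missions(st, full)$completed_missions)
  partial <- rbind(generate_session_log(4, sessions_per_day = 2),
                   generate_session_log(1, sessions_per_day = 1,
                                        start_date = "2023-01-06"))
  expect_false("methodic" %in%
               evaluate_missions(st, partial)$completed_missions)
  expect_length(evaluate_missions(st, empty_session_log())$completed_missions, 0)
})

test_that("a gap in the streak resets Methodic", {
  st <- new_player_state()
  gap <- rbind(generate_session_log(3, 2, start_date = "2023-01-02"),
               generate_session_log(2, 2, start_date = "2023-01-07"))  # skips Jan 5
  expect_false("methodic" %in% evaluate_missions(st, gap)$completed_missions)
  longer <- rbind(gap, generate_session_log(3, 2, start_date = "2023-01-09"))
  expect_true("methodic" %in% evaluate_missions(st, longer)$completed_missions)
})

test_that("mission completion is monotone under log growth", {
  st <- new_player_state()
  st <- evaluate_missions(st, generate_session_log(5, 2))
  expect_true("methodic" %in% st$completed_missions)
  st2 <- evaluate_missions(st, empty_session_log())
  expect_true("methodic" %in% st2$completed_missions)
})

test_that("player state persists through JSON", {
  st <- new_player_state()
  st$coins <- 17
  st <- try_unlock_next_city(st, default_itinerary(unlock_cost = 10))
  st$session_log <- generate_session_log(2, 1)
  st <- evaluate_missions(st)
  path <- withr::local_tempfile(fileext = ".json")
  write_player_state(st, path)
  back <- read_player_state(path)
  expect_equal(back$coins, st$coins)
  expect_equal(back$unlocked_cities, st$unlocked_cities)
  expect_equal(back$completed_missions, st$completed_missions)
  expect_equal(back$session_log$start, st$session_log$start)
  expect_equal(back$session_log$duration_min, st$session_log$duration_min)
})

test_that("random operation interleavings preserve the state invariants", {
  itin <- default_itinerary(unlock_cost = 7)
  set.seed(42)
  st <- new_player_state(itin)
  for (i in 1:200) {
    op <- sample(3, 1)
    if (op == 1) st <- award_coins(st, fake_scores(runif(sample(4, 1)) > 0.4))
    else if (op == 2) st <- try_unlock_next_city(st, itin)
    else st <- evaluate_missions(st, generate_session_log(sample(0:5, 1), 2))
    expect_gte(st$coins, 0)
    k <- length(st$unlocked_cities)
    expect_identical(st$unlocked_cities, itin$name[seq_len(k)])
  }
})
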