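test_that("item statistics match hand-checked rows", {
  s <- item_stats(c(3, 3, 3, 5, 5, 5, 5, 5, 5))
  expect_equal(s$mean, 4.33)
  expect_equal(s$sd, 1.00)
  s2 <- item_stats(c(5, 4, 4, 4, 4, 4, 4, 4, 2))
  expect_equal(s2$mean, 3.89)
  expect_equal(s2$sd, 0.78)
  s3 <- item_stats(rep(4, 9))
  expect_equal(s3$mean, 4)
  expect_equal(s3$sd, 0)
})

test_that("sample (n-1) SD is the reproducing convention", {
  x <- c(5, 4, 4, 4, 4, 4, 4, 4, 2)
  n_denominator <- sqrt(mean((x - mean(x))^2))
  expect_equal(round_half_up(n_denominator, 2), 0.74)  # would NOT match 0.78
  expect_equal(item_stats(x)$sd, 0.78)
})

test_that("mean/sd agree with a brute-force two-pass oracle", {
  set.seed(31)
  for (i in 1:20) {
    x <- sample(1:5, sample(2:12, 1), replace = TRUE)
    o <- brute_stats(x)
    s <- item_stats(x)
    expect_equal(s$mean, round_half_up(o["mean"], 2), ignore_attr = TRUE)
    expect_equal(s$sd, round_half_up(o["sd"], 2), ignore_attr = TRUE)
  }
})

test_that("statistics are invariant to participant permutation", {
  tab <- usability_fixture()
  set.seed(7)
  shuffled <- tab
  shuffled$scores <- tab$scores[sample(nrow(tab$scores)), ]
  expect_equal(stats_table(shuffled)[, c("mean", "sd")],
               stats_table(tab)[, c("mean", "sd")])
})

test_that("the packaged fixture reproduces all 16 printed statistics", {
  st <- stats_table(usability_fixture())
  expect_equal(st$item_id,
               c("ease_hw_instructions", "ease_hw_setup",
                 "ease_use_instructions", "ease_interface", "playability",
                 "enjoyment_trainer", "satisfaction", "acceptance_home"))
  expect_equal(st$mean, c(3.89, 3.78, 4.11, 3.78, 3.89, 4.11, 3.89, 4.33))
  expect_equal(st$sd,   c(0.33, 0.67, 0.33, 0.44, 0.78, 0.60, 0.60, 1.00))
  expect_true(all(st$n == 9))
})

test_that("duplicating a participant shifts the stats as the oracle predicts", {
  tab <- usability_fixture()
  dup <- tab
  dup$scores <- rbind(tab$scores, tab$scores[3, , drop = FALSE])
  st <- stats_table(dup)
  for (j in seq_len(ncol(dup$scores))) {
    o <- brute_stats(dup$scores[, j])
    expect_equal(st$mean[j], round_half_up(o["mean"], 2), ignore_attr = TRUE)
    expect_equal(st$sd[j], round_half_up(o["sd"], 2), ignore_attr = TRUE)
  }
})

test_that("item mean range", {
  st <- stats_table(usability_fixture())
  expect_equal(item_mean_range(st), c(3.78, 4.33))
  one <- data.frame(mean = 4.1)
  expect_equal(item_mean_range(one), c(4.1, 4.1))
  two <- data.frame(mean = c(3.5, 4.5))
  expect_equal(item_mean_range(two), c(3.5, 4.5))
  expect_error(item_mean_range(data.frame(mean = numeric(0))), "no items")
})

test_that("score validation and questionnaire IO", {
  expect_error(item_stats(c(3)), "at least 2")
  expect_error(item_stats(c(3, 6)), "\\[1, 5\\]")
  expect_error(item_stats(c(3, 2.5)), "integers")
  tab <- usability_fixture()
  expect_equal(dim(tab$scores), c(9L, 8L))
  expect_false(anyNA(tab$scores))
  # long-CSV round trip through a temp copy
  df <- expand.grid(participant_id = paste0("Q", 1:3),
                    item_id = c("a", "b"), stringsAsFactors = FALSE)
  df$score <- c(1, 2, 3, 4, 5, 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  tab2 <- read_questionnaire(path)
  expect_equal(dim(tab2$scores), c(3L, 2L))
  df_missing <- df[-2, ]
  write.csv(df_missing, path, row.names = FALSE)
  expect_error(read_questionnaire(path), "incomplete")
})

test_that("round_half_up rounds halves away from zero", {
  expect_equal(round_half_up(2.345, 2), 2.35)
  expect_equal(round_half_up(2.344, 2), 2.34)
  expect_equal(round_half_up(-2.345, 2), -2.35)
  expect_equal(round_half_up(35 / 9, 2), 3.89)
})
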