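#' Round half up
#'
#' Rounds halves away from zero (spreadsheet convention), unlike base
#' `round()`'s round-half-even. This is the convention that reproduces the
#' published questionnaire statistics.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Descriptive statistics for one Likert item
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator), each
#' rounded half-up to 2 decimals. Scores must be integers in 1..5.
#'
#' @param scores Integer vector of at least 2 scores in \[1, 5\].
#' @param item_id Optional identifier carried through.
#' @return List: `item_id`, `mean`, `sd`, `n`.
#' @export
item_stats <- function(scores, item_id = NA_character_) {
  if (length(scores) < 2) stop("need at least 2 scores")
  if (any(!is.finite(scores)) || any(scores < 1 | scores > 5) ||
      any(scores != round(scores)))
    stop("scores must be integers in [1, 5]")
  list(item_id = item_id,
       mean = round_half_up(mean(scores), 2),
       sd = round_half_up(stats::sd(scores), 2),
       n = length(scores))
}

#' Per-item statistics for a questionnaire table
#'
#' @param table A questionnaire table: list with `items` (data frame
#'   `item_id`, `domain`, `question`) and `scores` (participants x items
#'   integer matrix, columns in item order), as returned by
#'   [read_questionnaire()] or [usability_fixture()].
#' @return Data frame: `item_id`, `domain`, `mean`, `sd`, `n`, in table
#'   order.
#' @export
stats_table <- function(table) {
  stopifnot(ncol(table$scores) == nrow(table$items))
  rows <- lapply(seq_len(ncol(table$scores)), function(j)
    item_stats(table$scores[, j], table$items$item_id[j]))
  data.frame(item_id = vapply(rows, `[[`, character(1), "item_id"),
             domain = table$items$domain,
             mean = vapply(rows, `[[`, numeric(1), "mean"),
             sd = vapply(rows, `[[`, numeric(1), "sd"),
             n = vapply(rows, `[[`, integer(1), "n"),
             stringsAsFactors = FALSE)
}

#' Range of rounded item means
#'
#' @param stats Data frame from [stats_table()] (or any with a `mean`
#'   column), at least one row.
#' @return Numeric `c(min_mean, max_mean)`.
#' @export
item_mean_range <- function(stats) {
  if (NROW(stats) == 0) stop("no items")
  m <- if (is.data.frame(stats)) stats$mean else
    vapply(stats, `[[`, numeric(1), "mean")
  c(min(m), max(m))
}

#' Read a questionnaire from long CSV
#'
#' Expected columns: `participant_id`, `item_id`, `score`, optionally
#' `domain` and `question`. Item order follows first appearance.
#'
#' @param path CSV path.
#' @return A questionnaire table (see [stats_table()]).
#' @export
read_questionnaire <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "item_id", "score")
  if (length(setdiff(need, names(df))))
    stop("questionnaire CSV needs columns: ", paste(need, collapse = ", "))
  items <- unique(df$item_id)
  participants <- unique(df$participant_id)
  scores <- matrix(NA_integer_, length(participants), length(items),
                   dimnames = list(participants, items))
  scores[cbind(match(df$participant_id, participants),
               match(df$item_id, items))] <- df$score
  if (anyNA(scores)) stop("incomplete questionnaire: missing cells")
  meta <- df[!duplicated(df$item_id), ]
  list(items = data.frame(item_id = items,
                          domain = meta$domain %||% rep(NA_character_, length(items)),
                          question = meta$question %||% rep(NA_character_, length(items)),
                          stringsAsFactors = FALSE),
       scores = scores)
}

#' The packaged usability questionnaire fixture
#'
#' The 9-participant by 8-item post-study usability questionnaire (5-point
#' Likert: 1 = strongly disagree .. 5 = strongly agree) covering ease of use,
#' playability, enjoyment, satisfaction and acceptance, shipped with the
#' package as a CSV fixture.
#'
#' @return A questionnaire table (see [stats_table()]).
#' @export
usability_fixture <- function() {
  read_questionnaire(system.file("extdata", "usability_questionnaire.csv",
                                 package = "msfit", mustWork = TRUE))
}
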