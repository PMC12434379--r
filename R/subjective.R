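#' Validate a rating table
#'
#' A rating table is a long-format data frame with one row per
#' (trial, rater, repetition): columns `trial_id`, `rater_id`,
#' `repetition`, `score`. Scores are integers 1-5; keys must be unique.
#'
#' @param ratings A data frame of ratings.
#' @return The ratings as a tibble, invisibly checked.
#' @export
validate_ratings <- function(ratings) {
  need <- c("trial_id", "rater_id", "repetition", "score")
  missing <- setdiff(need, names(ratings))
  if (length(missing) > 0) {
    abort(paste0("Rating table is missing column(s): ", paste(missing, collapse = ", ")),
      class = "wavescore_invalid_input"
    )
  }
  if (!all(ratings$score %in% 1:5)) {
    abort("Scores must be integers in 1..5.", class = "wavescore_invalid_input")
  }
  keys <- paste(ratings$trial_id, ratings$rater_id, ratings$repetition)
  if (anyDuplicated(keys)) {
    abort("Duplicate (trial, rater, repetition) keys in rating table.",
      class = "wavescore_invalid_input"
    )
  }
  as_tibble(ratings)
}

#' Mean opinion score of one trial
#'
#' The arithmetic mean of every individual score the trial received, over
#' all raters and repetitions.
#'
#' @param ratings A rating table (see [validate_ratings()]).
#' @param trial_id The trial to aggregate.
#' @return A scalar in `[1, 5]`.
#' @export
mos <- function(ratings, trial_id) {
  ratings <- validate_ratings(ratings)
  s <- ratings$score[ratings$trial_id == trial_id]
  if (length(s) == 0) {
    abort(sprintf("No ratings for trial '%s'.", trial_id), class = "wavescore_missing_trial")
  }
  mean(s)
}

#' Mean opinion scores for every trial
#'
#' @param ratings A rating table.
#' @return A tibble: `trial_id`, `mos`, `n_ratings`.
#' @export
mos_scores <- function(ratings) {
  ratings <- validate_ratings(ratings)
  ratings |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::summarise(mos = mean(.data$score), n_ratings = dplyr::n(), .groups = "drop")
}

#' Randomized presentation order for a rating session
#'
#' Each trial appears exactly `repetitions` times, in a seeded random
#' order, matching the protocol where every trial is rated multiple times
#' in randomized order.
#'
#' @param trial_ids Character vector of trials.
#' @param repetitions Repetitions per trial (default 3).
#' @param seed Integer seed.
#' @return A character vector of length `length(trial_ids) * repetitions`.
#' @export
schedule_session <- function(trial_ids, repetitions = 3, seed = 1) {
  if (length(trial_ids) == 0) {
    abort("`trial_ids` is empty.", class = "wavescore_empty_input")
  }
  if (repetitions < 1) {
    abort("`repetitions` must be >= 1.", class = "wavescore_invalid_input")
  }
  withr::with_seed(seed, sample(rep(as.character(trial_ids), repetitions)))
}

#' Cronbach's alpha of a rater panel
#'
#' Inter-rater reliability with raters as items and trials as observations.
#' Repetitions are first averaged within each (trial, rater) cell, then
#' `alpha = k/(k-1) * (1 - sum_j var_j / var(rowsums))` with `k` raters,
#' per-rater variances taken across trials (unbiased, n-1 denominator).
#'
#' @param ratings A rating table with at least 2 raters and 2 trials; every
#'   rater must have rated every trial.
#' @return Alpha (`<= 1`).
#' @export
cronbach_alpha <- function(ratings) {
  ratings <- validate_ratings(ratings)
  cell <- ratings |>
    dplyr::group_by(.data$trial_id, .data$rater_id) |>
    dplyr::summarise(score = mean(.data$score), .groups = "drop")
  wide <- tidyr::pivot_wider(cell, names_from = "rater_id", values_from = "score")
  m <- as.matrix(wide[, -1, drop = FALSE])
  if (ncol(m) < 2 || nrow(m) < 2) {
    abort("Cronbach's alpha needs at least 2 raters and 2 trials.",
      class = "wavescore_invalid_input"
    )
  }
  if (anyNA(m)) {
    abort("Every rater must rate every trial (incomplete panel).",
      class = "wavescore_invalid_input"
    )
  }
  k <- ncol(m)
  item_var <- apply(m, 2, var)
  total_var <- var(rowSums(m))
  if (total_var == 0) {
    abort("Reliability undefined: total score has zero variance across trials.",
      class = "wavescore_undefined"
    )
  }
  k / (k - 1) * (1 - sum(item_var) / total_var)
}

#' Read / write a rating table as CSV
#'
#' Long format with header `trial_id,rater_id,repetition,score`.
#'
#' @param path CSV file path.
#' @return [read_ratings()] returns a validated tibble.
#' @export
read_ratings <- function(path) {
  validate_ratings(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_ratings
#' @param ratings A rating table.
#' @export
write_ratings <- function(ratings, path) {
  readr::write_csv(validate_ratings(ratings), path)
  invisible(path)
}
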