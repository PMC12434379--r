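cv_toy_data <- function(seed = 1, n_datasets = 3, per = 4) {
  withr::with_seed(seed, {
    n <- n_datasets * per
    tibble::tibble(
      trial_id = sprintf("t%02d", seq_len(n)),
      dataset_id = rep(sprintf("ds%d", seq_len(n_datasets)), each = per),
      stoi = runif(n),
      mcd = runif(n, 2, 12),
      entropy = runif(n),
      mos = NA_real_
    ) |>
      dplyr::mutate(mos = 1 + 3 * stoi - 0.1 * mcd + rnorm(n, sd = 0.1))
  })
}

test_that("grouped splits partition samples with the contracted fold sizes", {
  d <- cv_toy_data(n_datasets = 3, per = 4)
  sizes <- c(4, 5, 3)
  d$dataset_id <- rep(c("a", "b", "c"), times = sizes)
  folds <- lodo_split(d)
  expect_length(folds, 3)
  expect_equal(vapply(folds, function(f) length(f$test), integer(1)), sizes)
  all_test <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(all_test, seq_len(nrow(d))) # disjoint union = all samples
  for (f in folds) expect_length(intersect(f$train, f$test), 0)

  lt <- loto_split(d)
  expect_length(lt, nrow(d))
  expect_true(all(vapply(lt, function(f) length(f$train), integer(1)) == nrow(d) - 1))

  expect_error(lodo_split(dplyr::mutate(d, dataset_id = "one")),
    class = "wavescore_grouping_error"
  )
  expect_error(loto_split(d[1, ]), class = "wavescore_grouping_error")
})

test_that("r_squared and mae match hand-computed oracles", {
  pred <- c(1.1, 1.9, 3.2, 4.1)
  truth <- c(1, 2, 3, 4)
  expect_equal(r_squared(pred, truth), r2_oracle(pred, truth), tolerance = 1e-12)
  expect_equal(r_squared(truth, truth), 1)
  expect_equal(mae(truth + 0.5, truth), 0.5)
  expect_equal(mae(truth, truth), 0)
  expect_error(r_squared(c(1, 2), c(3, 3)), class = "wavescore_undefined")
})

test_that("the oracle predictor yields a perfect report and no leakage", {
  d <- cv_toy_data()
  rep <- cross_validate(d, model = "oracle", split = "lodo")
  expect_equal(rep$r_squared, 1)
  expect_equal(rep$mae, 0)
  # every trial predicted exactly once
  expect_equal(sort(rep$predictions$trial_id), sort(d$trial_id))
  # no leakage: the fold that predicted a trial is that trial's own dataset,
  # which is excluded from the training rows by construction of the split
  expect_true(all(rep$predictions$fold == rep$predictions$dataset_id))
  g <- glance(rep)
  expect_equal(g$n_predictions, nrow(d))
  expect_equal(g$n_flagged, 0L)
})

test_that("metrics are computed on aggregated predictions, not averaged per fold", {
  d <- cv_toy_data(seed = 9, n_datasets = 3, per = 4)
  rep <- cross_validate(d, model = "piecewise", split = "lodo", threshold = 0.5)
  preds <- rep$predictions
  aggregated <- r_squared(preds$pred, preds$truth)
  per_fold <- vapply(split(preds, preds$fold), function(p) {
    r_squared(p$pred, p$truth)
  }, numeric(1))
  expect_equal(rep$r_squared, aggregated, tolerance = 1e-12)
  # fold-averaging is a genuinely different number on grouped data
  expect_false(isTRUE(all.equal(rep$r_squared, mean(per_fold), tolerance = 1e-6)))
})

test_that("a constant-mean predictor cannot beat R-squared zero out of sample", {
  # piecewise with both slopes forced ~0 via constant features acts as a
  # fold-mean predictor; grouped held-out means differ from training means
  withr::with_seed(5, {
    d <- cv_toy_data(seed = 5)
    d$mos <- d$mos + rep(c(-1, 0, 1), each = 4) # dataset-level shifts
    d$stoi <- 0.5 + rnorm(12, sd = 1e-6)
    d$mcd <- 5 + rnorm(12, sd = 1e-6)
    rep <- cross_validate(d, model = "random_forest", split = "lodo", seed = 2)
    expect_lte(rep$r_squared, 0)
  })
})

test_that("degenerate piecewise folds are flagged and skipped with a warning", {
  d <- cv_toy_data(seed = 3, n_datasets = 3, per = 4)
  # all low-entropy mass sits in one dataset: fitting without it starves
  # the low-entropy group
  d$entropy <- c(rep(0.2, 4), rep(0.9, 8))
  expect_warning(
    rep <- cross_validate(d, model = "piecewise", split = "lodo"),
    "skipped"
  )
  expect_true("ds1" %in% rep$flagged_folds)
  expect_lt(nrow(rep$predictions), nrow(d))
})

test_that("stochastic models cross-validate reproducibly under a fixed seed", {
  d <- cv_toy_data(seed = 11)
  a <- cross_validate(d, model = "random_forest", split = "lodo", seed = 42)
  b <- cross_validate(d, model = "random_forest", split = "lodo", seed = 42)
  expect_identical(a$predictions, b$predictions)
  expect_identical(a$r_squared, b$r_squared)
})

test_that("reports export to JSON and CSV", {
  d <- cv_toy_data(seed = 13)
  rep <- cross_validate(d, model = "oracle", split = "lodo")
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_cv_report(rep, jp, cp)
  obj <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(obj$r_squared, 1)
  expect_equal(obj$model_kind, "oracle")
  back <- readr::read_csv(cp, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(d))
})
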