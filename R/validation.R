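#' Leave-one-dataset-out fold assignment
#'
#' One fold per distinct `dataset_id`: that dataset's trials form the test
#' set, all other datasets the training set. Folds iterate in sorted
#' `dataset_id` order and partition the samples.
#'
#' @param data Data frame with a `dataset_id` column (>= 2 distinct values).
#' @return A list of folds, each `list(id, train, test)` with row indices.
#' @export
lodo_split <- function(data) {
  if (!"dataset_id" %in% names(data)) {
    abort("`data` needs a `dataset_id` column.", class = "wavescore_invalid_input")
  }
  ids <- sort(unique(as.character(data$dataset_id)))
  if (length(ids) < 2) {
    abort("Only one dataset present; grouped CV needs >= 2 (or use leave-one-trial-out).",
      class = "wavescore_grouping_error"
    )
  }
  purrr::map(ids, function(d) {
    test <- which(data$dataset_id == d)
    list(id = d, train = setdiff(seq_len(nrow(data)), test), test = test)
  })
}

#' Leave-one-trial-out fold assignment
#'
#' One fold per trial (ordinary leave-one-out), iterating in sorted
#' `trial_id` order.
#'
#' @param data Data frame with a `trial_id` column (>= 2 trials).
#' @return A list of folds as in [lodo_split()].
#' @export
loto_split <- function(data) {
  if (!"trial_id" %in% names(data)) {
    abort("`data` needs a `trial_id` column.", class = "wavescore_invalid_input")
  }
  ids <- sort(unique(as.character(data$trial_id)))
  if (length(ids) < 2) {
    abort("Only one trial present; leave-one-trial-out needs >= 2.",
      class = "wavescore_grouping_error"
    )
  }
  purrr::map(ids, function(d) {
    test <- which(data$trial_id == d)
    list(id = d, train = setdiff(seq_len(nrow(data)), test), test = test)
  })
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` about the mean of `truth`.
#'
#' @param pred,truth Equal-length numeric vectors (`n >= 2`); `truth` must
#'   not be constant.
#' @return R-squared (`<= 1`, can be negative).
#' @export
r_squared <- function(pred, truth) {
  if (length(pred) != length(truth) || length(truth) < 2) {
    abort("`pred` and `truth` must have equal length >= 2.", class = "wavescore_invalid_input")
  }
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) {
    abort("R-squared undefined for constant truth.", class = "wavescore_undefined")
  }
  1 - sum((truth - pred)^2) / ss_tot
}

#' Mean absolute error
#' @inheritParams r_squared
#' @return MAE in score units (`>= 0`).
#' @export
mae <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    abort("`pred` and `truth` must have equal length.", class = "wavescore_invalid_input")
  }
  mean(abs(pred - truth))
}

#' Grouped cross-validation of a MOS predictor
#'
#' For each fold the chosen model is fitted on the training rows and
#' predicts the held-out rows; *all* out-of-sample predictions are then
#' aggregated and R-squared and MAE are computed once on the aggregate —
#' not averaged per fold (the two differ in general, and the aggregate is
#' the quantity reported here). Folds on which the model cannot be fitted
#' (e.g. an entropy group of the piecewise model falls below the 3-sample
#' minimum) are flagged and skipped, and metrics are computed on the
#' remaining predictions with a warning.
#'
#' The per-fold MCD min-max transform is fitted on the training pool only
#' and applied to the held-out rows, so no test information leaks into
#' feature scaling.
#'
#' @param data Data frame with columns `trial_id`, `dataset_id`, `stoi`,
#'   `mcd` (raw dB), `entropy`, `mos`.
#' @param model `"piecewise"`, `"random_forest"`, `"svr_rbf"`, or
#'   `"oracle"` (predicts the true MOS; a harness check, not a model).
#' @param split `"lodo"` (leave-one-dataset-out) or `"loto"`
#'   (leave-one-trial-out).
#' @param seed Integer seed for stochastic fits (varied per fold).
#' @param threshold Entropy threshold for the piecewise model.
#' @param hyperparameters Passed to [fit_scorer()].
#' @return A `cv_report`: list with `predictions` (tibble `trial_id`,
#'   `dataset_id`, `fold`, `truth`, `pred`), `r_squared`, `mae`,
#'   `model_kind`, `split`, `seed`, `flagged_folds`, `n_folds`.
#' @export
cross_validate <- function(data, model = c("piecewise", "random_forest", "svr_rbf", "oracle"),
                           split = c("lodo", "loto"), seed = 1, threshold = 0.7,
                           hyperparameters = list()) {
  model <- match.arg(model)
  split <- match.arg(split)
  need <- c("trial_id", "dataset_id", "stoi", "mcd", "entropy", "mos")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(paste0("`data` is missing column(s): ", paste(missing, collapse = ", ")),
      class = "wavescore_invalid_input"
    )
  }
  folds <- if (split == "lodo") lodo_split(data) else loto_split(data)
  flagged <- character(0)
  rows <- list()
  for (i in seq_along(folds)) {
    fold <- folds[[i]]
    train <- data[fold$train, , drop = FALSE]
    test <- data[fold$test, , drop = FALSE]
    pred <- tryCatch(
      {
        if (model == "oracle") {
          test$mos
        } else if (model == "piecewise") {
          tr <- minmax_transform(train$mcd)
          fit <- fit_piecewise(
            dplyr::mutate(train, mcd_feature = apply_transform(tr, .data$mcd)),
            threshold = threshold, transform = tr
          )
          predict(fit, dplyr::mutate(test, mcd_feature = apply_transform(tr, .data$mcd)))
        } else {
          fit <- fit_scorer(train,
            kind = model, hyperparameters = hyperparameters,
            seed = derive_seed(seed, "cvfold", i)
          )
          predict(fit, test)
        }
      },
      error = function(e) {
        warn(sprintf("Fold '%s' skipped: %s", fold$id, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(pred)) {
      flagged <- c(flagged, fold$id)
      next
    }
    rows[[length(rows) + 1]] <- tibble(
      trial_id = as.character(test$trial_id),
      dataset_id = as.character(test$dataset_id),
      fold = fold$id, truth = test$mos, pred = pred
    )
  }
  preds <- dplyr::bind_rows(rows)
  if (nrow(preds) < 2) {
    abort("Too few out-of-sample predictions to score (all folds degenerate?).",
      class = "wavescore_undefined"
    )
  }
  structure(
    list(
      predictions = preds,
      r_squared = r_squared(preds$pred, preds$truth),
      mae = mae(preds$pred, preds$truth),
      model_kind = model, split = split, seed = seed,
      flagged_folds = flagged, n_folds = length(folds)
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report: %s, %s, %d folds (%d flagged)>\n  R^2 = %.3f   MAE = %.3f\n",
    x$model_kind, toupper(x$split), x$n_folds, length(x$flagged_folds),
    x$r_squared, x$mae
  ))
  invisible(x)
}

#' @export
tidy.cv_report <- function(x, ...) x$predictions

#' @export
glance.cv_report <- function(x, ...) {
  tibble(
    r_squared = x$r_squared, mae = x$mae, model_kind = x$model_kind,
    split = x$split, seed = x$seed, n_folds = x$n_folds,
    n_flagged = length(x$flagged_folds),
    n_predictions = nrow(x$predictions)
  )
}

#' Export a cross-validation report
#'
#' Writes the scalar metrics and fold map as JSON and the per-trial
#' out-of-sample predictions as CSV.
#'
#' @param report A `cv_report`.
#' @param json_path,csv_path Output paths (either may be `NULL` to skip).
#' @export
write_cv_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "cv_report"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(
        r_squared = report$r_squared, mae = report$mae,
        model_kind = report$model_kind, split = report$split,
        seed = report$seed, n_folds = report$n_folds,
        flagged_folds = report$flagged_folds,
        fold_assignments = stats::setNames(
          as.list(report$predictions$fold), report$predictions$trial_id
        )
      ),
      json_path,
      auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(csv_path)) readr::write_csv(report$predictions, csv_path)
  invisible(report)
}
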