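#' Piecewise linear MOS scorer gated on spectrogram entropy
#'
#' The interpretable baseline model mapping (MCD feature, STOI) to a
#' predicted quality score, with two linear regimes selected by the
#' normalized entropy of the reference: below the threshold (simple,
#' narrowband material, where segment correlations mislead) MCD carries a
#' positive weight; above it (complex material, where absolute spectral
#' offsets mislead) MCD is penalized. The defaults are the published
#' coefficients: threshold 0.7, low regime `(0.101, 0.544, 0.089)`, high
#' regime `(0.921, -0.892, 0.223)` as (intercept, MCD slope, STOI slope).
#' Entropy exactly at the threshold uses the high regime (documented
#' tie-break; the two strict inequalities leave equality undefined).
#'
#' The scorer evaluates its linear form literally on whatever `mcd_feature`
#' it is given. The published coefficients presuppose a bounded, unitless
#' MCD; see [minmax_transform()] for the affine map used when fitting.
#'
#' @param threshold Entropy cutoff in `[0, 1]`.
#' @param low,high Length-3 numeric vectors `(intercept, mcd, stoi)`.
#' @param transform Optional recorded feature transform (a
#'   `minmax_transform`), carried for provenance.
#' @return A `piecewise_scorer` object.
#' @examples
#' m <- piecewise_scorer()
#' predict(m, tibble::tibble(mcd_feature = 0, stoi = 0, entropy = c(0.5, 0.9)))
#' @export
piecewise_scorer <- function(threshold = 0.7,
                             low = c(intercept = 0.101, mcd = 0.544, stoi = 0.089),
                             high = c(intercept = 0.921, mcd = -0.892, stoi = 0.223),
                             transform = NULL) {
  stopifnot(length(low) == 3, length(high) == 3, is.numeric(threshold))
  names(low) <- names(high) <- c("intercept", "mcd", "stoi")
  structure(
    list(threshold = threshold, low = low, high = high, transform = transform),
    class = "piecewise_scorer"
  )
}

#' @export
print.piecewise_scorer <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<piecewise_scorer (entropy threshold %.3g)>\n",
      "  entropy <  %.3g: score = %.3f %+.3f*mcd %+.3f*stoi\n",
      "  entropy >= %.3g: score = %.3f %+.3f*mcd %+.3f*stoi\n"
    ),
    x$threshold, x$threshold, x$low[1], x$low[2], x$low[3],
    x$threshold, x$high[1], x$high[2], x$high[3]
  ))
  invisible(x)
}

#' Predict from a piecewise linear scorer
#'
#' @param object A [piecewise_scorer()].
#' @param newdata Data frame with columns `mcd_feature`, `stoi`, `entropy`.
#' @param ... Unused.
#' @return Numeric vector of predicted scores.
#' @export
predict.piecewise_scorer <- function(object, newdata, ...) {
  need <- c("mcd_feature", "stoi", "entropy")
  missing <- setdiff(need, names(newdata))
  if (length(missing) > 0) {
    abort(paste0("`newdata` is missing column(s): ", paste(missing, collapse = ", ")),
      class = "wavescore_invalid_input"
    )
  }
  high <- newdata$entropy >= object$threshold
  co <- rbind(object$low, object$high)[high + 1L, , drop = FALSE]
  as.numeric(co[, 1] + co[, 2] * newdata$mcd_feature + co[, 3] * newdata$stoi)
}

#' @export
tidy.piecewise_scorer <- function(x, ...) {
  fd <- x$fit_details
  out <- tibble(
    regime = rep(c("low", "high"), each = 3),
    term = rep(c("intercept", "mcd_feature", "stoi"), 2),
    estimate = c(unname(x$low), unname(x$high))
  )
  if (!is.null(fd)) out$std.error <- c(fd$se_low, fd$se_high)
  out
}

#' @export
glance.piecewise_scorer <- function(x, ...) {
  fd <- x$fit_details
  tibble(
    threshold = x$threshold,
    n_low = if (is.null(fd)) NA_integer_ else fd$n_low,
    n_high = if (is.null(fd)) NA_integer_ else fd$n_high,
    fitted = !is.null(fd)
  )
}

#' Fit the piecewise linear scorer by ordinary least squares
#'
#' Samples are split into two groups at the entropy threshold; one linear
#' model `mos ~ mcd_feature + stoi` is fitted per group by least squares.
#' Each group needs at least 3 samples (two slopes plus an intercept).
#'
#' @param data Data frame with columns `mos`, `mcd_feature`, `stoi`,
#'   `entropy`.
#' @param threshold Entropy cutoff (default 0.7).
#' @param transform Optional transform to record on the fitted scorer.
#' @return A fitted [piecewise_scorer()] with a `fit_details` element
#'   (group sizes and coefficient standard errors).
#' @export
fit_piecewise <- function(data, threshold = 0.7, transform = NULL) {
  need <- c("mos", "mcd_feature", "stoi", "entropy")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(paste0("`data` is missing column(s): ", paste(missing, collapse = ", ")),
      class = "wavescore_invalid_input"
    )
  }
  high <- data$entropy >= threshold
  fit_group <- function(d, label) {
    if (nrow(d) < 3) {
      abort(
        sprintf(
          "Entropy group '%s' has %d sample(s); at least 3 are needed to fit intercept + 2 slopes.",
          label, nrow(d)
        ),
        class = "wavescore_rank_deficient"
      )
    }
    fit <- lm(mos ~ mcd_feature + stoi, data = d)
    if (any(is.na(coef(fit)))) {
      abort(sprintf("Entropy group '%s' is rank-deficient (collinear features).", label),
        class = "wavescore_rank_deficient"
      )
    }
    fit
  }
  fit_lo <- fit_group(data[!high, , drop = FALSE], "low")
  fit_hi <- fit_group(data[high, , drop = FALSE], "high")
  out <- piecewise_scorer(
    threshold = threshold,
    low = stats::setNames(coef(fit_lo), c("intercept", "mcd", "stoi")),
    high = stats::setNames(coef(fit_hi), c("intercept", "mcd", "stoi")),
    transform = transform
  )
  out$fit_details <- list(
    n_low = sum(!high), n_high = sum(high),
    se_low = unname(sqrt(diag(stats::vcov(fit_lo)))),
    se_high = unname(sqrt(diag(stats::vcov(fit_hi))))
  )
  out
}

# ---- feature transform -------------------------------------------------

#' Min-max feature transform for raw MCD
#'
#' MCD is in decibels and unbounded above; the regression models (and the
#' published piecewise coefficients) operate on a bounded, unitless MCD
#' feature. The transform is an affine min-max map fitted on the training
#' pool and stored with every fitted model, so evaluation-time inputs go
#' through the identical map.
#'
#' @param x Numeric vector to fit the map on (training-pool raw MCD, dB).
#' @return A `minmax_transform` with elements `min` and `range`.
#' @export
minmax_transform <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1, all(is.finite(x)))
  rng <- max(x) - min(x)
  structure(list(min = min(x), range = rng), class = "minmax_transform")
}

#' @rdname minmax_transform
#' @param transform A fitted `minmax_transform`.
#' @param new Values to map.
#' @export
apply_transform <- function(transform, new) {
  stopifnot(inherits(transform, "minmax_transform"))
  if (transform$range == 0) {
    return(rep(0.5, length(new)))
  }
  (new - transform$min) / transform$range
}

# ---- trainable regressors ---------------------------------------------

#' Fit a trainable MOS regressor on STOI and MCD
#'
#' Supervised regressors predicting MOS from the two objective features
#' (entropy is deliberately *not* an input to the trainable models — only
#' the piecewise baseline uses it, as a regime gate). Raw MCD (dB) is
#' min-max normalized on the training pool; the transform is stored with
#' the model. Kinds:
#' \describe{
#'   \item{`random_forest`}{ensemble of regression trees
#'     ([randomForest::randomForest]); default 500 trees, unrestricted
#'     depth.}
#'   \item{`svr_rbf`}{epsilon support-vector regression with an RBF kernel
#'     ([e1071::svm]); default cost 1 and kernel width from the inverse
#'     feature-variance heuristic `gamma = 1 / (p * var(X))`.}
#' }
#' All randomness flows through `seed`; refitting with identical data,
#' hyperparameters, and seed reproduces identical predictions.
#'
#' @param data Data frame with columns `mos`, `stoi`, `mcd` (raw dB).
#' @param kind `"random_forest"` or `"svr_rbf"`.
#' @param hyperparameters Named list overriding the defaults above
#'   (`ntree`, `nodesize`, `mtry` for the forest; `cost`, `gamma`,
#'   `epsilon` for the SVR).
#' @param seed Integer seed.
#' @return A `trained_scorer`.
#' @export
fit_scorer <- function(data, kind = c("random_forest", "svr_rbf"),
                       hyperparameters = list(), seed = 1) {
  kind <- match.arg(kind)
  need <- c("mos", "stoi", "mcd")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(paste0("`data` is missing column(s): ", paste(missing, collapse = ", ")),
      class = "wavescore_invalid_input"
    )
  }
  if (nrow(data) < 5) {
    abort("At least 5 training samples are required.", class = "wavescore_invalid_input")
  }
  transform <- minmax_transform(data$mcd)
  x <- cbind(stoi = data$stoi, mcd_feature = apply_transform(transform, data$mcd))
  y <- data$mos
  if (kind == "random_forest") {
    hp <- utils::modifyList(
      list(ntree = 500, nodesize = 5, mtry = 2, replace = TRUE, sampsize = nrow(x)),
      hyperparameters
    )
    fit <- withr::with_seed(seed, randomForest::randomForest(
      x = x, y = y,
      ntree = hp$ntree, nodesize = hp$nodesize, mtry = hp$mtry,
      replace = hp$replace, sampsize = hp$sampsize
    ))
  } else {
    hp <- utils::modifyList(
      list(cost = 1, gamma = 1 / (ncol(x) * max(var(as.numeric(x)), 1e-12)), epsilon = 0.1),
      hyperparameters
    )
    fit <- withr::with_seed(seed, e1071::svm(
      x = x, y = y, type = "eps-regression", kernel = "radial",
      cost = hp$cost, gamma = hp$gamma, epsilon = hp$epsilon, scale = FALSE
    ))
  }
  structure(
    list(
      kind = kind, hyperparameters = hp, seed = seed,
      fitted_state = fit, transform = transform,
      training_range = range(y), n_train = nrow(data)
    ),
    class = "trained_scorer"
  )
}

#' Predict MOS from a trained regressor
#'
#' @param object A `trained_scorer` from [fit_scorer()].
#' @param newdata Data frame with columns `stoi` and `mcd` (raw dB; the
#'   model's recorded transform is applied internally).
#' @param ... Unused.
#' @return Numeric vector of predicted MOS.
#' @export
predict.trained_scorer <- function(object, newdata, ...) {
  if (is.null(object$fitted_state)) {
    abort("Model has not been fitted.", class = "wavescore_state_error")
  }
  need <- c("stoi", "mcd")
  missing <- setdiff(need, names(newdata))
  if (length(missing) > 0) {
    abort(paste0("`newdata` is missing column(s): ", paste(missing, collapse = ", ")),
      class = "wavescore_invalid_input"
    )
  }
  x <- cbind(
    stoi = newdata$stoi,
    mcd_feature = apply_transform(object$transform, newdata$mcd)
  )
  as.numeric(predict(object$fitted_state, x))
}

#' @export
print.trained_scorer <- function(x, ...) {
  cat(sprintf(
    "<trained_scorer: %s, n_train = %d, seed = %d>\n",
    x$kind, x$n_train, x$seed
  ))
  invisible(x)
}

#' @export
glance.trained_scorer <- function(x, ...) {
  tibble(
    kind = x$kind, n_train = x$n_train, seed = x$seed,
    hyperparameters = list(x$hyperparameters),
    mcd_min = x$transform$min, mcd_range = x$transform$range
  )
}

# ---- serialization -----------------------------------------------------

#' Save / load a piecewise scorer as JSON
#'
#' Trainable scorers carry an opaque fitted state and are not serialized to
#' text; the piecewise model is fully described by its coefficients,
#' threshold, and recorded transform.
#'
#' @param model A `piecewise_scorer`.
#' @param path JSON file path.
#' @export
write_scorer <- function(model, path) {
  stopifnot(inherits(model, "piecewise_scorer"))
  obj <- list(
    kind = "piecewise", threshold = model$threshold,
    low = as.list(model$low), high = as.list(model$high),
    transform = if (is.null(model$transform)) NULL else unclass(model$transform)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scorer
#' @export
read_scorer <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$kind, "piecewise")) {
    abort("Only piecewise scorers are stored as JSON.", class = "wavescore_config_error")
  }
  tr <- if (is.null(obj$transform)) {
    NULL
  } else {
    structure(list(min = obj$transform$min, range = obj$transform$range),
      class = "minmax_transform"
    )
  }
  piecewise_scorer(
    threshold = obj$threshold,
    low = unlist(obj$low), high = unlist(obj$high), transform = tr
  )
}
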