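test_that("the default piecewise scorer carries the published coefficients", {
  m <- piecewise_scorer()
  expect_equal(m$threshold, 0.7)
  expect_equal(unname(m$low), c(0.101, 0.544, 0.089))
  expect_equal(unname(m$high), c(0.921, -0.892, 0.223))
  td <- tidy(m)
  expect_equal(nrow(td), 6)
  expect_equal(td$estimate[td$regime == "low" & td$term == "mcd_feature"], 0.544)
})

test_that("piecewise prediction is linear within regimes with a >= tie-break", {
  m <- piecewise_scorer()
  grid <- tibble::tibble(
    mcd_feature = c(0, 0, 1, 0.3),
    stoi = c(0, 0, 1, 0.6),
    entropy = c(0.5, 0.9, 0.5, 0.5)
  )
  expect_equal(
    predict(m, grid),
    c(0.101, 0.921, 0.101 + 0.544 + 0.089, 0.101 + 0.544 * 0.3 + 0.089 * 0.6)
  )
  # entropy exactly at the threshold uses the high regime
  at <- predict(m, tibble::tibble(mcd_feature = 0, stoi = 0, entropy = 0.7))
  expect_equal(at, 0.921)
  # within-regime linearity: increments equal slope dot products
  withr::with_seed(2, {
    a <- runif(2)
    b <- runif(2)
    base <- predict(m, tibble::tibble(mcd_feature = a[1], stoi = a[2], entropy = 0.4))
    bump <- predict(m, tibble::tibble(
      mcd_feature = a[1] + b[1], stoi = a[2] + b[2], entropy = 0.4
    ))
    expect_equal(bump - base, sum(m$low[2:3] * b), tolerance = 1e-12)
  })
})

test_that("noiseless data generated from the defaults is recovered exactly", {
  withr::with_seed(21, {
    d <- tibble::tibble(
      mcd_feature = runif(60),
      stoi = runif(60),
      entropy = runif(60, 0, 1)
    )
    d$mos <- predict(piecewise_scorer(), d)
    # lm warns about the (intentionally) perfect fit
    fit <- suppressWarnings(fit_piecewise(d))
    expect_equal(unname(fit$low), c(0.101, 0.544, 0.089), tolerance = 1e-8)
    expect_equal(unname(fit$high), c(0.921, -0.892, 0.223), tolerance = 1e-8)
  })
})

test_that("noisy refits recover coefficients within sampling error", {
  hits <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      d <- tibble::tibble(
        mcd_feature = runif(400),
        stoi = runif(400),
        entropy = c(runif(200, 0, 0.69), runif(200, 0.71, 1))
      )
      d$mos <- predict(piecewise_scorer(), d) + rnorm(400, sd = 0.05)
      fit <- fit_piecewise(d)
      est <- c(fit$low, fit$high)
      se <- c(fit$fit_details$se_low, fit$fit_details$se_high)
      truth <- c(0.101, 0.544, 0.089, 0.921, -0.892, 0.223)
      all(abs(est - truth) <= 3 * se)
    })
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("under-determined entropy groups raise a rank error naming the group", {
  d <- tibble::tibble(
    mcd_feature = runif(10), stoi = runif(10),
    entropy = rep(0.2, 10), mos = runif(10)
  )
  expect_error(fit_piecewise(d), regexp = "high", class = "wavescore_rank_deficient")
})

test_that("the min-max transform is affine, recorded, and degenerate-safe", {
  tr <- minmax_transform(c(4, 8, 10))
  expect_equal(apply_transform(tr, c(4, 7, 10, 13)), c(0, 0.5, 1, 1.5))
  flat <- minmax_transform(c(5, 5))
  expect_equal(apply_transform(flat, c(1, 9)), c(0.5, 0.5))
})

smooth_training_data <- function(n = 60, seed = 31) {
  withr::with_seed(seed, {
    d <- tibble::tibble(stoi = runif(n), mcd = runif(n, 2, 12))
    d$mos <- 1 + 3 * d$stoi - 0.15 * d$mcd + 0.5 * d$stoi * (12 - d$mcd) / 10
    d
  })
}

test_that("trainable regressors fit, predict deterministically, and stay in range", {
  d <- smooth_training_data()
  rf <- fit_scorer(d, "random_forest", seed = 7)
  p1 <- predict(rf, d)
  expect_gt(r_squared(p1, d$mos), 0.9) # in-sample on smooth data
  rf2 <- fit_scorer(d, "random_forest", seed = 7)
  expect_identical(p1, predict(rf2, d))
  # forest averages of training targets cannot leave the target range
  probe <- tibble::tibble(stoi = c(-5, 0.5, 5), mcd = c(100, 6, -40))
  expect_true(all(predict(rf, probe) >= min(d$mos) & predict(rf, probe) <= max(d$mos)))

  sv <- fit_scorer(d, "svr_rbf", seed = 7)
  ps <- predict(sv, d)
  expect_true(all(is.finite(ps)))
  expect_gt(r_squared(ps, d$mos), 0.7)
  # continuity: a tiny feature perturbation moves predictions slightly
  eps <- predict(sv, dplyr::mutate(d, stoi = stoi + 1e-6))
  expect_lt(max(abs(eps - ps)), 1e-3)
})

test_that("a single unrestricted tree memorizes its training points", {
  d <- smooth_training_data(n = 25, seed = 8)
  one <- fit_scorer(d, "random_forest",
    hyperparameters = list(ntree = 1, nodesize = 1, mtry = 2, replace = FALSE, sampsize = 25),
    seed = 3
  )
  expect_equal(predict(one, d), d$mos, tolerance = 1e-8)
})

test_that("scorer fitting validates inputs", {
  d <- smooth_training_data(n = 3)
  expect_error(fit_scorer(d, "random_forest"), class = "wavescore_invalid_input")
  expect_error(
    fit_scorer(smooth_training_data()[, c("stoi", "mos")], "svr_rbf"),
    class = "wavescore_invalid_input"
  )
})

test_that("piecewise scorers survive a JSON round-trip", {
  tr <- minmax_transform(c(3, 9))
  m <- piecewise_scorer(transform = tr)
  path <- withr::local_tempfile(fileext = ".json")
  write_scorer(m, path)
  back <- read_scorer(path)
  expect_equal(back$threshold, m$threshold)
  expect_equal(back$low, m$low)
  expect_equal(back$high, m$high)
  expect_equal(back$transform$min, 3)
  newdata <- tibble::tibble(mcd_feature = 0.2, stoi = 0.4, entropy = 0.9)
  expect_equal(predict(back, newdata), predict(m, newdata))
})
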