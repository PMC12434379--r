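test_that("pearson_cc agrees with the direct sum-formula oracle", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 3, 5)
  expect_equal(pearson_cc(x, y), pearson_oracle(x, y), tolerance = 1e-12)
  withr::with_seed(11, {
    for (i in 1:5) {
      a <- rnorm(20)
      b <- rnorm(20)
      expect_equal(pearson_cc(a, b), pearson_oracle(a, b), tolerance = 1e-12)
    }
  })
  expect_equal(pearson_cc(x, x), 1)
  expect_equal(pearson_cc(x, -x), -1)
  expect_error(pearson_cc(rep(1, 5), 1:5), class = "wavescore_undefined")
  expect_error(pearson_cc(1:3, 1:4), class = "wavescore_invalid_input")
})

test_that("mcd matches the double-loop brute-force oracle on random matrices", {
  withr::with_seed(42, {
    for (i in 1:10) {
      a <- matrix(rnorm(15), 3, 5)
      b <- matrix(rnorm(15), 3, 5)
      expect_equal(mcd(fake_mfcc(a), fake_mfcc(b)), mcd_oracle(a, b), tolerance = 1e-10)
      expect_equal(
        mcd(fake_mfcc(a), fake_mfcc(b), exclude_c0 = FALSE),
        mcd_oracle(a, b, exclude_c0 = FALSE),
        tolerance = 1e-10
      )
    }
  })
})

test_that("mcd closed-form constant, identity, and symmetry hold", {
  a <- fake_mfcc(matrix(0, 1, 2))
  b <- fake_mfcc(matrix(c(0, 1), 1, 2))
  # one frame, one included coefficient differing by 1
  expect_equal(mcd(a, b), (10 / log(10)) * sqrt(2))
  expect_equal(mcd(a, a), 0)
  withr::with_seed(5, {
    x <- fake_mfcc(matrix(rnorm(26), 2, 13))
    y <- fake_mfcc(matrix(rnorm(26), 2, 13))
    expect_equal(mcd(x, y), mcd(y, x))
    expect_gte(mcd(x, y), 0)
  })
})

test_that("mcd enforces comparability and alignment", {
  a <- fake_mfcc(matrix(rnorm(20), 4, 5))
  b <- fake_mfcc(matrix(rnorm(15), 3, 5))
  expect_error(mcd(a, b), class = "wavescore_invalid_input")
  c_other <- fake_mfcc(matrix(rnorm(20), 4, 5), hop = 0.02)
  expect_error(mcd(a, c_other), class = "wavescore_config_error")
})

test_that("segment-correlation score: identity, affine invariance, segment oracle", {
  withr::with_seed(9, {
    a <- fake_mfcc(matrix(rnorm(13 * 60), 60, 13))
    expect_equal(as.numeric(stoi_mfcc(a, a)), 1)
    # positive affine maps leave every segment correlation at 1
    b <- fake_mfcc(unclass(a) * 2.5 + 0.7)
    expect_equal(as.numeric(stoi_mfcc(a, b)), 1, tolerance = 1e-12)
    # two-segment toy equals the mean of hand-oracle per-segment correlations
    rec <- fake_mfcc(unclass(a) + matrix(rnorm(13 * 60), 60, 13))
    got <- stoi_mfcc(a, rec, segment_frames = 30)
    r1 <- pearson_oracle(
      as.numeric(t(unclass(a)[1:30, ])),
      as.numeric(t(unclass(rec)[1:30, ]))
    )
    r2 <- pearson_oracle(
      as.numeric(t(unclass(a)[31:60, ])),
      as.numeric(t(unclass(rec)[31:60, ]))
    )
    expect_equal(as.numeric(got), (r1 + r2) / 2, tolerance = 1e-12)
    expect_equal(attr(got, "n_segments"), 2L)
  })
})

test_that("segment score degenerates to whole-matrix correlation and flags fallback", {
  withr::with_seed(10, {
    a <- fake_mfcc(matrix(rnorm(13 * 45), 45, 13))
    b <- fake_mfcc(matrix(rnorm(13 * 45), 45, 13))
    # segment covering all frames == flattened correlation
    expect_equal(
      as.numeric(stoi_mfcc(a, b, segment_frames = 45)),
      pearson_oracle(as.numeric(t(unclass(a))), as.numeric(t(unclass(b)))),
      tolerance = 1e-12
    )
    # fewer frames than a segment -> single-segment fallback, flagged
    short <- stoi_mfcc(a, b, segment_frames = 100)
    expect_true(attr(short, "fallback"))
    expect_equal(attr(short, "n_segments"), 1L)
  })
})

test_that("constant segments are skipped and counted, not scored as zero", {
  withr::with_seed(12, {
    a <- matrix(rnorm(13 * 60), 60, 13)
    b <- a + rnorm(13 * 60, sd = 0.1)
    a[1:30, ] <- 3 # first segment constant on the reference side
    got <- stoi_mfcc(fake_mfcc(a), fake_mfcc(b), segment_frames = 30)
    expect_equal(attr(got, "n_skipped"), 1L)
    expect_equal(
      as.numeric(got),
      pearson_oracle(as.numeric(t(a[31:60, ])), as.numeric(t(b[31:60, ]))),
      tolerance = 1e-12
    )
  })
})

test_that("constant offsets dissociate the segment score from distortion", {
  withr::with_seed(13, {
    a <- fake_mfcc(matrix(rnorm(13 * 90), 90, 13))
    noisy <- fake_mfcc(unclass(a) + matrix(rnorm(13 * 90, sd = 0.3), 90, 13))
    shifted <- fake_mfcc(unclass(noisy) + 1.5)
    expect_equal(as.numeric(stoi_mfcc(a, shifted)), as.numeric(stoi_mfcc(a, noisy)),
      tolerance = 1e-12
    )
    expect_gt(mcd(a, shifted), mcd(a, noisy))
  })
})

test_that("whole-utterance correlation and the bundled record behave on identical audio", {
  w <- synth_utterance("complex", 1.2, seed = 3)
  pair <- identity_pair(w)
  expect_equal(cc_full(pair), 1)
  rec <- evaluate_pair(pair)
  expect_equal(rec$cc, 1)
  expect_equal(rec$stoi, 1)
  expect_equal(rec$mcd, 0)
  expect_true(rec$entropy > 0 && rec$entropy < 1)
  expect_match(rec$config_hash, "^[0-9a-f]+$")
  # deterministic re-evaluation is bit-identical
  expect_identical(rec, evaluate_pair(pair))
})

test_that("whole-utterance correlation degrades with increasing noise", {
  w <- synth_utterance("complex", 1.2, seed = 4)
  ccs <- vapply(c(0.005, 0.05, 0.3), function(ns) {
    vals <- vapply(1:5, function(s) {
      rec <- degrade(w, degradation_spec(noise_sd = ns, seed = s))
      cc_full(align_pair(w, rec))
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(ccs) < 0))
  expect_lt(ccs[1], 1)
})

test_that("window-sensitivity curve has the contracted shape and identity value", {
  w <- synth_utterance("complex", 2.5, seed = 6)
  pair <- identity_pair(w)
  cur <- cc_window_sensitivity(pair, c(0.3, 0.8, 2))
  expect_equal(nrow(cur), 3)
  expect_equal(cur$mean_cc, rep(1, 3))
  expect_false(any(cur$flagged))
  # a window longer than the audio is flagged as a single-window entry
  over <- cc_window_sensitivity(pair, 10)
  expect_true(over$flagged)
  expect_equal(over$n_windows, 1L)
})
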