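#' Pearson correlation coefficient
#'
#' Thin, checked wrapper used by every correlation-based metric in the
#' package. Constant input has no defined correlation and raises an error;
#' callers (the STOI variant, the window-sensitivity curve) decide how to
#' handle that case.
#'
#' @param x,y Equal-length numeric vectors, `n >= 2`, neither constant.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.", class = "wavescore_invalid_input")
  }
  if (length(x) < 2) {
    abort("Correlation needs at least two points.", class = "wavescore_invalid_input")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation undefined for constant input.", class = "wavescore_undefined")
  }
  cor(x, y)
}

#' Whole-utterance correlation on MFCC features
#'
#' Pearson correlation between the flattened MFCC matrices of reference and
#' reconstruction, over the entire utterance with silent periods included.
#' This is the single-number CC most of the speech-BCI literature reports,
#' computed on the same feature substrate as the other metrics.
#'
#' @param pair An `audio_pair` from [align_pair()].
#' @param config A [feature_config()].
#' @return Correlation in `[-1, 1]`.
#' @export
cc_full <- function(pair, config = feature_config()) {
  stopifnot(inherits(pair, "audio_pair"))
  a <- mfcc_from_config(pair$reference, config)
  b <- mfcc_from_config(pair$reconstruction, config)
  pearson_cc(as.numeric(t(unclass(a))), as.numeric(t(unclass(b))))
}

#' Short-time segment-correlation intelligibility score on MFCCs
#'
#' The MFCC-domain STOI variant: frames are partitioned into consecutive
#' non-overlapping segments of `segment_frames`; for each full segment the
#' Pearson correlation between the flattened reference and reconstruction
#' sub-matrices is computed; the score is the mean over segments. Trailing
#' frames that do not fill a segment are dropped. Segments where either
#' side is constant are skipped; the number skipped is reported in the
#' `n_skipped` attribute. If the matrices hold fewer frames than one
#' segment, a single segment covering all frames is used and flagged
#' (`fallback` attribute).
#'
#' @param ref,rec Comparable `mfcc_matrix` objects with equal frame counts.
#' @param segment_frames Frames per segment (default 30, i.e. ~300 ms at a
#'   10 ms hop — the standard short-time analysis length).
#' @return A score in `[-1, 1]` with attributes `n_segments`, `n_skipped`,
#'   `fallback`.
#' @export
stoi_mfcc <- function(ref, rec, segment_frames = 30) {
  check_comparable_mfcc(ref, rec)
  t_frames <- nrow(ref)
  if (nrow(rec) != t_frames) {
    abort("Frame-count mismatch: align the pair before computing features.",
      class = "wavescore_invalid_input"
    )
  }
  fallback <- FALSE
  if (t_frames < segment_frames) {
    segment_frames <- t_frames
    fallback <- TRUE
  }
  n_seg <- t_frames %/% segment_frames
  cors <- numeric(0)
  n_skipped <- 0L
  for (j in seq_len(n_seg)) {
    idx <- ((j - 1) * segment_frames + 1):(j * segment_frames)
    a <- as.numeric(t(unclass(ref)[idx, , drop = FALSE]))
    b <- as.numeric(t(unclass(rec)[idx, , drop = FALSE]))
    if (sd(a) == 0 || sd(b) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    cors <- c(cors, cor(a, b))
  }
  if (length(cors) == 0) {
    abort("All segments constant: STOI undefined for this pair.",
      class = "wavescore_undefined"
    )
  }
  structure(mean(cors),
    n_segments = n_seg, n_skipped = n_skipped, fallback = fallback
  )
}

#' Mel cepstral distortion
#'
#' Decibel-scaled Euclidean distance between MFCC frames:
#' `(10/ln 10) * sqrt(2) * mean_t ||c(t) - c_hat(t)||`, with the sum over
#' coefficients `1..M-1` when `exclude_c0` (the conventional choice — the
#' energy term is dropped) or `0..M-1` otherwise.
#'
#' @param ref,rec Comparable `mfcc_matrix` objects with equal frame counts.
#' @param exclude_c0 Drop the energy coefficient c0 (default `TRUE`).
#' @return Distortion in dB (`>= 0`; 0 iff the compared coefficients are
#'   identical).
#' @export
mcd <- function(ref, rec, exclude_c0 = TRUE) {
  check_comparable_mfcc(ref, rec)
  if (nrow(ref) != nrow(rec)) {
    abort("Frame-count mismatch: align the pair before computing features.",
      class = "wavescore_invalid_input"
    )
  }
  m <- ncol(ref)
  cols <- if (exclude_c0) seq(2, m) else seq_len(m)
  d <- unclass(ref)[, cols, drop = FALSE] - unclass(rec)[, cols, drop = FALSE]
  (10 / log(10)) * sqrt(2) * mean(sqrt(rowSums(d^2)))
}

#' Correlation-vs-window-length sensitivity curve
#'
#' Splits the aligned pair into consecutive non-overlapping windows of each
#' requested length, computes the whole-window MFCC correlation per window,
#' and averages. Longer windows inflate correlation whenever the coarse
#' energy envelope is shared even though fine structure is not — the
#' mechanism that makes CC values incomparable across studies using
#' different window sizes. Windows longer than the audio yield a flagged
#' single-window entry; windows whose correlation is undefined (constant
#' features) are skipped and counted.
#'
#' @param pair An `audio_pair`.
#' @param window_lengths Window lengths in seconds.
#' @param config A [feature_config()].
#' @return A `cc_window_curve` tibble: `window_s`, `mean_cc`, `n_windows`,
#'   `n_failed`, `flagged`.
#' @export
cc_window_sensitivity <- function(pair, window_lengths, config = feature_config()) {
  stopifnot(inherits(pair, "audio_pair"))
  rate <- pair$reference$rate
  n <- length(pair$reference$samples)
  rows <- purrr::map(window_lengths, function(wl) {
    ws <- floor(wl * rate)
    flagged <- ws > n
    n_win <- if (flagged) 1L else max(1L, n %/% ws)
    if (flagged) ws <- n
    ccs <- purrr::map_dbl(seq_len(n_win), function(k) {
      idx <- ((k - 1) * ws + 1):(k * ws)
      sub <- align_pair(
        waveform(pair$reference$samples[idx], rate, pair$reference$id),
        waveform(pair$reconstruction$samples[idx], rate, pair$reconstruction$id)
      )
      tryCatch(cc_full(sub, config), error = function(e) NA_real_)
    })
    tibble(
      window_s = wl, mean_cc = mean(ccs, na.rm = TRUE),
      n_windows = n_win, n_failed = sum(is.na(ccs)), flagged = flagged
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cc_window_curve", class(out))
  out
}

#' Evaluate one reference/reconstruction pair
#'
#' Computes the full per-trial objective record: whole-utterance MFCC
#' correlation (CC), the short-time segment correlation score (STOI
#' variant), mel cepstral distortion (MCD), and the normalized spectrogram
#' entropy of the *reference* (the complexity gate). The feature
#' configuration used is attached and hashed so records are only ever
#' compared like-for-like.
#'
#' @param pair An `audio_pair`.
#' @param config A [feature_config()].
#' @return A one-row tibble: `trial_id`, `dataset_id`, `cc`, `stoi`,
#'   `stoi_skipped`, `mcd`, `entropy`, `n_frames`, `config_hash`; the full
#'   configuration in the `feature_config` attribute.
#' @export
evaluate_pair <- function(pair, config = feature_config()) {
  stopifnot(inherits(pair, "audio_pair"))
  a <- mfcc_from_config(pair$reference, config)
  b <- mfcc_from_config(pair$reconstruction, config)
  cc <- pearson_cc(as.numeric(t(unclass(a))), as.numeric(t(unclass(b))))
  st <- stoi_mfcc(a, b, segment_frames = config$segment_frames)
  md <- mcd(a, b, exclude_c0 = config$exclude_c0)
  ent <- normalized_entropy(stft_magnitude(pair$reference, config$frame_len, config$hop))
  out <- tibble(
    trial_id = pair$trial_id, dataset_id = pair$dataset_id,
    cc = cc, stoi = as.numeric(st), stoi_skipped = attr(st, "n_skipped"),
    mcd = md, entropy = ent, n_frames = nrow(a), config_hash = config_hash(config)
  )
  attr(out, "feature_config") <- config
  out
}

#' Evaluate a table of audio pairs
#'
#' @param pairs A tibble with a `pair` list-column of `audio_pair` objects
#'   (as produced by [pair_directories()] or [make_benchmark()]).
#' @param config A [feature_config()].
#' @return A tibble with one metric record per pair (see [evaluate_pair()]).
#' @export
evaluate_pairs <- function(pairs, config = feature_config()) {
  stopifnot(is.data.frame(pairs), "pair" %in% names(pairs))
  out <- dplyr::bind_rows(purrr::map(pairs$pair, evaluate_pair, config = config))
  attr(out, "feature_config") <- config
  out
}
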