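#' Feature-extraction configuration
#'
#' Bundles every framing and MFCC setting the objective metrics depend on.
#' Two metric values are only comparable when they were computed under the
#' same configuration, so the configuration (and its hash) travels with
#' every metric record.
#'
#' @param rate Working sample rate, Hz.
#' @param frame_len Analysis frame length, seconds.
#' @param hop Hop between frames, seconds.
#' @param n_coef Number of MFCC coefficients kept (c0..c_{n_coef-1}).
#' @param n_mels Number of mel filterbank bands.
#' @param segment_frames Frames per short-time segment of the STOI variant.
#' @param exclude_c0 Should MCD drop the energy coefficient c0?
#' @return A `feature_config` list.
#' @export
feature_config <- function(rate = 16000, frame_len = 0.025, hop = 0.010,
                           n_coef = 13, n_mels = 40, segment_frames = 30,
                           exclude_c0 = TRUE) {
  if (frame_len < hop || hop <= 0) {
    abort("Require frame_len >= hop > 0.", class = "wavescore_config_error")
  }
  if (n_coef > n_mels) {
    abort("`n_coef` cannot exceed `n_mels`.", class = "wavescore_config_error")
  }
  structure(
    list(
      rate = rate, frame_len = frame_len, hop = hop, n_coef = n_coef,
      n_mels = n_mels, segment_frames = segment_frames, exclude_c0 = exclude_c0
    ),
    class = "feature_config"
  )
}

config_hash <- function(config) rlang::hash(unclass(config))

# slice a signal into a frame-matrix (frame_samples x n_frames);
# n_frames = 1 + floor((n - frame)/hop), trailing partial frame dropped
frame_signal <- function(x, frame_samples, hop_samples) {
  n <- length(x)
  if (n < frame_samples) {
    abort("Waveform shorter than one analysis frame.", class = "wavescore_empty_input")
  }
  n_frames <- 1L + (n - frame_samples) %/% hop_samples
  idx <- outer(seq_len(frame_samples), (seq_len(n_frames) - 1L) * hop_samples, `+`)
  matrix(x[idx], nrow = frame_samples)
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

#' Short-time Fourier magnitude spectrogram
#'
#' Hann-windowed STFT magnitudes, frames as rows. The FFT length is the
#' next power of two at or above the frame length.
#'
#' @param w A [waveform()].
#' @param frame_len Frame length in seconds.
#' @param hop Hop in seconds.
#' @return A `spectrogram`: a frames x bins nonnegative matrix with
#'   attributes `rate`, `frame_len`, `hop`, `freqs`.
#' @export
stft_magnitude <- function(w, frame_len = 0.025, hop = 0.010) {
  stopifnot(inherits(w, "waveform"))
  if (frame_len < hop || hop <= 0) {
    abort("Require frame_len >= hop > 0.", class = "wavescore_config_error")
  }
  frame_samples <- round(frame_len * w$rate)
  hop_samples <- round(hop * w$rate)
  frames <- frame_signal(w$samples, frame_samples, hop_samples)
  nfft <- 2^ceiling(log2(frame_samples))
  win <- hann_window(frame_samples)
  padded <- rbind(frames * win, matrix(0, nfft - frame_samples, ncol(frames)))
  spec <- Mod(mvfft(padded))[seq_len(nfft / 2 + 1), , drop = FALSE]
  structure(
    t(spec),
    class = c("spectrogram", "matrix", "array"),
    rate = w$rate, frame_len = frame_len, hop = hop,
    freqs = (0:(nfft / 2)) * w$rate / nfft
  )
}

# HTK mel scale
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

mel_filterbank <- function(n_mels, nfft, rate) {
  edges <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(rate / 2), length.out = n_mels + 2))
  bin_freqs <- (0:(nfft / 2)) * rate / nfft
  fb <- matrix(0, n_mels, nfft / 2 + 1)
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; ce <- edges[m + 1]; hi <- edges[m + 2]
    up <- (bin_freqs - lo) / (ce - lo)
    down <- (hi - bin_freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# orthonormal DCT-II matrix (n_coef x n_in)
dct_matrix <- function(n_coef, n_in) {
  k <- seq_len(n_coef) - 1
  n <- seq_len(n_in) - 1
  d <- sqrt(2 / n_in) * cos(pi * outer(k, n + 0.5) / n_in)
  d[1, ] <- d[1, ] / sqrt(2)
  d
}

#' Mel-frequency cepstral coefficients
#'
#' Standard MFCC pipeline: Hann-windowed power spectrum, triangular mel
#' filterbank, log energies with an 80 dB dynamic-range floor relative to
#' the loudest band, orthonormal DCT-II keeping coefficients
#' `0..n_coef-1`. The energy coefficient c0 is always present
#' in the output; downstream operations decide whether to exclude it.
#'
#' @inheritParams stft_magnitude
#' @param n_coef Number of cepstral coefficients kept.
#' @param n_mels Number of mel bands.
#' @return An `mfcc_matrix`: frames x `n_coef` matrix with the framing
#'   settings as attributes.
#' @export
mfcc <- function(w, n_coef = 13, frame_len = 0.025, hop = 0.010, n_mels = 40) {
  stopifnot(inherits(w, "waveform"))
  if (n_coef > n_mels) {
    abort("`n_coef` cannot exceed `n_mels`.", class = "wavescore_config_error")
  }
  spec <- stft_magnitude(w, frame_len, hop)
  nfft_bins <- ncol(spec)
  fb <- mel_filterbank(n_mels, (nfft_bins - 1) * 2, w$rate)
  mel_energy <- unclass(spec)^2 %*% t(fb) # frames x n_mels
  # dynamic-range-limited log: floor 80 dB below the loudest band energy
  # (absolute fallback for all-zero input); keeps cepstra finite and scale-
  # covariant, and turns pure-silence frames into constant vectors
  floor_e <- max(max(mel_energy) * 1e-5, 1e-12)
  log_e <- log(pmax(mel_energy, floor_e))
  cep <- log_e %*% t(dct_matrix(n_coef, n_mels)) # frames x n_coef
  structure(
    cep,
    class = c("mfcc_matrix", "matrix", "array"),
    rate = w$rate, frame_len = frame_len, hop = hop,
    n_coef = n_coef, n_mels = n_mels, includes_c0 = TRUE
  )
}

mfcc_from_config <- function(w, config) {
  mfcc(w,
    n_coef = config$n_coef, frame_len = config$frame_len,
    hop = config$hop, n_mels = config$n_mels
  )
}

check_comparable_mfcc <- function(a, b) {
  stopifnot(inherits(a, "mfcc_matrix"), inherits(b, "mfcc_matrix"))
  for (at in c("n_coef", "frame_len", "hop")) {
    if (!isTRUE(all.equal(attr(a, at), attr(b, at)))) {
      abort(sprintf("MFCC matrices differ in '%s'; recompute under one configuration.", at),
        class = "wavescore_config_error"
      )
    }
  }
  invisible(TRUE)
}

#' Normalized Shannon entropy of a spectrogram
#'
#' Treats the full time-frequency magnitude matrix as one discrete
#' distribution: `p_i = m_i / sum(m)` over all cells, `H = -sum(p log p)`
#' (with `0 log 0 = 0`), returned as `H / log(K)` where `K` is the total
#' number of cells. The result lies in `[0, 1]`, is invariant to global
#' amplitude scaling, and is base-invariant. Simple narrowband utterances
#' score low; broadband multi-syllable material scores high — this is the
#' complexity measure gating the two regimes of the piecewise scorer.
#'
#' @param x A `spectrogram` (or any nonnegative matrix), or a [waveform()]
#'   (its spectrogram is computed with default framing).
#' @return A scalar in `[0, 1]`.
#' @export
normalized_entropy <- function(x) {
  if (inherits(x, "waveform")) x <- stft_magnitude(x)
  m <- as.numeric(x)
  if (any(m < 0) || !all(is.finite(m))) {
    abort("Magnitudes must be finite and nonnegative.", class = "wavescore_invalid_input")
  }
  total <- sum(m)
  if (total == 0) {
    abort("Entropy undefined: all-zero spectrogram.", class = "wavescore_undefined")
  }
  p <- m / total
  p <- p[p > 0]
  h <- -sum(p * log(p))
  h / log(length(m))
}
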