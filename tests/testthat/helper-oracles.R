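# Independent oracles, written directly from the defining formulas and kept
# free of any package internals.

# Pearson correlation by direct evaluation of the sum formula
pearson_oracle <- function(x, y) {
  n <- length(x)
  xb <- sum(x) / n
  yb <- sum(y) / n
  num <- sum((x - xb) * (y - yb))
  num / sqrt(sum((x - xb)^2) * sum((y - yb)^2))
}

# mel cepstral distortion by explicit double loop over frames and coefficients
mcd_oracle <- function(a, b, exclude_c0 = TRUE) {
  t_frames <- nrow(a)
  cols <- if (exclude_c0) 2:ncol(a) else 1:ncol(a)
  acc <- 0
  for (t in seq_len(t_frames)) {
    s <- 0
    for (m in cols) s <- s + (a[t, m] - b[t, m])^2
    acc <- acc + sqrt(s)
  }
  (10 / log(10)) * sqrt(2) * acc / t_frames
}

# coefficient of determination from its sum-of-squares definition
r2_oracle <- function(pred, truth) {
  1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2)
}

# Cronbach's alpha from the variance formula on a trials x raters matrix
alpha_oracle <- function(m) {
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / var(rowSums(m)))
}

# wrap a plain matrix as an mfcc_matrix with default framing metadata
fake_mfcc <- function(m, frame_len = 0.025, hop = 0.01) {
  structure(
    as.matrix(m),
    class = c("mfcc_matrix", "matrix", "array"),
    rate = 16000, frame_len = frame_len, hop = hop,
    n_coef = ncol(m), n_mels = 40, includes_c0 = TRUE
  )
}

# short test tone
test_tone <- function(freq = 440, duration = 1, rate = 16000, amp = 0.5) {
  waveform(amp * sin(2 * pi * freq * (seq_len(duration * rate) - 1) / rate), rate, "tone")
}

# identity pair from any waveform
identity_pair <- function(w) align_pair(w, w, trial_id = w$id)

# hand-written stereo 16-bit PCM WAV writer (interleaved), independent of
# the package's mono writer
write_stereo_wav <- function(path, left, right, rate) {
  pcm <- as.integer(round(pmin(pmax(c(rbind(left, right)), -1), 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nbytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 2L), con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate) * 4L, con, size = 4, endian = "little")
  writeBin(c(4L, 16L), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
}
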