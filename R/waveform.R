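#' Construct a waveform object
#'
#' A waveform is the unit of audio in wavescore: a numeric vector of
#' amplitude samples in `[-1, 1]` together with its sample rate in Hz and an
#' identifier used to label per-trial results.
#'
#' @param samples Numeric vector of amplitude samples. All values must be
#'   finite.
#' @param rate Sample rate in Hz (positive scalar).
#' @param id Character label for the waveform (defaults to `"wave"`).
#' @return An object of class `waveform`: a list with elements `samples`,
#'   `rate`, and `id`.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 1, by = 1 / 16000)), 16000, "a440")
#' wave_duration(w)
#' @export
waveform <- function(samples, rate, id = "wave") {
  if (!is.numeric(samples) || length(samples) == 0) {
    abort("`samples` must be a non-empty numeric vector.", class = "wavescore_empty_input")
  }
  if (!all(is.finite(samples))) {
    abort("All waveform samples must be finite.", class = "wavescore_invalid_input")
  }
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    abort("`rate` must be a single positive number (Hz).", class = "wavescore_invalid_input")
  }
  structure(
    list(samples = as.numeric(samples), rate = as.numeric(rate), id = as.character(id)),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf(
    "<waveform '%s': %d samples @ %g Hz (%.3f s), peak %.3f>\n",
    x$id, length(x$samples), x$rate, wave_duration(x), max(abs(x$samples))
  ))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param w A `waveform`.
#' @return Duration in seconds.
#' @export
wave_duration <- function(w) {
  stopifnot(inherits(w, "waveform"))
  length(w$samples) / w$rate
}

# ---- RIFF/WAVE I/O -----------------------------------------------------
# Minimal RIFF PCM reader/writer. Supports 8/16/32-bit integer PCM and
# 32/64-bit IEEE float, mono or interleaved multichannel. No R audio
# package is assumed.

read_wav_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) {
    abort(sprintf("'%s' is not a RIFF/WAV file.", path), class = "wavescore_io_error")
  }
  readBin(con, "integer", 1, 4, endian = "little") # riff size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    abort(sprintf("'%s' is not a WAVE file.", path), class = "wavescore_io_error")
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id, type = "bytes") < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(sz) == 0) break
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        format   = readBin(raw[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        rate     = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits     = readBin(raw[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
      # WAVE_FORMAT_EXTENSIBLE: actual format lives in the subformat GUID
      if (fmt$format == 65534L && length(raw) >= 26) {
        fmt$format <- readBin(raw[25:26], "integer", 1, 2, signed = FALSE, endian = "little")
      }
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz)
    }
    if (sz %% 2 == 1) readBin(con, "raw", 1) # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    abort(sprintf("Malformed WAV file '%s' (missing fmt/data chunk).", path),
      class = "wavescore_io_error"
    )
  }
  bytes <- fmt$bits %/% 8
  n <- length(data_raw) %/% bytes
  x <- if (fmt$format == 1L) { # integer PCM
    if (fmt$bits == 16) {
      readBin(data_raw, "integer", n, 2, signed = TRUE, endian = "little") / 32768
    } else if (fmt$bits == 8) {
      (readBin(data_raw, "integer", n, 1, signed = FALSE) - 128) / 128
    } else if (fmt$bits == 32) {
      readBin(data_raw, "integer", n, 4, endian = "little") / 2147483648
    } else {
      abort(sprintf("Unsupported PCM bit depth %d in '%s'.", fmt$bits, path),
        class = "wavescore_io_error"
      )
    }
  } else if (fmt$format == 3L) { # IEEE float
    readBin(data_raw, "numeric", n, bytes, endian = "little")
  } else {
    abort(sprintf("Unsupported WAV format code %d in '%s'.", fmt$format, path),
      class = "wavescore_io_error"
    )
  }
  list(samples = x, channels = fmt$channels, rate = fmt$rate)
}

#' Load a WAV file as a mono waveform at a target sample rate
#'
#' Reads a RIFF PCM/float WAV file, averages channels to mono, resamples to
#' `target_rate`, and peak-normalizes only if any sample exceeds 1 in
#' magnitude. No silence trimming or loudness normalization is applied:
#' whole utterances, silent periods included, are what the downstream
#' metrics are defined on.
#'
#' @param path Path to a readable WAV file.
#' @param target_rate Desired sample rate in Hz (default 16000, the
#'   speech-band standard used throughout the package).
#' @param id Identifier for the waveform; defaults to the file basename
#'   without extension.
#' @return A [waveform()].
#' @export
load_waveform <- function(path, target_rate = 16000, id = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("Cannot read WAV file '%s': no such file.", path),
      class = "wavescore_io_error"
    )
  }
  if (!is.numeric(target_rate) || target_rate <= 0) {
    abort("`target_rate` must be positive.", class = "wavescore_invalid_input")
  }
  raw <- read_wav_raw(path)
  if (length(raw$samples) == 0) {
    abort(sprintf("WAV file '%s' contains no audio.", path), class = "wavescore_empty_input")
  }
  x <- raw$samples
  if (raw$channels > 1) {
    usable <- (length(x) %/% raw$channels) * raw$channels
    x <- rowMeans(matrix(x[seq_len(usable)], ncol = raw$channels, byrow = TRUE))
  }
  x <- resample_samples(x, raw$rate, target_rate)
  peak <- max(abs(x))
  if (peak > 1) x <- x / peak
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  waveform(x, target_rate, id = id)
}

# polyphase resampling via signal::resample; integer rates assumed
resample_samples <- function(x, from_rate, to_rate) {
  if (from_rate == to_rate) {
    return(x)
  }
  g <- gcd_int(round(to_rate), round(from_rate))
  as.numeric(signal::resample(x, round(to_rate) / g, round(from_rate) / g))
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Write a waveform to a 16-bit PCM WAV file
#'
#' @param w A [waveform()]. Samples outside `[-1, 1]` are clipped.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  x <- pmin(pmax(w$samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  data_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little") # PCM
  writeBin(1L, con, size = 2, endian = "little") # mono
  writeBin(as.integer(round(w$rate)), con, size = 4, endian = "little")
  writeBin(as.integer(round(w$rate)) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little") # block align
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Pair a reference and a reconstruction at equal length
#'
#' Brings two waveforms of the same sample rate to a common sample count.
#' `"truncate"` (the default) cuts both to the shorter length; `"pad"`
#' zero-pads the shorter at the end. No time warping is performed: the
#' metrics compare whole utterances as-is.
#'
#' @param ref Reference [waveform()] (clean speech).
#' @param rec Reconstructed [waveform()].
#' @param policy `"truncate"` or `"pad"`.
#' @param dataset_id,trial_id Labels carried into metric records. `trial_id`
#'   defaults to the reference id.
#' @return An `audio_pair`: a list with `reference`, `reconstruction`,
#'   `dataset_id`, `trial_id`.
#' @export
align_pair <- function(ref, rec, policy = c("truncate", "pad"),
                       dataset_id = "", trial_id = NULL) {
  stopifnot(inherits(ref, "waveform"), inherits(rec, "waveform"))
  policy <- match.arg(policy)
  if (!isTRUE(all.equal(ref$rate, rec$rate))) {
    abort(
      sprintf(
        "Sample-rate mismatch (%g vs %g Hz): resample both waveforms to a common rate first.",
        ref$rate, rec$rate
      ),
      class = "wavescore_rate_mismatch"
    )
  }
  n_ref <- length(ref$samples)
  n_rec <- length(rec$samples)
  if (policy == "truncate") {
    n <- min(n_ref, n_rec)
    ref$samples <- ref$samples[seq_len(n)]
    rec$samples <- rec$samples[seq_len(n)]
  } else {
    n <- max(n_ref, n_rec)
    ref$samples <- c(ref$samples, rep(0, n - n_ref))
    rec$samples <- c(rec$samples, rep(0, n - n_rec))
  }
  if (is.null(trial_id)) trial_id <- ref$id
  structure(
    list(
      reference = ref, reconstruction = rec,
      dataset_id = as.character(dataset_id), trial_id = as.character(trial_id)
    ),
    class = "audio_pair"
  )
}

#' @export
print.audio_pair <- function(x, ...) {
  cat(sprintf(
    "<audio_pair '%s' (dataset '%s'): %d samples @ %g Hz>\n",
    x$trial_id, x$dataset_id, length(x$reference$samples), x$reference$rate
  ))
  invisible(x)
}

#' Pair matching WAV files from a reference and a reconstruction directory
#'
#' Files are matched on basename (without extension); `<name>_ref` /
#' `<name>_rec` suffixes, if present, are stripped before matching so a
#' single flat layout also works. Unmatched files are reported in the
#' `unmatched` attribute.
#'
#' @param ref_dir,rec_dir Directories of WAV files.
#' @param target_rate Working sample rate in Hz.
#' @param policy Alignment policy passed to [align_pair()].
#' @param dataset_id Dataset label for every pair.
#' @return A tibble with columns `trial_id` and `pair` (a list-column of
#'   `audio_pair` objects).
#' @export
pair_directories <- function(ref_dir, rec_dir, target_rate = 16000,
                             policy = "truncate", dataset_id = "") {
  key_of <- function(f) sub("_(ref|rec)$", "", sub("\\.[^.]*$", "", basename(f)))
  refs <- list.files(ref_dir, pattern = "\\.wav$", ignore.case = TRUE, full.names = TRUE)
  recs <- list.files(rec_dir, pattern = "\\.wav$", ignore.case = TRUE, full.names = TRUE)
  if (normalizePath(ref_dir) == normalizePath(rec_dir)) {
    # flat layout: one directory of <trial>_ref.wav / <trial>_rec.wav
    refs <- refs[grepl("_ref\\.wav$", refs, ignore.case = TRUE)]
    recs <- recs[grepl("_rec\\.wav$", recs, ignore.case = TRUE)]
  }
  ref_keys <- key_of(refs)
  rec_keys <- key_of(recs)
  common <- sort(intersect(ref_keys, rec_keys))
  if (length(common) == 0) {
    abort("No matching WAV basenames between the two directories.",
      class = "wavescore_empty_input"
    )
  }
  pairs <- purrr::map(common, function(k) {
    ref <- load_waveform(refs[match(k, ref_keys)], target_rate, id = k)
    rec <- load_waveform(recs[match(k, rec_keys)], target_rate, id = k)
    align_pair(ref, rec, policy = policy, dataset_id = dataset_id, trial_id = k)
  })
  out <- tibble(trial_id = common, pair = pairs)
  attr(out, "unmatched") <- c(setdiff(ref_keys, rec_keys), setdiff(rec_keys, ref_keys))
  out
}
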