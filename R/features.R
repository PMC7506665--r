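#' Short-time Fourier transform of a recording
#'
#' Frame length 4096 samples, hop 2048 (the classifier's analysis grid at a
#' 192 kHz rate), Hann window. Frame count is `1 + floor((N - window) /
#' hop)`; trailing samples that do not fill a window are dropped.
#'
#' @param recording An [audio_recording()].
#' @param window_len,hop_len Analysis window and hop in samples.
#' @return A `spectrogram` object: `magnitudes` (frames x bins, bins =
#'   `window_len/2 + 1`), `bin_hz` (bin centre frequencies),
#'   `frame_times_s`, plus the analysis parameters.
#' @export
stft <- function(recording, window_len = 4096L, hop_len = 2048L) {
  stopifnot(inherits(recording, "audio_recording"))
  x <- recording$samples
  n <- length(x)
  if (n < window_len) {
    stop(sprintf("stft: recording has %d samples, shorter than one %d-sample window",
                 n, window_len))
  }
  n_frames <- 1L + (n - window_len) %/% hop_len
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(window_len) / window_len) # periodic Hann
  starts <- (seq_len(n_frames) - 1L) * hop_len
  frames <- matrix(x[outer(seq_len(window_len), starts, `+`)],
                   nrow = window_len)
  frames <- frames * w
  spec <- Mod(stats::mvfft(frames))[seq_len(window_len %/% 2L + 1L), ,
                                    drop = FALSE]
  fs <- recording$sample_rate_hz
  structure(
    list(
      magnitudes = t(spec),
      bin_hz = (seq_len(window_len %/% 2L + 1L) - 1L) * fs / window_len,
      frame_times_s = (starts + window_len / 2) / fs,
      window_len = window_len, hop_len = hop_len,
      sample_rate_hz = fs
    ),
    class = "spectrogram"
  )
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Mel filter bank with a hard frequency ceiling
#'
#' `n_mels` triangular filters on the HTK mel scale spanning `[0, fmax_hz]`,
#' normalised to unit peak. The 2000 Hz default ceiling restricts the
#' classifier to the band where AVF bruit carries information.
#'
#' With the reference analysis grid (window 4096 at 192 kHz) only
#' `floor(2000 / 46.875) + 1 = 43` linear bins lie at or below 2000 Hz, so
#' filter counts above that cannot all hold a bin centre; such filters are
#' realised by linear interpolation from the two nearest bins and a warning
#' is raised, since neighbouring filters are then no longer independent.
#'
#' @param n_mels Number of filters (the study swept 64–1024).
#' @param fmax_hz Top edge of the highest filter.
#' @param sample_rate_hz,window_len Analysis parameters defining the bin grid.
#' @param warn_interpolated Warn when `n_mels` exceeds the in-band bin
#'   count. Bulk featurizers that construct the same bank repeatedly pass
#'   `FALSE`, since the condition is a fixed property of the configuration.
#' @return `n_mels` x `(window_len/2 + 1)` weight matrix with attribute
#'   `centre_hz` (filter peak frequencies).
#' @export
mel_filterbank <- function(n_mels, fmax_hz = 2000, sample_rate_hz = 192000L,
                           window_len = 4096L, warn_interpolated = TRUE) {
  if (n_mels < 1L) stop("mel_filterbank: n_mels must be >= 1")
  if (fmax_hz > sample_rate_hz / 2) {
    stop("mel_filterbank: fmax_hz above Nyquist")
  }
  n_bins <- window_len %/% 2L + 1L
  bin_hz <- (seq_len(n_bins) - 1L) * sample_rate_hz / window_len
  n_inband <- sum(bin_hz <= fmax_hz)
  if (n_mels > n_inband && warn_interpolated) {
    warning(sprintf(
      "mel_filterbank: %d filters over only %d bins at or below %g Hz; filters without a bin centre are interpolated and are not independent",
      n_mels, n_inband, fmax_hz
    ))
  }
  edges <- mel_to_hz(seq(0, hz_to_mel(fmax_hz), length.out = n_mels + 2L))
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; mid <- edges[m + 1L]; hi <- edges[m + 2L]
    up <- (bin_hz - lo) / max(mid - lo, 1e-12)
    down <- (hi - bin_hz) / max(hi - mid, 1e-12)
    w <- pmax(0, pmin(up, down))
    if (all(w == 0)) {
      # no bin falls inside the triangle: interpolate the peak from the
      # two bins bracketing the centre frequency
      j <- findInterval(mid, bin_hz)
      j <- min(max(j, 1L), n_bins - 1L)
      frac <- (mid - bin_hz[j]) / (bin_hz[j + 1L] - bin_hz[j])
      w[j] <- 1 - frac
      w[j + 1L] <- frac
    }
    fb[m, ] <- w / max(w)
  }
  attr(fb, "centre_hz") <- edges[2:(n_mels + 1L)]
  attr(fb, "fmax_hz") <- fmax_hz
  fb
}

#' Log-mel features of a spectrogram
#'
#' Applies the mel filter bank, log-compresses with floor `1e-10`, and
#' standardises the whole clip to zero mean and unit variance (computed over
#' real frames only), which removes global gain: doubling the waveform
#' amplitude leaves the output unchanged.
#'
#' @param spec A [stft()] result.
#' @param filterbank A [mel_filterbank()] matrix.
#' @return A `log_mel_spectrogram`: `values` (frames x n_mels),
#'   `pad_mask` (TRUE = real frame), `n_mels`, `fmax_hz`.
#' @export
log_mel <- function(spec, filterbank) {
  stopifnot(inherits(spec, "spectrogram"))
  if (ncol(filterbank) != ncol(spec$magnitudes)) {
    stop(sprintf("log_mel: filterbank has %d bins but spectrogram has %d",
                 ncol(filterbank), ncol(spec$magnitudes)))
  }
  v <- log(spec$magnitudes %*% t(filterbank) + 1e-10)
  mu <- mean(v)
  s <- sd(v)
  v <- if (is.na(s) || s == 0) v * 0 else (v - mu) / s
  structure(
    list(
      values = v,
      pad_mask = rep(TRUE, nrow(v)),
      n_mels = nrow(filterbank),
      fmax_hz = attr(filterbank, "fmax_hz") %||% NA_real_,
      hop_len = spec$hop_len,
      sample_rate_hz = spec$sample_rate_hz
    ),
    class = "log_mel_spectrogram"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pad a log-mel spectrogram to a fixed time axis
#'
#' Beats vary in length with heart rate, but the classifiers require a
#' constant 400-frame time axis; short beats are blank-padded at the end
#' with the post-standardisation zero value. Real frames are untouched.
#'
#' @param spec A [log_mel()] result.
#' @param target_frames Fixed frame count, default 400.
#' @return A `log_mel_spectrogram` with exactly `target_frames` frames and
#'   an updated `pad_mask`.
#' @export
pad_to_length <- function(spec, target_frames = 400L) {
  stopifnot(inherits(spec, "log_mel_spectrogram"))
  n <- nrow(spec$values)
  if (n > target_frames) {
    stop(sprintf("pad_to_length: input has %d frames, more than target %d",
                 n, target_frames))
  }
  if (n < target_frames) {
    pad <- matrix(0, target_frames - n, ncol(spec$values))
    spec$values <- rbind(spec$values, pad)
    spec$pad_mask <- c(spec$pad_mask, rep(FALSE, target_frames - n))
  }
  spec
}

#' Featurize a beat recording end to end
#'
#' Convenience wrapper: STFT -> mel filter bank -> log compression ->
#' standardisation -> padding to the fixed 400-frame axis.
#'
#' @param recording An [audio_recording()] of one beat.
#' @param n_mels Number of mel filters.
#' @param fmax_hz Mel ceiling.
#' @param target_frames Fixed time axis length.
#' @param window_len,hop_len STFT parameters.
#' @return A padded `log_mel_spectrogram`.
#' @export
featurize_beat <- function(recording, n_mels = 64L, fmax_hz = 2000,
                           target_frames = 400L, window_len = 4096L,
                           hop_len = 2048L) {
  fb <- mel_filterbank(n_mels, fmax_hz, recording$sample_rate_hz, window_len,
                       warn_interpolated = FALSE)
  pad_to_length(log_mel(stft(recording, window_len, hop_len), fb),
                target_frames)
}

#' Materialise log-mel features for a synthetic corpus
#'
#' Realises each [synth_corpus()] row as audio, featurizes it, and discards
#' the waveform, keeping memory proportional to the feature set.
#'
#' @param corpus A [synth_corpus()] result.
#' @param n_mels,sample_rate_hz Feature and synthesis parameters.
#' @param target_frames Fixed time axis length.
#' @return A `bruit_corpus_features` list: `features` (list of
#'   `log_mel_spectrogram`), `labels`, `patient_id`, `split`, `manifest`.
#' @export
corpus_features <- function(corpus, n_mels = 64L, sample_rate_hz = 192000L,
                            target_frames = 400L) {
  fb <- mel_filterbank(n_mels, 2000, sample_rate_hz, 4096L,
                       warn_interpolated = FALSE)
  feats <- lapply(corpus$specs, function(sp) {
    rec <- synth_beat(sp, sample_rate_hz)
    pad_to_length(log_mel(stft(rec), fb), target_frames)
  })
  structure(
    list(
      features = feats,
      labels = corpus$manifest$sound_class,
      patient_id = corpus$manifest$patient_id,
      split = corpus$manifest$split,
      manifest = corpus$manifest
    ),
    class = "bruit_corpus_features"
  )
}
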