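#' Band-limited energy envelope
#'
#' Short-time magnitude spectra are averaged over the bins whose centre
#' frequency falls in `band_hz` (default 2-750 Hz, the band where AVF bruit
#' carries its energy), one value per analysis frame. The 2 Hz lower edge
#' is below the frame resolution and effectively excludes only DC.
#'
#' @param recording An [audio_recording()].
#' @param band_hz Length-2 numeric, `(low, high)` in Hz.
#' @param frame_len_s,hop_s Analysis frame and hop in seconds (defaults
#'   0.05 and 0.01: fine enough to resolve 0.5 s beats).
#' @return An `envelope`: `times_s` (frame centres), `values`
#'   (nonnegative), plus the parameters.
#' @export
band_energy_envelope <- function(recording, band_hz = c(2, 750),
                                 frame_len_s = 0.05, hop_s = 0.01) {
  stopifnot(inherits(recording, "audio_recording"))
  if (!length(recording$samples)) stop("band_energy_envelope: empty audio")
  if (band_hz[1] >= band_hz[2]) stop("band_energy_envelope: inverted band")
  fs <- recording$sample_rate_hz
  if (band_hz[2] > fs / 2) stop("band_energy_envelope: band above Nyquist")
  frame_len <- max(4L, round(frame_len_s * fs))
  hop <- max(1L, round(hop_s * fs))
  x <- recording$samples
  n <- length(x)
  if (n < frame_len) stop("band_energy_envelope: audio shorter than one frame")
  n_frames <- 1L + (n - frame_len) %/% hop
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(frame_len) / frame_len)
  bin_hz <- (seq_len(frame_len %/% 2L + 1L) - 1L) * fs / frame_len
  in_band <- which(bin_hz >= band_hz[1] & bin_hz <= band_hz[2])
  if (!length(in_band)) stop("band_energy_envelope: no bins in band")

  values <- numeric(n_frames)
  chunk <- 512L
  for (c0 in seq(1L, n_frames, by = chunk)) {
    idx <- c0:min(c0 + chunk - 1L, n_frames)
    starts <- (idx - 1L) * hop
    frames <- matrix(x[outer(seq_len(frame_len), starts, `+`)],
                     nrow = frame_len) * w
    spec <- Mod(stats::mvfft(frames))[in_band, , drop = FALSE]
    values[idx] <- colMeans(spec)
  }
  structure(
    list(
      times_s = ((seq_len(n_frames) - 1L) * hop + frame_len / 2) / fs,
      values = values,
      band_hz = band_hz, frame_len_s = frame_len_s, hop_s = hop_s
    ),
    class = "envelope"
  )
}

#' Smooth an envelope with a cubic smoothing spline
#'
#' Noise riding on the envelope creates spurious local extrema that defeat
#' beat detection; a penalised cubic spline fit (evaluated back at the
#' frame times, clipped at zero) removes them.
#'
#' @param envelope An [band_energy_envelope()] result.
#' @param smoothing Spline flexibility in degrees of freedom per second of
#'   envelope. The default 25 gives the fit a ~40 ms resolution: fine
#'   enough to track a systolic rise, coarse enough to iron out
#'   frame-level noise. `0` returns the interpolating limit (values
#'   unchanged at frame times).
#' @return An `envelope` on the same time grid.
#' @export
spline_smooth <- function(envelope, smoothing = 25) {
  stopifnot(inherits(envelope, "envelope"))
  n <- length(envelope$values)
  if (n < 4L) stop("spline_smooth: need at least 4 frames")
  if (is.null(smoothing)) smoothing <- 25
  v <- if (smoothing == 0) {
    envelope$values
  } else {
    span <- diff(range(envelope$times_s))
    df <- max(4, min(n - 1L, round(smoothing * span)))
    nk <- as.integer(min(n, max(df + 2, round(1.5 * df))))
    fit <- stats::smooth.spline(envelope$times_s, envelope$values,
                                df = df, nknots = nk)
    stats::predict(fit, envelope$times_s)$y
  }
  envelope$values <- pmax(v, 0)
  envelope
}

# indices of strict local maxima/minima; plateaus take the leftmost point,
# boundary points are eligible as minima only
local_extrema <- function(v) {
  n <- length(v)
  maxima <- integer(0)
  minima <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[j]) j <- j + 1L
      if (j < n && v[j + 1L] < v[j]) maxima <- c(maxima, i)
      i <- j + 1L
    } else if (v[i] < v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[j]) j <- j + 1L
      if (j < n && v[j + 1L] > v[j]) minima <- c(minima, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  list(maxima = maxima, minima = minima)
}

#' Detect convex single-beat ranges in a smoothed envelope
#'
#' A beat candidate is a local-minimum-to-local-minimum range containing
#' exactly one local maximum of sufficient prominence. Ranges whose
#' duration falls outside `[min_dur_s, max_dur_s]` are discarded, which
#' also drops non-auscultation stretches. Candidates are returned sorted
#' and non-overlapping.
#'
#' @param envelope A smoothed envelope (see [spline_smooth()]).
#' @param min_dur_s,max_dur_s Admissible beat duration bounds (0.5-2 s:
#'   40-120 bpm).
#' @param prominence_frac Minimum peak prominence as a fraction of the
#'   global envelope maximum (suppresses micro-bumps).
#' @param min_rel_prominence Additionally, a peak's prominence must reach
#'   this fraction of its own height. A genuine beat rises from the
#'   inter-beat valley (ratio near 1); a secondary ripple riding on the
#'   diastolic plateau has a low ratio and must not split the beat's
#'   range.
#' @param onset_frac Edge-refinement level: within a convex range, the
#'   reported onset (offset) is the last (first) time the envelope sits
#'   below this fraction of the peak's rise above the bounding minimum.
#'   Without refinement the reported onset would float anywhere inside the
#'   flat inter-beat valley.
#' @return Tibble of beat candidates: `start_s`, `end_s`, `duration_s`,
#'   `peak_value`.
#' @export
detect_convex_ranges <- function(envelope, min_dur_s = 0.5, max_dur_s = 2.0,
                                 prominence_frac = 0.1,
                                 min_rel_prominence = 0.5,
                                 onset_frac = 0.05) {
  stopifnot(inherits(envelope, "envelope"))
  v <- envelope$values
  t <- envelope$times_s
  ext <- local_extrema(v)
  out <- tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                        duration_s = numeric(0), peak_value = numeric(0))
  if (!length(ext$maxima)) return(out)
  floor_prom <- prominence_frac * max(v)
  n <- length(v)

  # prominence of each local maximum: height above the higher of the two
  # valley minima separating it from taller terrain; micro-bumps riding on
  # a beat fall below the floor and do not split its convex range
  prominent <- integer(0)
  for (m in ext$maxima) {
    lo_l <- v[m]
    i <- m
    while (i > 1L && v[i - 1L] <= v[m]) { i <- i - 1L; lo_l <- min(lo_l, v[i]) }
    if (i == 1L) lo_l <- min(lo_l, v[1L])
    lo_r <- v[m]
    i <- m
    while (i < n && v[i + 1L] <= v[m]) { i <- i + 1L; lo_r <- min(lo_r, v[i]) }
    if (i == n) lo_r <- min(lo_r, v[n])
    prom <- v[m] - max(lo_l, lo_r)
    if (prom >= floor_prom && prom >= min_rel_prominence * v[m]) {
      prominent <- c(prominent, m)
    }
  }
  if (!length(prominent)) return(out)
  # boundaries: the lowest point between consecutive prominent peaks
  bounds <- integer(length(prominent) + 1L)
  bounds[1L] <- which.min(v[1L:prominent[1L]])
  if (length(prominent) > 1L) {
    for (k in seq_len(length(prominent) - 1L)) {
      seg <- prominent[k]:prominent[k + 1L]
      bounds[k + 1L] <- seg[which.min(v[seg])]
    }
  }
  bounds[length(bounds)] <-
    (prominent[length(prominent)]:n)[which.min(v[prominent[length(prominent)]:n])]

  rows <- list()
  last_end <- -Inf
  for (k in seq_along(prominent)) {
    m <- prominent[k]
    i0 <- bounds[k]
    i1 <- bounds[k + 1L]
    # the duration filter applies to the convex (min-to-min) range
    dur_range <- t[i1] - t[i0]
    if (dur_range < min_dur_s || dur_range > max_dur_s) next
    # refine the edges to the rise/fall crossings
    thr_l <- v[i0] + onset_frac * (v[m] - v[i0])
    below_l <- which(v[i0:m] <= thr_l)
    j0 <- if (length(below_l)) i0 + max(below_l) - 1L else i0
    thr_r <- v[i1] + onset_frac * (v[m] - v[i1])
    below_r <- which(v[m:i1] <= thr_r)
    j1 <- if (length(below_r)) m + min(below_r) - 1L else i1
    dur <- t[j1] - t[j0]
    if (dur < min_dur_s) next # refined interval must still hold a beat
    if (t[j0] < last_end) next # keep earlier candidate on overlap
    rows[[length(rows) + 1L]] <- tibble::tibble(
      start_s = t[j0], end_s = t[j1], duration_s = dur, peak_value = v[m]
    )
    last_end <- t[j1]
  }
  if (length(rows)) do.call(rbind, rows) else out
}

#' Train the AVF-vs-environment gate classifier
#'
#' A binary classifier (the convolutional trunk of the five-class
#' architecture with a 2-class softmax head) that scores whether a candidate
#' interval contains AVF bruit rather than environmental sound. The study's
#' gate was trained against a 5000-clip real environmental corpus; here the
#' negative class is the package's synthetic environment generator.
#'
#' @param avf_beats List of [audio_recording()]s containing bruit.
#' @param environment_clips List of [audio_recording()]s of environmental
#'   sound.
#' @param n_mels Mel resolution of the gate features.
#' @param base_channels Trunk width (desk-scale default 8).
#' @param config A [training_config()].
#' @return An `avf_gate`: a trained 2-class `bruit_model` plus its feature
#'   parameters.
#' @export
train_gate <- function(avf_beats, environment_clips, n_mels = 64L,
                       base_channels = 8L,
                       config = training_config(epochs = 5L)) {
  if (!length(avf_beats) || !length(environment_clips)) {
    stop("train_gate: both classes must be non-empty")
  }
  feats <- lapply(c(avf_beats, environment_clips), featurize_beat,
                  n_mels = n_mels)
  labels <- c(rep("avf", length(avf_beats)),
              rep("environment", length(environment_clips)))
  spec <- architecture_spec("vgg13", n_mels = n_mels,
                            base_channels = base_channels, n_classes = 2L)
  model <- build_model(spec, seed = config$seed,
                       classes = c("avf", "environment"))
  # interleave simulated patients so the validation split sees both classes
  patient_id <- sprintf("G%02d", (seq_along(labels) %% 8L) + 1L)
  model <- train_model(model, feats, labels, patient_id, config)
  structure(list(model = model, n_mels = n_mels), class = "avf_gate")
}

#' Score the AVF probability of a clip
#'
#' @param gate An [train_gate()] result.
#' @param recording An [audio_recording()].
#' @return Probability in `[0, 1]` that the clip is AVF bruit.
#' @export
gate_probability <- function(gate, recording) {
  stopifnot(inherits(gate, "avf_gate"))
  f <- featurize_beat(recording, n_mels = gate$n_mels,
                      target_frames = gate$model$cfg$input_frames)
  unname(predict(gate$model, f)[1, "avf"])
}

#' Gate beat candidates by AVF probability
#'
#' Each candidate interval is sliced from the recording, featurized and
#' scored; a candidate is accepted if and only if its AVF probability
#' strictly exceeds 0.5 (a score of exactly 0.5 is rejected).
#'
#' @param candidates A [detect_convex_ranges()] tibble.
#' @param recording The source [audio_recording()].
#' @param gate An [train_gate()] result.
#' @return The candidates tibble with `avf_probability` and `accepted`
#'   columns appended.
#' @export
gate_candidates <- function(candidates, recording, gate) {
  stopifnot(inherits(gate, "avf_gate"))
  if (!isTRUE(gate$model$trained)) stop("gate_candidates: untrained gate")
  if (!nrow(candidates)) {
    candidates$avf_probability <- numeric(0)
    candidates$accepted <- logical(0)
    return(candidates)
  }
  feats <- lapply(seq_len(nrow(candidates)), function(i) {
    featurize_beat(
      slice_audio(recording, candidates$start_s[i], candidates$end_s[i]),
      n_mels = gate$n_mels,
      target_frames = gate$model$cfg$input_frames
    )
  })
  p <- predict(gate$model, feats)[, "avf"]
  candidates$avf_probability <- unname(p)
  candidates$accepted <- candidates$avf_probability > 0.5
  candidates
}

#' Full single-beat segmentation of a recording
#'
#' Envelope -> spline smoothing -> convex-range detection -> AVF gate.
#'
#' @param recording An [audio_recording()].
#' @param gate An [train_gate()] result, or `NULL` to skip gating.
#' @param band_hz,frame_len_s,hop_s,smoothing,min_dur_s,max_dur_s,prominence_frac
#'   Stage parameters, passed through.
#' @return Tibble of candidates with gate columns (if a gate was supplied).
#' @export
segment_beats <- function(recording, gate = NULL, band_hz = c(2, 750),
                          frame_len_s = 0.05, hop_s = 0.01, smoothing = NULL,
                          min_dur_s = 0.5, max_dur_s = 2.0,
                          prominence_frac = 0.1) {
  env <- band_energy_envelope(recording, band_hz, frame_len_s, hop_s)
  env <- spline_smooth(env, smoothing)
  cand <- detect_convex_ranges(env, min_dur_s, max_dur_s, prominence_frac)
  if (!is.null(gate)) cand <- gate_candidates(cand, recording, gate)
  cand
}
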