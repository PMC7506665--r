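#' @useDynLib avfbruit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft rnorm runif sd predict smooth.spline spline
#' @importFrom utils head read.csv write.csv
"_PACKAGE"

#' The five bruit sound classes
#'
#' Fixed label order used by every classifier, prediction vector and metric
#' table in the package: normal (baseline bruit), hard (exaggerated systolic
#' peak, raised vascular resistance), high (high-frequency bruit from a long
#' narrow segment), intermittent (diastolic silence, severe obstruction),
#' whistle (narrowband tonal component from a sharp diameter decrease).
#'
#' @return Character vector of length 5.
#' @export
bruit_classes <- function() {
  c("normal", "hard", "high", "intermittent", "whistle")
}

#' Evaluate code under a fixed RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the
#' caller's RNG state afterwards, so seeded synthesis never perturbs an
#' enclosing simulation.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Gaussian noise confined to [lo_hz, hi_hz] by hard FFT-domain masking.
# Direct spectral masking is used instead of an IIR design because the
# band edges (2 Hz at a 192 kHz rate) are far below any stable filter's
# resolution; the mask is exact and deterministic.
band_noise <- function(n, sample_rate_hz, lo_hz, hi_hz) {
  if (n == 0L) return(numeric(0))
  # FFT at the next 5-smooth length (mixed-radix FFTs are slow at lengths
  # with large prime factors), then truncate
  m <- stats::nextn(n, c(2, 3, 5))
  x <- rnorm(m)
  X <- fft(x)
  f <- (seq_len(m) - 1L) / m * sample_rate_hz
  f <- pmin(f, sample_rate_hz - f) # fold to [0, fs/2]
  X[f < lo_hz | f > hi_hz] <- 0+0i
  y <- Re(fft(X, inverse = TRUE))[seq_len(n)] / m
  s <- sd(y)
  if (s > 0) y / s else y
}

# Systolic-peak / diastolic-decay amplitude envelope on [0, 1).
# Raised-cosine systolic bump of width `systolic_fraction`, then an
# exponential decay toward `diastolic_level`.
beat_envelope <- function(n, systolic_fraction, diastolic_level) {
  t <- seq(0, 1, length.out = n + 1L)[seq_len(n)]
  env <- numeric(n)
  sys <- t < systolic_fraction
  env[sys] <- 0.5 - 0.5 * cos(2 * pi * t[sys] / systolic_fraction)
  tau <- 0.25
  env[!sys] <- diastolic_level +
    (env[sum(sys)] - diastolic_level) * exp(-(t[!sys] - systolic_fraction) / tau)
  env <- pmax(env, diastolic_level)
  env
}

#' Specification of one synthetic heartbeat
#'
#' @param sound_class One of [bruit_classes()].
#' @param beat_duration_s Beat length in seconds, in `[0.3, 3]`. The range is
#'   deliberately wider than the segmentation filter's 0.5–2 s window so
#'   rejection paths are exercisable.
#' @param systolic_fraction Fraction of the beat occupied by systole,
#'   in (0, 1). Default 0.35, a typical systole/cycle ratio.
#' @param snr_db Beat-to-environment signal-to-noise ratio in dB used when
#'   the beat is mixed into a recording with environmental sound.
#' @param whistle_hz Tone frequency of the whistle class, 800–1500 Hz.
#' @param seed Integer RNG seed; generation is a pure function of
#'   (spec, seed).
#' @return A `beat_spec` list.
#' @export
beat_spec <- function(sound_class, beat_duration_s = 1.0,
                      systolic_fraction = 0.35, snr_db = 10,
                      whistle_hz = 1000, seed = 1L) {
  sound_class <- match.arg(sound_class, bruit_classes())
  if (!(beat_duration_s >= 0.3 && beat_duration_s <= 3.0)) {
    stop("beat_spec: beat_duration_s must lie in [0.3, 3]")
  }
  if (!(systolic_fraction > 0 && systolic_fraction < 1)) {
    stop("beat_spec: systolic_fraction must lie in (0, 1)")
  }
  structure(
    list(
      sound_class = sound_class, beat_duration_s = beat_duration_s,
      systolic_fraction = systolic_fraction, snr_db = snr_db,
      whistle_hz = whistle_hz, seed = as.integer(seed)
    ),
    class = "beat_spec"
  )
}

#' Synthesise one heartbeat of AVF bruit
#'
#' Each class carries the acoustic signature clinicians describe:
#' * `normal` — band-limited (2–750 Hz) turbulence noise with a systolic
#'   peak and a diastolic tail at ~35% of peak amplitude;
#' * `hard` — the systolic peak is exaggerated (peak/diastole ratio about
#'   12, more than three times the normal class's ~2.9) and the noise band
#'   extends to 1500 Hz, the ceiling of sustained AVF sound;
#' * `high` — systolic noise energy concentrated in 250–750 Hz over a
#'   quieter low-band diastole;
#' * `intermittent` — the diastolic segment is gated to silence,
#'   mimicking flow interruption under severe obstruction;
#' * `whistle` — the normal base plus a narrowband tone at `whistle_hz`
#'   with a slow frequency wobble.
#'
#' @param spec A [beat_spec()].
#' @param sample_rate_hz Sample rate, default 192000 (the reference
#'   recorder).
#' @return An [audio_recording()] of one beat, peak-normalised to 0.9.
#' @export
synth_beat <- function(spec, sample_rate_hz = 192000L) {
  stopifnot(inherits(spec, "beat_spec"))
  n <- round(spec$beat_duration_s * sample_rate_hz)
  if (n <= 0) stop("synth_beat: non-positive duration")
  sf <- spec$systolic_fraction
  x <- with_seed(spec$seed, {
    switch(spec$sound_class,
      normal = {
        band_noise(n, sample_rate_hz, 2, 750) *
          beat_envelope(n, sf, 0.35)
      },
      hard = {
        band_noise(n, sample_rate_hz, 2, 1500) *
          beat_envelope(n, sf, 0.08)
      },
      high = {
        env <- beat_envelope(n, sf, 0.30)
        sys <- seq_len(n) <= round(sf * n)
        y <- numeric(n)
        y[sys] <- band_noise(sum(sys), sample_rate_hz, 250, 750)
        y[!sys] <- 0.6 * band_noise(sum(!sys), sample_rate_hz, 2, 300)
        y * env
      },
      intermittent = {
        env <- beat_envelope(n, sf, 0.35)
        t <- seq_len(n) / n
        # smooth gate closing right after systole; silent from 1.25*sf on
        gate <- ifelse(t <= sf, 1,
                ifelse(t >= 1.25 * sf, 0,
                       0.5 + 0.5 * cos(pi * (t - sf) / (0.25 * sf))))
        band_noise(n, sample_rate_hz, 2, 750) * env * gate
      },
      whistle = {
        base <- band_noise(n, sample_rate_hz, 2, 750)
        t <- seq_len(n) / sample_rate_hz
        wobble <- 0.01 * spec$whistle_hz *
          sin(2 * pi * 3 * t + runif(1, 0, 2 * pi))
        phase <- 2 * pi * cumsum(spec$whistle_hz + wobble) / sample_rate_hz
        (base + 1.5 * sin(phase)) * beat_envelope(n, sf, 0.35)
      }
    )
  })
  peak <- max(abs(x))
  if (peak > 0) x <- 0.9 * x / peak
  audio_recording(x, sample_rate_hz)
}

#' Synthesise an environmental sound clip
#'
#' Stand-ins for the ward sounds superimposed on bedside auscultation:
#' `hum` is 50 Hz mains with decaying harmonics, `babble` is speech-band
#' (100–4000 Hz) noise with slow syllabic amplitude modulation, `clatter`
#' is sparse broadband transients (dropped instruments, knocks), `silence`
#' is all zeros.
#'
#' @param kind One of `"hum"`, `"babble"`, `"clatter"`, `"silence"`.
#' @param duration_s Clip length in seconds.
#' @param seed Integer RNG seed.
#' @param sample_rate_hz Sample rate.
#' @return An [audio_recording()], peak-normalised to 0.9 (except silence).
#' @export
synth_environment <- function(kind, duration_s, seed = 1L,
                              sample_rate_hz = 192000L) {
  kind <- match.arg(kind, c("hum", "babble", "clatter", "silence"))
  if (duration_s <= 0) stop("synth_environment: duration_s must be positive")
  n <- round(duration_s * sample_rate_hz)
  x <- with_seed(seed, {
    switch(kind,
      silence = numeric(n),
      hum = {
        t <- seq_len(n) / sample_rate_hz
        h <- c(1, 0.5, 0.25, 0.12)
        rowSums(sapply(seq_along(h), function(k) {
          h[k] * sin(2 * pi * 50 * k * t + runif(1, 0, 2 * pi))
        }))
      },
      babble = {
        mod_hz <- 4
        t <- seq_len(n) / sample_rate_hz
        mod <- 0.55 + 0.45 * sin(2 * pi * mod_hz * t + runif(1, 0, 2 * pi)) *
          sin(2 * pi * 0.7 * mod_hz * t + runif(1, 0, 2 * pi))
        band_noise(n, sample_rate_hz, 100, 4000) * mod
      },
      clatter = {
        y <- numeric(n)
        n_events <- max(1L, stats::rpois(1, duration_s * 2))
        starts <- sort(sample.int(max(1L, n - 1L), n_events, replace = TRUE))
        for (s in starts) {
          len <- min(n - s + 1L, round(0.03 * sample_rate_hz))
          y[s:(s + len - 1L)] <- y[s:(s + len - 1L)] +
            rnorm(len) * exp(-seq_len(len) / (0.004 * sample_rate_hz))
        }
        y
      }
    )
  })
  peak <- max(abs(x), 0)
  if (peak > 0) x <- 0.9 * x / peak
  audio_recording(x, sample_rate_hz)
}

#' Assemble a full synthetic auscultation recording
#'
#' Beats are concatenated in order with `gap_s` of silence between them;
#' environmental clips are mixed on top at the signal-to-noise ratio carried
#' by the beat specs (mean `snr_db`, measured as beat RMS over environment
#' RMS within the beat span).
#'
#' @param beat_specs List of [beat_spec()]s.
#' @param gap_s Inter-beat gap in seconds (default 0.05).
#' @param environment Either a character vector of environment kinds, each
#'   spanning the whole recording, or a data frame with columns
#'   `kind`, `start_s`, `end_s` describing bursts.
#' @param seed Integer seed for environment generation.
#' @param sample_rate_hz Sample rate.
#' @param lead_s Leading/trailing silence in seconds (default 0.25).
#' @return A list with `recording` (an [audio_recording()]),
#'   `ground_truth` (`beats`: tibble of start_s, end_s, sound_class;
#'   `environment_intervals`: tibble of start_s, end_s, kind) and `gain`,
#'   the headroom factor applied after mixing (1 unless the mix exceeded
#'   full scale).
#' @export
synth_recording <- function(beat_specs, gap_s = 0.05, environment = NULL,
                            seed = 1L, sample_rate_hz = 192000L,
                            lead_s = 0.25) {
  stopifnot(is.list(beat_specs))
  durations <- vapply(beat_specs, function(s) s$beat_duration_s, numeric(1))
  total_s <- 2 * lead_s + sum(durations) +
    gap_s * max(0L, length(beat_specs) - 1L)
  if (total_s > 300) stop("synth_recording: total duration exceeds 300 s")
  n_total <- round(total_s * sample_rate_hz)
  x <- numeric(n_total)
  beats <- list()
  cursor <- lead_s
  for (i in seq_along(beat_specs)) {
    b <- synth_beat(beat_specs[[i]], sample_rate_hz)
    i0 <- round(cursor * sample_rate_hz)
    idx <- i0 + seq_along(b$samples)
    x[idx] <- x[idx] + b$samples
    beats[[i]] <- tibble::tibble(
      start_s = cursor,
      end_s = cursor + b$duration_s,
      sound_class = beat_specs[[i]]$sound_class
    )
    cursor <- cursor + b$duration_s + gap_s
  }
  beats <- if (length(beats)) do.call(rbind, beats) else {
    tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                   sound_class = character(0))
  }

  env_tbl <- tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                            kind = character(0))
  if (!is.null(environment) && length(environment)) {
    if (is.character(environment)) {
      environment <- data.frame(kind = environment, start_s = 0,
                                end_s = total_s)
    }
    beat_rms <- if (nrow(beats)) {
      idx <- unlist(lapply(seq_len(nrow(beats)), function(i) {
        (round(beats$start_s[i] * sample_rate_hz) + 1L):
          round(beats$end_s[i] * sample_rate_hz)
      }))
      .rms(x[idx])
    } else 0
    snr_db <- if (length(beat_specs)) {
      mean(vapply(beat_specs, function(s) s$snr_db, numeric(1)))
    } else 0
    for (i in seq_len(nrow(environment))) {
      k <- environment$kind[i]
      s0 <- max(0, environment$start_s[i])
      s1 <- min(total_s, environment$end_s[i])
      if (s1 <= s0) next
      clip <- synth_environment(k, s1 - s0, seed = seed + i,
                                sample_rate_hz = sample_rate_hz)
      e <- clip$samples
      if (beat_rms > 0 && .rms(e) > 0) {
        e <- e * (beat_rms / 10^(snr_db / 20)) / .rms(e)
        # recorder headroom: transients saturate at full scale, as on a
        # real ADC; without this an impulsive clip scaled to a continuous
        # bruit's RMS would peak far beyond any physical recording
        e <- pmin(pmax(e, -1), 1)
      }
      i0 <- round(s0 * sample_rate_hz)
      idx <- i0 + seq_along(e)
      idx <- idx[idx <= n_total]
      x[idx] <- x[idx] + e[seq_along(idx)]
      env_tbl <- rbind(env_tbl,
                       tibble::tibble(start_s = s0, end_s = s1, kind = k))
    }
  }
  peak <- max(abs(x), 0)
  gain <- if (peak > 1) 1 / peak else 1 # headroom if mixing exceeded full scale
  x <- x * gain
  list(
    recording = audio_recording(x, sample_rate_hz),
    ground_truth = list(beats = beats, environment_intervals = env_tbl),
    gain = gain
  )
}

#' Generate a labelled beat corpus with patient-grouped splits
#'
#' Emulates the composition of a human-labelled AVF sound archive: class
#' counts default to the archive's training-set proportions
#' (normal 394 : hard 578 : high 670 : intermittent 91 : whistle 91),
#' beats are attributed to simulated patients, and the train/test split is
#' patient-grouped so no patient contributes to both sides.
#'
#' Audio is not materialised here (a corpus row is a [beat_spec()] plus
#' metadata); use [synth_beat()] or [corpus_features()] to realise
#' waveforms or features on demand.
#'
#' @param n_per_class Named integer vector (names from [bruit_classes()]).
#'   Missing classes default to 0; `NULL` means the archive proportions
#'   scaled to `n_total`.
#' @param n_total Total corpus size when `n_per_class` is `NULL`.
#' @param n_patients Number of simulated patients (default 10).
#' @param test_fraction Fraction of patients assigned to the test split.
#' @param duration_range_s Beat duration range, sampled uniformly.
#' @param seed Integer seed.
#' @return A list with `manifest` (tibble: beat_id, sound_class, patient_id,
#'   split, beat_duration_s, seed) and `specs` (list of [beat_spec()]).
#' @export
synth_corpus <- function(n_per_class = NULL, n_total = 200L, n_patients = 10L,
                         test_fraction = 0.3,
                         duration_range_s = c(0.6, 1.5), seed = 1L) {
  classes <- bruit_classes()
  if (is.null(n_per_class)) {
    ref <- c(normal = 394, hard = 578, high = 670,
             intermittent = 91, whistle = 91)
    n_per_class <- round(ref / sum(ref) * n_total)
  }
  counts <- integer(length(classes))
  names(counts) <- classes
  counts[names(n_per_class)] <- as.integer(n_per_class)
  if (any(counts < 0)) stop("synth_corpus: negative class count")
  if (sum(counts) == 0L) stop("synth_corpus: all class counts are zero")

  with_seed(seed, {
    labels <- rep(classes, counts)
    n <- length(labels)
    patient_id <- sprintf("P%02d", sample.int(n_patients, n, replace = TRUE))
    test_patients <- sprintf(
      "P%02d",
      sample.int(n_patients, max(1L, round(test_fraction * n_patients)))
    )
    split <- ifelse(patient_id %in% test_patients, "test", "train")
    dur <- runif(n, duration_range_s[1], duration_range_s[2])
    beat_seed <- sample.int(.Machine$integer.max %/% 2L, n)
    whistle_hz <- runif(n, 800, 1500)
    specs <- lapply(seq_len(n), function(i) {
      beat_spec(labels[i], beat_duration_s = dur[i],
                snr_db = 10, whistle_hz = whistle_hz[i],
                seed = beat_seed[i])
    })
    manifest <- tibble::tibble(
      beat_id = sprintf("B%05d", seq_len(n)),
      sound_class = labels,
      patient_id = patient_id,
      split = split,
      beat_duration_s = dur,
      seed = beat_seed
    )
    list(manifest = manifest, specs = specs)
  })
}

#' Superimpose environmental sound on a recording
#'
#' Mixes an environment clip into a recording at a stated signal-to-noise
#' ratio, clamping the noise at full scale (recorder headroom) and
#' renormalising the sum. Gate classifiers are trained on such mixtures:
#' a candidate sliced from a bedside recording always carries background
#' sound, so clean-beat training would face a domain shift at the gate.
#'
#' @param recording An [audio_recording()].
#' @param kind Environment kind, see [synth_environment()].
#' @param snr_db Recording-to-environment RMS ratio in dB.
#' @param seed Integer seed for the environment clip.
#' @return An [audio_recording()] of the same length.
#' @export
mix_with_environment <- function(recording, kind, snr_db, seed = 1L) {
  stopifnot(inherits(recording, "audio_recording"))
  env <- synth_environment(kind, recording$duration_s + 0.05, seed = seed,
                           sample_rate_hz = recording$sample_rate_hz)
  e <- env$samples[seq_along(recording$samples)]
  if (.rms(e) > 0) {
    e <- e * (.rms(recording$samples) / 10^(snr_db / 20)) / .rms(e)
    e <- pmin(pmax(e, -1), 1)
  }
  x <- recording$samples + e
  peak <- max(abs(x), 1)
  audio_recording(x / peak, recording$sample_rate_hz)
}

#' Generate a training set for the AVF-vs-environment gate
#'
#' Positives are beat intervals sliced out of full synthetic recordings
#' (beats of all five classes over environmental sound at 5-15 dB SNR), so
#' they look exactly like the candidates the gate will score; negatives
#' are environment-only clips. The study's gate was likewise trained on
#' beats extracted from real recordings against an environmental corpus.
#'
#' @param n_recordings Number of synthetic recordings to slice.
#' @param beats_per_recording Beats per recording.
#' @param n_environment Number of negative clips.
#' @param seed Integer seed.
#' @param sample_rate_hz Sample rate.
#' @return A list with `beats` and `environment`, each a list of
#'   [audio_recording()]s.
#' @export
synth_gate_training_set <- function(n_recordings = 10L,
                                    beats_per_recording = 8L,
                                    n_environment = 80L, seed = 1L,
                                    sample_rate_hz = 192000L) {
  kinds <- c("hum", "babble", "clatter")
  with_seed(seed, {
    beats <- list()
    for (r in seq_len(n_recordings)) {
      specs <- lapply(seq_len(beats_per_recording), function(i) {
        beat_spec(sample(bruit_classes(), 1),
                  beat_duration_s = runif(1, 0.6, 1.5),
                  snr_db = runif(1, 5, 15),
                  whistle_hz = runif(1, 800, 1500),
                  seed = sample.int(1e8, 1))
      })
      env <- sample(kinds, 1)
      sr <- synth_recording(specs, gap_s = runif(1, 0.05, 0.3),
                            environment = env,
                            seed = sample.int(1e8, 1),
                            sample_rate_hz = sample_rate_hz)
      gt <- sr$ground_truth$beats
      for (i in seq_len(nrow(gt))) {
        beats[[length(beats) + 1L]] <-
          slice_audio(sr$recording, gt$start_s[i], gt$end_s[i])
      }
    }
    environment <- lapply(seq_len(n_environment), function(i) {
      synth_environment(sample(kinds, 1),
                        duration_s = runif(1, 0.6, 1.5),
                        seed = sample.int(1e8, 1), sample_rate_hz)
    })
    list(beats = beats, environment = environment)
  })
}
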