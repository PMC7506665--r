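test_that("band energy envelope separates in-band from out-of-band tones", {
  fs <- 48000L
  t <- seq_len(fs) / fs
  in_band <- audio_recording(0.5 * sin(2 * pi * 300 * t), fs)
  out_band <- audio_recording(0.5 * sin(2 * pi * 1500 * t), fs)
  e_in <- band_energy_envelope(in_band)
  e_out <- band_energy_envelope(out_band)
  expect_lt(mean(e_out$values), 0.01 * mean(e_in$values))
})

test_that("envelope is zero on silence and linear in amplitude", {
  fs <- 48000L
  sil <- band_energy_envelope(audio_recording(numeric(fs), fs))
  expect_true(all(sil$values == 0))

  with_seed(2, x <- runif(fs, -0.4, 0.4))
  e1 <- band_energy_envelope(audio_recording(x, fs))
  e2 <- band_energy_envelope(audio_recording(2 * x, fs))
  expect_equal(e2$values, 2 * e1$values, tolerance = 1e-9)
})

test_that("envelope ignores energy strictly above the band", {
  fs <- 48000L
  t <- seq_len(fs) / fs
  base <- 0.4 * sin(2 * pi * 200 * t)
  plus5k <- 0.5 * (base + 0.4 * sin(2 * pi * 5000 * t))
  e_base <- band_energy_envelope(audio_recording(base, fs))
  e_plus <- band_energy_envelope(audio_recording(plus5k, fs))
  # compare after undoing the amplitude halving applied above
  expect_lt(max(abs(2 * e_plus$values - e_base$values)) /
              max(e_base$values), 0.01)
})

test_that("envelope rejects degenerate inputs", {
  fs <- 48000L
  expect_error(band_energy_envelope(audio_recording(numeric(0), fs)),
               "empty")
  expect_error(
    band_energy_envelope(audio_recording(numeric(fs), fs),
                         band_hz = c(750, 2)),
    "inverted"
  )
})

test_that("spline smoothing reproduces constants and reduces noise extrema", {
  const <- envelope_from_values(rep(3.5, 200))
  sm <- spline_smooth(const)
  expect_equal(sm$values, rep(3.5, 200), tolerance = 1e-6)

  with_seed(13, {
    n <- 300
    t <- seq(0, 3, length.out = n)
    clean <- 0.5 - 0.5 * cos(2 * pi * t / 3)
    noisy <- clean + rnorm(n, sd = 0.1)
  })
  env <- envelope_from_values(pmax(noisy, 0), hop_s = 0.01)
  sm <- spline_smooth(env)
  n_max <- function(v) length(avfbruit:::local_extrema(v)$maxima)
  expect_lt(n_max(sm$values), n_max(env$values))
})

test_that("smoothing 0 is the interpolating limit", {
  with_seed(3, v <- runif(50))
  env <- envelope_from_values(v)
  expect_equal(spline_smooth(env, smoothing = 0)$values, pmax(v, 0))
  expect_error(spline_smooth(envelope_from_values(c(1, 2, 3))), "4 frames")
})

test_that("a train of 1 s bumps is detected with accurate onsets", {
  bt <- bump_train(rep(1.0, 5))
  cand <- detect_convex_ranges(bt$envelope)
  expect_equal(nrow(cand), 5L)
  expect_true(all(abs(cand$start_s - bt$starts_s) < 0.1))
})

test_that("bumps outside 0.5-2 s are rejected by the duration filter", {
  short <- bump_train(0.3)
  expect_equal(nrow(detect_convex_ranges(short$envelope)), 0L)
  long <- bump_train(2.5)
  expect_equal(nrow(detect_convex_ranges(long$envelope)), 0L)
  mixed <- bump_train(c(0.3, 1.0, 2.5, 1.0))
  cand <- detect_convex_ranges(mixed$envelope)
  expect_equal(nrow(cand), 2L)
})

test_that("detected candidates never overlap and respect duration bounds", {
  with_seed(31, {
    for (rep in 1:5) {
      widths <- runif(6, 0.3, 2.6)
      bt <- bump_train(widths, gap_s = runif(1, 0.3, 0.6))
      env <- bt$envelope
      env$values <- env$values + abs(rnorm(length(env$values), sd = 0.01))
      cand <- detect_convex_ranges(spline_smooth(env))
      if (nrow(cand) > 1) {
        expect_true(all(cand$start_s[-1] >= cand$end_s[-nrow(cand)]))
      }
      expect_true(all(cand$duration_s >= 0.5 & cand$duration_s <= 2.0))
    }
  })
})

test_that("the gate separates bruit from environment on held-out clips", {
  gate <- demo_gate()
  with_seed(17, {
    pb <- sapply(1:12, function(i) {
      gate_probability(gate, synth_beat(
        beat_spec(sample(bruit_classes(), 1),
                  beat_duration_s = runif(1, 0.6, 1.4), seed = 7000 + i)
      ))
    })
    pe <- sapply(1:12, function(i) {
      gate_probability(gate, synth_environment(
        sample(c("hum", "babble", "clatter"), 1),
        duration_s = runif(1, 0.6, 1.4), seed = 8000 + i
      ))
    })
  })
  expect_gte(roc_auc(c(pb, pe), rep(c(TRUE, FALSE), each = 12))$auc, 0.95)
})

test_that("train_gate requires both classes", {
  beat <- synth_beat(beat_spec("normal", seed = 1))
  expect_error(train_gate(list(beat), list()), "non-empty")
  expect_error(train_gate(list(), list(beat)), "non-empty")
})

test_that("acceptance is strict: probability must exceed 0.5", {
  # a 2-class model with zeroed head emits exactly 0.5 for both classes
  spec <- architecture_spec("vgg13", n_mels = 16L, base_channels = 2L,
                            n_classes = 2L, input_frames = 32L)
  spec$conv_plan <- c(2L, 2L)
  m <- build_model(spec, seed = 1, classes = c("avf", "environment"))
  m$params$head_W[] <- 0
  m$params$head_b[] <- 0
  m$trained <- TRUE
  gate <- structure(list(model = m, n_mels = 16L), class = "avf_gate")

  rec <- synth_beat(beat_spec("normal", beat_duration_s = 0.6, seed = 2),
                    sample_rate_hz = 48000L)
  cand <- tibble::tibble(start_s = 0.0, end_s = 0.55, duration_s = 0.55,
                         peak_value = 1)
  gated <- suppressWarnings(gate_candidates(cand, rec, gate))
  expect_equal(gated$avf_probability, 0.5)
  expect_false(gated$accepted)

  m$params$head_b[1, 1] <- 0.1 # tip the score just above 0.5
  gate$model <- m
  gated <- suppressWarnings(gate_candidates(cand, rec, gate))
  expect_gt(gated$avf_probability, 0.5)
  expect_true(gated$accepted)
})

test_that("gate_candidates refuses an untrained gate and empty input works", {
  spec <- architecture_spec("vgg13", n_mels = 16L, base_channels = 2L,
                            n_classes = 2L, input_frames = 32L)
  spec$conv_plan <- c(2L, 2L)
  m <- build_model(spec, seed = 1, classes = c("avf", "environment"))
  gate <- structure(list(model = m, n_mels = 16L), class = "avf_gate")
  cand <- tibble::tibble(start_s = 0, end_s = 1, duration_s = 1,
                         peak_value = 1)
  rec <- audio_recording(numeric(48000), 48000L)
  expect_error(gate_candidates(cand, rec, gate), "untrained")

  trained <- demo_gate()
  empty <- detect_convex_ranges(envelope_from_values(rep(0.01, 100)))
  out <- gate_candidates(empty, rec, trained)
  expect_equal(nrow(out), 0L)
  expect_true(all(c("avf_probability", "accepted") %in% names(out)))
})
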