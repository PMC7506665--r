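test_that("intermittent beats are silent in late diastole", {
  rec <- synth_beat(beat_spec("intermittent", beat_duration_s = 1.0,
                              seed = 5))
  n <- length(rec$samples)
  sys <- rec$samples[1:round(0.35 * n)]
  tail40 <- rec$samples[round(0.6 * n):n]
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(tail40), 0.05 * rms(sys))
})

test_that("whistle beats carry a narrowband tone near whistle_hz", {
  rec <- synth_beat(beat_spec("whistle", beat_duration_s = 1.0,
                              whistle_hz = 1000, seed = 6))
  x <- rec$samples
  p <- Mod(fft(x))[1:(length(x) %/% 2)]^2
  f <- (seq_along(p) - 1) / length(x) * rec$sample_rate_hz
  peak_band <- p[f >= 950 & f <= 1050]
  # noise floor: the band just outside the tone's neighbourhood
  floor_band <- p[(f >= 700 & f <= 900) | (f >= 1100 & f <= 1300)]
  expect_gt(10 * log10(max(peak_band) / mean(floor_band)), 10)
})

test_that("hard beats have an exaggerated systolic peak and a wider band", {
  rms <- function(x) sqrt(mean(x^2))
  ratio <- function(class) {
    rec <- synth_beat(beat_spec(class, beat_duration_s = 1.0, seed = 7))
    n <- length(rec$samples)
    rms(rec$samples[1:round(0.35 * n)]) /
      rms(rec$samples[round(0.7 * n):n])
  }
  expect_gt(ratio("hard"), 3 * ratio("normal"))
})

test_that("beat synthesis is a pure function of (spec, seed)", {
  s <- beat_spec("high", beat_duration_s = 0.8, seed = 42)
  a <- synth_beat(s)
  b <- synth_beat(s)
  expect_identical(a$samples, b$samples)
  c <- synth_beat(beat_spec("high", beat_duration_s = 0.8, seed = 43))
  expect_false(identical(a$samples, c$samples))
})

test_that("generated beats keep >=90% of their energy below 2000 Hz", {
  for (cl in bruit_classes()) {
    rec <- synth_beat(beat_spec(cl, beat_duration_s = 0.6, seed = 11))
    x <- rec$samples
    p <- Mod(fft(x))[1:(length(x) %/% 2)]^2
    f <- (seq_along(p) - 1) / length(x) * rec$sample_rate_hz
    expect_gt(sum(p[f < 2000]) / sum(p), 0.9)
  }
})

test_that("beat_spec validates its fields", {
  expect_error(beat_spec("buzzing"), "arg")
  expect_error(beat_spec("normal", beat_duration_s = 0.1), "0.3, 3")
  expect_error(beat_spec("normal", systolic_fraction = 1.2), "0, 1")
})

test_that("environment kinds have their stated structure", {
  sil <- synth_environment("silence", 0.5, seed = 1, 48000L)
  expect_true(all(sil$samples == 0))

  hum <- synth_environment("hum", 1.0, seed = 1, 48000L)
  p <- Mod(fft(hum$samples))[1:(length(hum$samples) %/% 2)]^2
  f <- (seq_along(p) - 1) / length(hum$samples) * 48000
  expect_lt(abs(f[which.max(p)] - 50), 2)

  a <- synth_environment("babble", 0.5, seed = 3, 48000L)
  b <- synth_environment("babble", 0.5, seed = 3, 48000L)
  expect_identical(a$samples, b$samples)
  expect_error(synth_environment("traffic", 1, 1), "arg")
  expect_error(synth_environment("hum", 0, 1), "positive")
})

test_that("synth_recording lays out beats and records ground truth", {
  specs <- lapply(1:10, function(i) {
    beat_spec("normal", beat_duration_s = 1.0, seed = i)
  })
  out <- synth_recording(specs, gap_s = 0.1, seed = 2,
                         sample_rate_hz = 48000L)
  gt <- out$ground_truth$beats
  expect_equal(nrow(gt), 10L)
  expect_true(all(diff(gt$start_s) > 0))
  expect_true(all(gt$end_s[-10] <= gt$start_s[-1] + 1e-9))
  expect_equal(out$recording$duration_s,
               2 * 0.25 + 10 * 1.0 + 9 * 0.1, tolerance = 1e-6)

  empty <- synth_recording(list(), environment = "hum", seed = 2,
                           sample_rate_hz = 48000L)
  expect_equal(nrow(empty$ground_truth$beats), 0L)
  expect_gt(max(abs(empty$recording$samples)), 0)
})

test_that("environment mixing at 0 dB SNR matches beat RMS within 1 dB", {
  specs <- lapply(1:8, function(i) {
    beat_spec("normal", beat_duration_s = 1.0, snr_db = 0, seed = 100 + i)
  })
  clean <- synth_recording(specs, gap_s = 0.1, seed = 3,
                           sample_rate_hz = 48000L)
  noisy <- synth_recording(specs, gap_s = 0.1, environment = "babble",
                           seed = 3, sample_rate_hz = 48000L)
  # undo the headroom gain, then isolate the babble-only component
  env_part <- noisy$recording$samples / noisy$gain -
    clean$recording$samples / clean$gain
  gt <- clean$ground_truth$beats
  idx <- unlist(lapply(seq_len(nrow(gt)), function(i) {
    (round(gt$start_s[i] * 48000) + 1):round(gt$end_s[i] * 48000)
  }))
  rms <- function(x) sqrt(mean(x^2))
  ratio_db <- 20 * log10(rms(clean$recording$samples[idx] / clean$gain) /
                           rms(env_part[idx]))
  expect_lt(abs(ratio_db), 1)
})

test_that("synth_recording rejects durations over 300 s", {
  specs <- lapply(1:150, function(i) beat_spec("normal", 2.5, seed = i))
  expect_error(synth_recording(specs, gap_s = 0.1), "300")
})

test_that("synth_corpus defaults follow the archive class proportions", {
  corpus <- synth_corpus(n_total = 1824L, n_patients = 12L, seed = 1)
  counts <- table(corpus$manifest$sound_class)[bruit_classes()]
  expect_equal(unname(as.integer(counts)), c(394L, 578L, 670L, 91L, 91L))
})

test_that("synth_corpus respects explicit counts and patient-grouped splits", {
  corpus <- synth_corpus(n_per_class = c(normal = 10), seed = 2)
  expect_equal(nrow(corpus$manifest), 10L)
  expect_true(all(corpus$manifest$sound_class == "normal"))

  big <- synth_corpus(n_per_class = c(normal = 30, hard = 30), seed = 3,
                      n_patients = 10L)
  tr_p <- unique(big$manifest$patient_id[big$manifest$split == "train"])
  te_p <- unique(big$manifest$patient_id[big$manifest$split == "test"])
  expect_length(intersect(tr_p, te_p), 0L)

  expect_error(synth_corpus(n_per_class = c(normal = 0)), "zero")
})

test_that("corpus generation is deterministic under seed", {
  a <- synth_corpus(n_per_class = c(hard = 5, whistle = 5), seed = 9)
  b <- synth_corpus(n_per_class = c(hard = 5, whistle = 5), seed = 9)
  expect_identical(a$manifest, b$manifest)
})
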