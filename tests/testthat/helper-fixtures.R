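# Shared fixtures. Heavy objects (trained models, featurized corpora) are
# built once per test session and memoised here.

fixture_env <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

# a labelled 10-beats-per-class corpus with 64-mel features
demo_features <- function() {
  cached("demo_features", function() {
    corpus <- synth_corpus(
      n_per_class = c(normal = 10, hard = 10, high = 10,
                      intermittent = 10, whistle = 10),
      seed = 21
    )
    corpus_features(corpus, n_mels = 64L)
  })
}

# a small trained five-class CNN (shared by prediction, metric and
# Grad-CAM tests)
demo_vgg13 <- function() {
  cached("demo_vgg13", function() {
    cf <- demo_features()
    spec <- architecture_spec("vgg13", n_mels = 64L, base_channels = 4L)
    m <- build_model(spec, seed = 3)
    tr <- cf$split == "train"
    train_model(m, cf$features[tr], cf$labels[tr], cf$patient_id[tr],
                training_config(epochs = 8L, seed = 3))
  })
}

# a trained AVF-vs-environment gate; positives are beat intervals sliced
# from full synthetic recordings, matching what gated candidates look like
demo_gate <- function() {
  cached("demo_gate", function() {
    gate_set <- synth_gate_training_set(n_recordings = 25L,
                                        n_environment = 200L, seed = 11)
    train_gate(gate_set$beats, gate_set$environment, base_channels = 4L,
               config = training_config(epochs = 16L, seed = 3))
  })
}

# the seeded 1-minute 60-bpm recording with clatter bursts used by the
# segmentation chain tests
demo_recording <- function() {
  cached("demo_recording", function() {
    specs <- lapply(1:55, function(i) {
      beat_spec("normal", beat_duration_s = 0.85, snr_db = 10,
                seed = 1000 + i)
    })
    bursts <- data.frame(kind = "clatter", start_s = c(10, 25, 40),
                         end_s = c(11, 26, 41))
    synth_recording(specs, gap_s = 0.15, environment = bursts, seed = 9)
  })
}

# construct an envelope object directly (for detector unit tests)
envelope_from_values <- function(values, hop_s = 0.01) {
  structure(
    list(times_s = (seq_along(values) - 1L) * hop_s, values = values,
         band_hz = c(2, 750), frame_len_s = 0.05, hop_s = hop_s),
    class = "envelope"
  )
}

# a train of raised-cosine bumps on a quiet floor; returns the envelope and
# the true bump start times
bump_train <- function(widths_s, gap_s = 0.4, floor_level = 0.02,
                       hop_s = 0.01) {
  values <- rep(floor_level, round(gap_s / hop_s))
  starts <- numeric(0)
  for (w in widths_s) {
    starts <- c(starts, length(values) * hop_s)
    n <- round(w / hop_s)
    t <- seq(0, 1, length.out = n)
    values <- c(values, floor_level + (1 - floor_level) *
                  (0.5 - 0.5 * cos(2 * pi * t)))
    values <- c(values, rep(floor_level, round(gap_s / hop_s)))
  }
  list(envelope = envelope_from_values(values, hop_s), starts_s = starts)
}

# tiny architectures for engine-level tests
tiny_spec <- function(kind, n_classes = 3L) {
  spec <- architecture_spec(kind, n_mels = 8L, base_channels = 2L,
                            rnn_width = 3L, n_classes = n_classes,
                            input_frames = 16L)
  spec$conv_plan <- c(2L, 3L)
  spec
}

tiny_inputs <- function(n, seed = 1) {
  with_seed(seed, lapply(seq_len(n), function(i) {
    matrix(rnorm(16 * 8), ncol = 1)
  }))
}

# exhaustive pairwise-concordance oracle for the AUC
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  pairs <- expand.grid(p = pos, n = neg)
  mean(ifelse(pairs$p > pairs$n, 1, ifelse(pairs$p == pairs$n, 0.5, 0)))
}

make_onehot_scores <- function(labels, classes, good_class, seed) {
  # informative for good_class only; uniform noise elsewhere
  with_seed(seed, {
    n <- length(labels)
    m <- matrix(runif(n * length(classes)), n,
                dimnames = list(NULL, classes))
    m[, good_class] <- 0.25 * runif(n) + 0.7 * (labels == good_class)
    m / rowSums(m)
  })
}

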