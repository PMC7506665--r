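#' Classifier architecture specification
#'
#' The published stack: pairs of 3x3 convolutions (each followed by batch
#' normalisation and ReLU) at widths `base_channels * c(1, 2, 4, 8, 8)`,
#' a 2x2 max pool after every pair, then either global average pooling
#' (`vgg13`) or a bidirectional recurrent layer over the pooled time axis
#' (`crnn_bigru` / `crnn_bilstm`) whose ReLU'd outputs are time-averaged,
#' and a 5-way softmax head.
#'
#' With a 400-frame input the five pools give 400 -> 200 -> 100 -> 50 ->
#' 25 -> 12 time steps at the recurrent (or final-feature) input: the
#' printed block table lists four pools, but the stated 400 -> 12
#' time-axis contract requires a fifth, which is therefore appended after
#' the final convolution pair.
#'
#' @param kind `"vgg13"`, `"crnn_bigru"` or `"crnn_bilstm"`.
#' @param n_mels Number of mel filters the model consumes.
#' @param base_channels Width of the first convolution pair; the published
#'   width is 64. Desk-scale training in the package's own tests uses 4-8.
#' @param rnn_width Hidden width per direction of the recurrent layer;
#'   published width 512 (`8 * base_channels` by default).
#' @param n_classes Output classes, default the 5 bruit classes.
#' @param input_frames Fixed time axis length, default 400.
#' @return An `architecture_spec`.
#' @export
architecture_spec <- function(kind = c("vgg13", "crnn_bigru", "crnn_bilstm"),
                              n_mels = 64L, base_channels = 64L,
                              rnn_width = 8L * base_channels,
                              n_classes = 5L, input_frames = 400L) {
  kind <- match.arg(kind)
  structure(
    list(
      kind = kind,
      n_mels = as.integer(n_mels),
      conv_plan = as.integer(base_channels * c(1L, 2L, 4L, 8L, 8L)),
      rnn_width = as.integer(rnn_width),
      n_classes = as.integer(n_classes),
      input_frames = as.integer(input_frames)
    ),
    class = "architecture_spec"
  )
}

nn_cfg <- function(spec) {
  list(
    channels = spec$conv_plan,
    kind = switch(spec$kind, vgg13 = "cnn", crnn_bigru = "gru",
                  crnn_bilstm = "lstm"),
    rnn_width = spec$rnn_width,
    n_classes = spec$n_classes,
    input_frames = spec$input_frames,
    n_mels = spec$n_mels
  )
}

#' Time-axis length at the recurrent / final-feature input
#'
#' Applies the 2x2 pooling plan (floor division per stage) to
#' `input_frames`; with the default 400-frame input and five stages this
#' is exactly 12.
#'
#' @param spec An [architecture_spec()].
#' @return Integer frame count.
#' @export
time_frames_after_conv <- function(spec) {
  h <- spec$input_frames
  for (s in seq_along(spec$conv_plan)) h <- h %/% 2L
  h
}

# He-style initialisation; all parameters are matrices (vectors as 1 x n)
nn_init_params <- function(cfg, seed) {
  with_seed(seed, {
    p <- list()
    st <- list()
    cin <- 1L
    for (s in seq_along(cfg$channels)) {
      cout <- cfg$channels[s]
      for (l in 1:2) {
        base <- sprintf("conv%d_%d", s, l)
        fan_in <- 9L * cin
        p[[paste0(base, "_W")]] <-
          matrix(rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout)
        p[[paste0(base, "_b")]] <- matrix(0, 1, cout)
        p[[paste0(base, "_g")]] <- matrix(1, 1, cout)
        p[[paste0(base, "_be")]] <- matrix(0, 1, cout)
        st[[paste0(base, "_rm")]] <- matrix(0, 1, cout)
        st[[paste0(base, "_rv")]] <- matrix(1, 1, cout)
        cin <- cout
      }
    }
    c_last <- cfg$channels[length(cfg$channels)]
    if (cfg$kind == "cnn") {
      feat_dim <- c_last
    } else {
      w_final <- cfg$n_mels
      for (s in seq_along(cfg$channels)) w_final <- w_final %/% 2L
      d <- w_final * c_last
      gates <- if (cfg$kind == "gru") 3L else 4L
      r <- cfg$rnn_width
      for (dir in c("rnn_f", "rnn_b")) {
        p[[paste0(dir, "_Wx")]] <-
          matrix(rnorm(d * gates * r, sd = sqrt(1 / d)), d, gates * r)
        p[[paste0(dir, "_Wh")]] <-
          matrix(rnorm(r * gates * r, sd = sqrt(1 / r)), r, gates * r)
        b0 <- matrix(0, 1, gates * r)
        if (cfg$kind == "lstm") b0[1, (r + 1):(2 * r)] <- 1 # forget-gate bias
        p[[paste0(dir, "_b")]] <- b0
      }
      feat_dim <- 2L * r
    }
    p[["head_W"]] <- matrix(rnorm(feat_dim * cfg$n_classes,
                                  sd = sqrt(1 / feat_dim)),
                            feat_dim, cfg$n_classes)
    p[["head_b"]] <- matrix(0, 1, cfg$n_classes)
    list(params = p, state = st)
  })
}

#' Build an untrained classifier
#'
#' @param spec An [architecture_spec()].
#' @param seed Seed for weight initialisation.
#' @param classes Class labels in output order.
#' @return A `bruit_model`.
#' @export
build_model <- function(spec, seed = 1L, classes = bruit_classes()) {
  stopifnot(inherits(spec, "architecture_spec"))
  if (length(classes) != spec$n_classes) {
    stop("build_model: length(classes) must equal spec$n_classes")
  }
  cfg <- nn_cfg(spec)
  init <- nn_init_params(cfg, seed)
  structure(
    list(spec = spec, cfg = cfg, params = init$params, state = init$state,
         classes = classes, trained = FALSE),
    class = "bruit_model"
  )
}

#' @export
print.bruit_model <- function(x, ...) {
  cat(sprintf("<bruit_model %s: %d mels, conv plan %s, %d classes%s>\n",
              x$spec$kind, x$spec$n_mels,
              paste(x$spec$conv_plan, collapse = "-"),
              x$spec$n_classes,
              if (x$trained) ", trained" else ""))
  invisible(x)
}

#' Inverse-frequency class weights
#'
#' `w_c = N / (K * N_c)` for `K` classes: balanced counts give all ones,
#' rare classes are up-weighted in the cross-entropy so imbalanced corpora
#' do not swamp the minority sounds.
#'
#' @param counts Named positive integer vector of per-class counts.
#' @return Named numeric vector of weights.
#' @export
compute_class_weights <- function(counts) {
  counts <- unlist(counts)
  if (any(counts <= 0)) {
    stop("compute_class_weights: every class needs a positive count")
  }
  n <- sum(counts)
  k <- length(counts)
  w <- n / (k * counts)
  names(w) <- names(counts)
  w
}

#' Training configuration
#'
#' @param epochs Training epochs (the study trained for 100).
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param class_weights Named per-class loss weights; `NULL` computes
#'   inverse-frequency weights from the training labels.
#' @param val_fraction Fraction of training *patients* held out for the
#'   per-epoch validation curve.
#' @param seed RNG seed for shuffling and the validation split.
#' @return A `training_config`.
#' @export
training_config <- function(epochs = 100L, batch_size = 16L,
                            learning_rate = 1e-3, class_weights = NULL,
                            val_fraction = 0.15, seed = 1L) {
  if (epochs < 1L) stop("training_config: epochs must be >= 1")
  if (!is.null(class_weights) && any(class_weights <= 0)) {
    stop("training_config: class weights must be positive")
  }
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, class_weights = class_weights,
         val_fraction = val_fraction, seed = as.integer(seed)),
    class = "training_config"
  )
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

feature_matrix <- function(feat) {
  # time x mel matrix
  if (inherits(feat, "log_mel_spectrogram")) feat$values else as.matrix(feat)
}

# engine input layout: column-major flattening of (frames x mels) to
# (frames*mels) x 1, spatial position (i, j) at row i + j*frames
nn_input <- function(x) matrix(as.vector(x), ncol = 1L)

#' Train a classifier on labelled log-mel features
#'
#' Weighted cross-entropy optimisation with Adam. The per-epoch validation
#' split is patient-grouped (entire simulated patients are held out), and
#' the weights from the best-validation-accuracy epoch are retained. If a
#' `split` column is available, supplying beats marked `"test"` alongside
#' training beats of the same patient is an error: the study's split
#' discipline keeps every patient on one side.
#'
#' @param model A [build_model()] result.
#' @param features List of `log_mel_spectrogram` (or time x mel matrices).
#' @param labels Character vector of class labels.
#' @param patient_id Character vector grouping beats by simulated patient.
#' @param config A [training_config()].
#' @param split Optional character vector of split markers for the supplied
#'   beats; if any patient appears under more than one marker the call is
#'   an error (patient leakage across splits).
#' @return The trained `bruit_model`, with a `learning_curve` tibble
#'   (epoch, train_accuracy, train_loss, val_accuracy, val_loss) attached.
#' @export
train_model <- function(model, features, labels, patient_id = NULL,
                        config = training_config(), split = NULL) {
  stopifnot(inherits(model, "bruit_model"))
  n <- length(features)
  if (n != length(labels)) stop("train_model: features/labels length mismatch")
  if (!is.null(split) && !is.null(patient_id)) {
    leaks <- tapply(split, patient_id, function(s) length(unique(s)))
    if (any(leaks > 1L)) {
      stop("train_model: patient(s) appear in more than one split: ",
           paste(names(leaks)[leaks > 1L], collapse = ", "))
    }
  }
  if (length(unique(labels)) < 2L) {
    stop("train_model: corpus must contain at least two classes")
  }
  bad <- setdiff(unique(labels), model$classes)
  if (length(bad)) stop("train_model: unknown labels: ",
                        paste(bad, collapse = ", "))
  if (is.null(patient_id)) patient_id <- sprintf("P%05d", seq_len(n))

  xs <- lapply(features, feature_matrix)
  d <- dim(xs[[1]])
  if (d[1] != model$cfg$input_frames || d[2] != model$cfg$n_mels) {
    stop(sprintf(
      "train_model: features are %d x %d but the model expects %d frames x %d mels",
      d[1], d[2], model$cfg$input_frames, model$cfg$n_mels
    ))
  }
  xs <- lapply(xs, nn_input)
  y <- match(labels, model$classes) - 1L

  cw <- config$class_weights
  if (is.null(cw)) {
    counts <- table(factor(labels, levels = model$classes))
    counts <- counts[counts > 0]
    cw_all <- compute_class_weights(as.integer(counts))
    names(cw_all) <- names(counts)
    cw <- cw_all
  }
  wts <- unname(cw[labels])
  if (anyNA(wts)) stop("train_model: class weight missing for some label")

  curve <- vector("list", config$epochs)
  best <- list(acc = -Inf, params = model$params, state = model$state)
  with_seed(config$seed, {
    patients <- unique(patient_id)
    n_val_p <- max(1L, round(config$val_fraction * length(patients)))
    if (length(patients) <= n_val_p) {
      stop("train_model: too few patients for a patient-grouped validation split")
    }
    val_p <- sample(patients, n_val_p)
    val_idx <- which(patient_id %in% val_p)
    tr_idx <- setdiff(seq_len(n), val_idx)

    params <- model$params
    state <- model$state
    opt <- adam_new(params)
    for (ep in seq_len(config$epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0
      ep_correct <- 0L
      nb <- 0L
      for (b0 in seq(1, length(ord), by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1L, length(ord))]
        stp <- cpp_nn_train_step(model$cfg, params, state, xs[idx],
                                 y[idx], wts[idx])
        state <- stp$state
        upd <- adam_step(params, stp$grads, opt, config$learning_rate)
        params <- upd$params
        opt <- upd$opt
        ep_loss <- ep_loss + stp$loss * length(idx)
        ep_correct <- ep_correct +
          sum(max.col(stp$probs) - 1L == y[idx])
        nb <- nb + length(idx)
      }
      vl <- nn_eval_loss(model$cfg, params, state, xs[val_idx], y[val_idx],
                         wts[val_idx], config$batch_size)
      curve[[ep]] <- tibble::tibble(
        epoch = ep,
        train_accuracy = ep_correct / nb,
        train_loss = ep_loss / nb,
        val_accuracy = vl$accuracy,
        val_loss = vl$loss
      )
      if (vl$accuracy >= best$acc) {
        best <- list(acc = vl$accuracy, params = params, state = state)
      }
    }
  })
  model$params <- best$params
  model$state <- best$state
  model$trained <- TRUE
  model$learning_curve <- do.call(rbind, curve)
  model
}

nn_eval_loss <- function(cfg, params, state, xs, y, wts, batch_size = 32L) {
  if (!length(xs)) return(list(accuracy = NA_real_, loss = NA_real_))
  loss <- 0
  correct <- 0L
  for (b0 in seq(1, length(xs), by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, length(xs))
    fw <- cpp_nn_forward(cfg, params, state, xs[idx])
    p <- fw$probs
    pc <- pmax(p[cbind(seq_along(idx), y[idx] + 1L)], 1e-12)
    loss <- loss + sum(-wts[idx] * log(pc))
    correct <- correct + sum(max.col(p) - 1L == y[idx])
  }
  list(accuracy = correct / length(xs), loss = loss / length(xs))
}

#' Measure the time-axis length at the recurrent / final-feature input
#'
#' Runs an actual forward pass and reports the time length of the tensor
#' leaving the convolutional trunk (entering the recurrent layer for CRNN
#' kinds, the global average pool for the CNN): with the default 400-frame
#' input this is exactly 12. Unlike [time_frames_after_conv()], which
#' computes the same number arithmetically, this inspects the tensor.
#'
#' @param model A `bruit_model`.
#' @return Integer frame count at the trunk output.
#' @export
measure_trunk_frames <- function(model) {
  x <- matrix(0, model$cfg$input_frames, model$cfg$n_mels)
  fw <- cpp_nn_forward(model$cfg, model$params, model$state,
                       list(nn_input(x)))
  fw$trunk_frames
}

#' Predict class probabilities
#'
#' @param object A `bruit_model` (trained or untrained; an untrained model
#'   still emits a valid softmax distribution).
#' @param features A single `log_mel_spectrogram` or a list of them.
#' @param ... Unused.
#' @return A matrix (beats x 5) of probabilities, columns named by class,
#'   each row summing to 1.
#' @export
predict.bruit_model <- function(object, features, ...) {
  if (inherits(features, "log_mel_spectrogram") || is.matrix(features)) {
    features <- list(features)
  }
  xs <- lapply(features, feature_matrix)
  d <- dim(xs[[1]])
  if (d[1] != object$cfg$input_frames || d[2] != object$cfg$n_mels) {
    stop(sprintf(
      "predict: features are %d x %d but the model expects %d frames x %d mels",
      d[1], d[2], object$cfg$input_frames, object$cfg$n_mels
    ))
  }
  xs <- lapply(xs, nn_input)
  out <- matrix(NA_real_, length(xs), object$cfg$n_classes)
  for (b0 in seq(1, length(xs), by = 32L)) {
    idx <- b0:min(b0 + 31L, length(xs))
    out[idx, ] <- cpp_nn_forward(object$cfg, object$params, object$state,
                                 xs[idx])$probs
  }
  colnames(out) <- object$classes
  out
}
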