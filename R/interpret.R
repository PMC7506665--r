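bilinear_upsample <- function(m, out_rows, out_cols) {
  r_in <- nrow(m); c_in <- ncol(m)
  # map output pixel centres onto input pixel centres
  ri <- (seq_len(out_rows) - 0.5) / out_rows * r_in + 0.5
  ci <- (seq_len(out_cols) - 0.5) / out_cols * c_in + 0.5
  ri <- pmin(pmax(ri, 1), r_in)
  ci <- pmin(pmax(ci, 1), c_in)
  r0 <- pmin(floor(ri), r_in - 1L); r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(ci), c_in - 1L); c0 <- pmax(c0, 1L)
  fr <- ri - r0; fc <- ci - c0
  m00 <- m[r0, c0, drop = FALSE]
  m10 <- m[r0 + 1L, c0, drop = FALSE]
  m01 <- m[r0, c0 + 1L, drop = FALSE]
  m11 <- m[r0 + 1L, c0 + 1L, drop = FALSE]
  fr_m <- matrix(fr, out_rows, out_cols)
  fc_m <- matrix(fc, out_rows, out_cols, byrow = TRUE)
  m00 * (1 - fr_m) * (1 - fc_m) + m10 * fr_m * (1 - fc_m) +
    m01 * (1 - fr_m) * fc_m + m11 * fr_m * fc_m
}

#' Grad-CAM heatmap for a class decision
#'
#' Localises the time-frequency regions driving a model's score for one
#' class: the activations of the last convolutional layer are weighted by
#' the spatial mean of the target-class logit's gradient per channel,
#' summed, rectified, bilinearly upsampled to the input grid, and
#' max-normalised (an all-zero map stays zero). For recurrent
#' architectures the attribution is taken on the convolutional trunk.
#'
#' @param model A `bruit_model`.
#' @param spec A `log_mel_spectrogram` matching the model's input shape.
#' @param target_class Class label (or index) whose evidence to localise.
#' @return A `grad_cam_map`: `values` (`n_frames` x `n_mels`, in `[0, 1]`),
#'   `target_class`, `kind`.
#' @export
grad_cam <- function(model, spec, target_class) {
  stopifnot(inherits(model, "bruit_model"))
  x <- feature_matrix(spec)
  if (nrow(x) != model$cfg$input_frames || ncol(x) != model$cfg$n_mels) {
    stop(sprintf(
      "grad_cam: features are %d x %d but the model expects %d frames x %d mels",
      nrow(x), ncol(x), model$cfg$input_frames, model$cfg$n_mels
    ))
  }
  if (is.character(target_class)) {
    idx <- match(target_class, model$classes)
    if (is.na(idx)) stop("grad_cam: unknown class: ", target_class)
  } else {
    idx <- as.integer(target_class)
    if (idx < 1L || idx > length(model$classes)) {
      stop("grad_cam: class index out of range")
    }
    target_class <- model$classes[idx]
  }
  res <- cpp_nn_gradcam(model$cfg, model$params, model$state,
                        list(nn_input(x)),
                        idx - 1L)
  h <- res$H; w <- res$W
  act <- res$act   # (h*w) x C
  grad <- res$grad
  ch_w <- colMeans(grad)
  cam <- as.vector(act %*% ch_w)
  cam <- pmax(cam, 0)
  cam <- matrix(cam, h, w) # rows = pooled time, cols = pooled frequency
  up <- bilinear_upsample(cam, nrow(x), ncol(x))
  mx <- max(up)
  if (mx > 0) up <- up / mx
  structure(
    list(values = up, target_class = target_class, kind = model$spec$kind,
         probs = res$probs[1, ]),
    class = "grad_cam_map"
  )
}
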