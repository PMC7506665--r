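#' One-vs-rest ROC curve and AUC
#'
#' Threshold sweep over the unique scores (tied scores flip together),
#' true/false positive rates per threshold, and the trapezoidal area under
#' the (FPR, TPR) curve. Equivalent to the pairwise concordance statistic
#' `(concordant + 0.5 * ties) / pairs`.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Logical (or 0/1) ground-truth labels.
#' @return A `roc_result`: `thresholds`, `fpr`, `tpr` (aligned, threshold
#'   decreasing), `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("roc_auc: length mismatch")
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("roc_auc: both label values must be present")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # group tied scores so they flip together
  grp_end <- which(diff(s) != 0)
  ends <- c(grp_end, length(s))
  tp <- cumsum(l)[ends]
  fp <- cumsum(!l)[ends]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(
    list(thresholds = c(Inf, s[ends]), fpr = fpr, tpr = tpr, auc = auc),
    class = "roc_result"
  )
}

model_kind_rank <- function(model) {
  match(tolower(model), c("cnn", "gru", "lstm"), nomatch = 99L)
}

#' Select the best base model per class
#'
#' Per-class argmax of one-vs-rest AUC over a (class, model, n_mels) table.
#' Ties break deterministically toward smaller `n_mels`, then model order
#' CNN < GRU < LSTM.
#'
#' @param auc_table Data frame with columns `class`, `model`, `n_mels`,
#'   `auc`.
#' @return Tibble with one row per class: `class`, `model`, `n_mels`,
#'   `auc`.
#' @export
select_best_models <- function(auc_table) {
  need <- c("class", "model", "n_mels", "auc")
  if (!all(need %in% names(auc_table))) {
    stop("select_best_models: auc_table needs columns ",
         paste(need, collapse = ", "))
  }
  out <- lapply(split(auc_table, auc_table$class), function(d) {
    d <- d[order(-d$auc, d$n_mels, model_kind_rank(d$model)), ]
    d[1, need]
  })
  res <- do.call(rbind, out)
  tibble::as_tibble(res)
}

#' Fit a per-class stacking ensemble over base-model scores
#'
#' For each class, a logistic meta-classifier is fitted on the base models'
#' one-vs-rest probabilities for that class; ensemble predictions are the
#' per-class meta-probabilities renormalised to sum to 1. Base scores must
#' come from data disjoint from the base models' training beats.
#'
#' @param base_scores Named list of matrices (beats x classes), one per
#'   base model, columns named by class.
#' @param labels Character vector of true classes.
#' @param seed Seed (the logistic fits are deterministic; the seed is kept
#'   for interface symmetry and future resampling).
#' @param beat_ids,base_train_ids Optional identifiers used to verify that
#'   no beat was seen during base-model training.
#' @return An `ensemble_spec` with per-class coefficient vectors.
#' @export
fit_stacker <- function(base_scores, labels, seed = 1L, beat_ids = NULL,
                        base_train_ids = NULL) {
  stopifnot(is.list(base_scores), length(base_scores) >= 1L)
  if (!is.null(beat_ids) && !is.null(base_train_ids)) {
    leaked <- intersect(beat_ids, base_train_ids)
    if (length(leaked)) {
      stop("fit_stacker: beats used for base-model training leaked into the stacking fold: ",
           paste(utils::head(leaked, 5), collapse = ", "))
    }
  }
  classes <- colnames(base_scores[[1]])
  n <- nrow(base_scores[[1]])
  if (length(labels) != n) stop("fit_stacker: labels length mismatch")
  coefs <- list()
  for (cl in classes) {
    X <- sapply(base_scores, function(m) m[, cl])
    X <- matrix(X, nrow = n)
    ybin <- as.integer(labels == cl)
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, X), ybin,
                     family = stats::binomial())
    )
    coefs[[cl]] <- fit$coefficients
  }
  structure(
    list(coefficients = coefs, classes = classes,
         models = names(base_scores) %||% paste0("model", seq_along(base_scores)),
         seed = seed),
    class = "ensemble_spec"
  )
}

#' Predict with a stacking ensemble
#'
#' @param object An [fit_stacker()] result.
#' @param base_scores Named list of base-model score matrices, as in
#'   [fit_stacker()].
#' @param ... Unused.
#' @return Matrix (beats x classes) of renormalised probabilities.
#' @export
predict.ensemble_spec <- function(object, base_scores, ...) {
  n <- nrow(base_scores[[1]])
  out <- matrix(NA_real_, n, length(object$classes),
                dimnames = list(NULL, object$classes))
  for (cl in object$classes) {
    X <- matrix(sapply(base_scores, function(m) m[, cl]), nrow = n)
    eta <- cbind(1, X) %*% object$coefficients[[cl]]
    out[, cl] <- 1 / (1 + exp(-eta))
  }
  out / rowSums(out)
}

confusion_counts <- function(pred_pos, true_pos) {
  c(tp = sum(pred_pos & true_pos), fp = sum(pred_pos & !true_pos),
    fn = sum(!pred_pos & true_pos), tn = sum(!pred_pos & !true_pos))
}

#' Per-class metric report
#'
#' One-vs-rest confusion per class at the stated threshold rule (default:
#' argmax assignment), then accuracy, precision, recall, specificity, F1
#' and one-vs-rest AUC, plus their macro means.
#'
#' @param predictions Matrix (beats x classes) of probabilities with class
#'   column names.
#' @param labels Character vector of true classes.
#' @param threshold_rule `"argmax"` (default) or a named numeric vector of
#'   per-class probability thresholds (a beat is positive for a class when
#'   its probability exceeds that class's threshold).
#' @return A tibble with one row per class plus a `macro` row; columns
#'   `class`, `accuracy`, `precision`, `recall`, `specificity`, `f1`,
#'   `auc`.
#' @export
metrics_report <- function(predictions, labels, threshold_rule = "argmax") {
  if (nrow(predictions) != length(labels)) {
    stop("metrics_report: predictions/labels length mismatch")
  }
  classes <- colnames(predictions)
  argmax_class <- classes[max.col(predictions, ties.method = "first")]
  rows <- lapply(classes, function(cl) {
    true_pos <- labels == cl
    pred_pos <- if (identical(threshold_rule, "argmax")) {
      argmax_class == cl
    } else {
      predictions[, cl] > threshold_rule[[cl]]
    }
    cc <- confusion_counts(pred_pos, true_pos)
    prec <- if (cc["tp"] + cc["fp"] > 0) cc["tp"] / (cc["tp"] + cc["fp"]) else NA_real_
    rec <- if (cc["tp"] + cc["fn"] > 0) cc["tp"] / (cc["tp"] + cc["fn"]) else NA_real_
    spec <- if (cc["tn"] + cc["fp"] > 0) cc["tn"] / (cc["tn"] + cc["fp"]) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
      2 * prec * rec / (prec + rec)
    } else NA_real_
    auc <- if (any(true_pos) && !all(true_pos)) {
      roc_auc(predictions[, cl], true_pos)$auc
    } else NA_real_
    tibble::tibble(
      class = cl,
      accuracy = unname((cc["tp"] + cc["tn"]) / sum(cc)),
      precision = unname(prec), recall = unname(rec),
      specificity = unname(spec), f1 = unname(f1), auc = unname(auc)
    )
  })
  per_class <- do.call(rbind, rows)
  macro <- tibble::tibble(
    class = "macro",
    accuracy = mean(per_class$accuracy, na.rm = TRUE),
    precision = mean(per_class$precision, na.rm = TRUE),
    recall = mean(per_class$recall, na.rm = TRUE),
    specificity = mean(per_class$specificity, na.rm = TRUE),
    f1 = mean(per_class$f1, na.rm = TRUE),
    auc = mean(per_class$auc, na.rm = TRUE)
  )
  rbind(per_class, macro)
}

#' Longitudinal class-proportion trend
#'
#' For monitoring a patient's access over time: per date, the mean
#' predicted probability and the argmax share of each class over that
#' day's beats, sorted chronologically. A rising share of intermittent or
#' whistle sounds flags developing stenosis.
#'
#' @param daily_beat_predictions Named list: names are dates (coercible by
#'   `as.Date`), values are matrices (beats x classes) of probabilities.
#' @return Tibble: `date`, `class`, `mean_probability`, `argmax_share`,
#'   sorted by date.
#' @export
class_trend <- function(daily_beat_predictions) {
  if (!length(daily_beat_predictions)) stop("class_trend: empty input")
  dates <- as.Date(names(daily_beat_predictions))
  ord <- order(dates)
  rows <- lapply(ord, function(i) {
    p <- daily_beat_predictions[[i]]
    classes <- colnames(p)
    am <- classes[max.col(p, ties.method = "first")]
    tibble::tibble(
      date = dates[i],
      class = classes,
      mean_probability = unname(colMeans(p)),
      argmax_share = unname(vapply(classes, function(cl) mean(am == cl),
                                    numeric(1)))
    )
  })
  do.call(rbind, rows)
}
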