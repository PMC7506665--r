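test_that("roc_auc handles the canonical cases", {
  labels <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(roc_auc(c(1, 0, 1, 0), labels)$auc, 1.0)
  expect_equal(roc_auc(c(0, 1, 0, 1), labels)$auc, 0.0)
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(TRUE, FALSE, TRUE, FALSE))$auc,
               0.75)
  expect_error(roc_auc(c(1, 2), c(TRUE, TRUE)), "both label values")
})

test_that("roc curves are monotone and anchored", {
  with_seed(7, {
    s <- runif(30)
    l <- runif(30) < 0.4
  })
  r <- roc_auc(s, l)
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))
  expect_equal(r$fpr[1], 0)
  expect_equal(r$tpr[length(r$tpr)], 1)
})

test_that("roc_auc equals the exhaustive pairwise concordance oracle", {
  with_seed(123, {
    for (i in 1:30) {
      n <- sample(4:50, 1)
      scores <- round(runif(n), sample(c(1, 2, 6), 1)) # force some ties
      labels <- runif(n) < runif(1, 0.2, 0.8)
      if (!any(labels) || all(labels)) next
      expect_equal(roc_auc(scores, labels)$auc,
                   auc_bruteforce(scores, labels), tolerance = 1e-12)
    }
  })
})

test_that("label-independent scores give AUC near one half", {
  with_seed(55, {
    aucs <- replicate(40, {
      s <- runif(60)
      l <- c(rep(TRUE, 30), rep(FALSE, 30))
      roc_auc(s, l)$auc
    })
  })
  v <- (30 + 30 + 1) / (12 * 30 * 30) # AUC variance under the null
  expect_lt(abs(mean(aucs) - 0.5), 3 * sqrt(v / 40))
})

test_that("per-class model selection takes the AUC argmax", {
  models <- c("cnn", "gru", "lstm")
  mels <- c(64, 128, 256, 512, 1024)
  grid <- expand.grid(model = models, n_mels = mels,
                      stringsAsFactors = FALSE)
  # a published-style AUC sweep: one row per (class, model, n_mels)
  aucs <- list(
    normal = c(0.58, 0.59, 0.60, 0.70, 0.72, 0.64, 0.69, 0.73, 0.66,
               0.69, 0.72, 0.66, 0.70, 0.72, 0.65),
    hard = c(0.70, 0.70, 0.68, 0.81, 0.81, 0.69, 0.84, 0.87, 0.78,
             0.83, 0.90, 0.85, 0.83, 0.91, 0.73),
    high = c(0.77, 0.77, 0.76, 0.80, 0.77, 0.78, 0.80, 0.80, 0.80,
             0.78, 0.80, 0.80, 0.79, 0.76, 0.77),
    intermittent = c(0.83, 0.88, 0.77, 0.78, 0.85, 0.82, 0.83, 0.78, 0.77,
                     0.87, 0.87, 0.82, 0.84, 0.94, 0.92),
    whistle = c(0.89, 0.85, 0.85, 0.89, 0.89, 0.86, 0.89, 0.89, 0.89,
                0.87, 0.87, 0.87, 0.88, 0.88, 0.86)
  )
  tbl <- do.call(rbind, lapply(names(aucs), function(cl) {
    data.frame(class = cl, grid, auc = aucs[[cl]])
  }))
  best <- select_best_models(tbl)
  pick <- function(cl) best[best$class == cl, ]
  expect_equal(pick("hard")$model, "gru")
  expect_equal(pick("hard")$n_mels, 1024)
  expect_equal(pick("hard")$auc, 0.91)
  expect_equal(pick("intermittent")$model, "gru")
  expect_equal(pick("intermittent")$n_mels, 1024)
  expect_equal(pick("intermittent")$auc, 0.94)
  # ties break toward smaller n_mels, then CNN < GRU < LSTM
  expect_equal(pick("whistle")$model, "cnn")
  expect_equal(pick("whistle")$n_mels, 64)
  expect_equal(pick("high")$model, "cnn")
  expect_equal(pick("high")$n_mels, 128)
})

test_that("a dominant model is selected for every class", {
  tbl <- expand.grid(class = c("a", "b"), model = c("cnn", "gru"),
                     n_mels = c(64, 128), stringsAsFactors = FALSE)
  tbl$auc <- ifelse(tbl$model == "gru" & tbl$n_mels == 128, 0.95, 0.6)
  best <- select_best_models(tbl)
  expect_true(all(best$model == "gru" & best$n_mels == 128))
  expect_error(select_best_models(tbl[, -4]), "columns")
})

test_that("stacking dominates base models that specialise per class", {
  classes <- bruit_classes()
  with_seed(77, {
    labels <- sample(classes, 300, replace = TRUE)
  })
  scores <- list(
    hard_expert = make_onehot_scores(labels, classes, "hard", 1),
    whistle_expert = make_onehot_scores(labels, classes, "whistle", 2)
  )
  macro_auc <- function(p) {
    mean(sapply(classes, function(cl) roc_auc(p[, cl], labels == cl)$auc))
  }
  ens <- fit_stacker(scores, labels, seed = 1)
  stacked <- predict(ens, scores)
  expect_gte(macro_auc(stacked),
             max(macro_auc(scores[[1]]), macro_auc(scores[[2]])) - 1e-9)
})

test_that("a single-model stack preserves its ranking", {
  classes <- c("a", "b")
  with_seed(5, {
    labels <- sample(classes, 80, replace = TRUE)
    s <- matrix(runif(160), 80, dimnames = list(NULL, classes))
    s[, "a"] <- s[, "a"] + (labels == "a")
    s <- s / rowSums(s)
  })
  ens <- fit_stacker(list(only = s), labels)
  p <- predict(ens, list(only = s))
  expect_equal(roc_auc(p[, "a"], labels == "a")$auc,
               roc_auc(s[, "a"], labels == "a")$auc, tolerance = 1e-6)
})

test_that("stacker fits are reproducible and refuse leaked beats", {
  classes <- c("a", "b")
  with_seed(6, {
    labels <- sample(classes, 40, replace = TRUE)
    s <- matrix(runif(80), 40, dimnames = list(NULL, classes))
  })
  e1 <- fit_stacker(list(m = s), labels, seed = 3)
  e2 <- fit_stacker(list(m = s), labels, seed = 3)
  expect_identical(e1$coefficients, e2$coefficients)
  expect_error(
    fit_stacker(list(m = s), labels, beat_ids = sprintf("B%02d", 1:40),
                base_train_ids = c("B05", "XX")),
    "leaked"
  )
})

test_that("metrics_report computes the standard confusion formulas", {
  classes <- c("a", "b")
  perfect <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
                    dimnames = list(NULL, classes))
  rep <- metrics_report(perfect, c("a", "b"))
  expect_true(all(rep[rep$class != "macro",
                      c("accuracy", "precision", "recall",
                        "specificity", "f1", "auc")] == 1))

  # constructed confusion for class "a": TP=43, FN=49, FP=54, TN=54
  n <- 200
  labels <- c(rep("a", 92), rep("b", 108))
  pred_a <- c(rep(TRUE, 43), rep(FALSE, 49), rep(TRUE, 54), rep(FALSE, 54))
  p <- matrix(0.5, n, 2, dimnames = list(NULL, classes))
  p[pred_a, "a"] <- 0.9; p[pred_a, "b"] <- 0.1
  p[!pred_a, "a"] <- 0.1; p[!pred_a, "b"] <- 0.9
  rep <- metrics_report(p, labels)
  a <- rep[rep$class == "a", ]
  expect_equal(a$accuracy, (43 + 54) / 200)
  expect_equal(a$precision, 43 / (43 + 54))
  expect_equal(a$recall, 43 / (43 + 49))
  expect_equal(a$specificity, 54 / (54 + 54))
  expect_equal(a$f1, 2 * a$precision * a$recall / (a$precision + a$recall))
  # internal consistency per class: accuracy = (TP+TN)/N
  b <- rep[rep$class == "b", ]
  expect_equal(b$accuracy, a$accuracy)
})

test_that("an always-positive predictor has zero specificity", {
  classes <- c("a", "b")
  p <- matrix(c(0.99, 0.01), 50, 2, byrow = TRUE,
              dimnames = list(NULL, classes))
  with_seed(2, labels <- sample(classes, 50, replace = TRUE))
  rep <- metrics_report(p, labels)
  expect_equal(rep$specificity[rep$class == "a"], 0)
  expect_error(metrics_report(p, labels[-1]), "length")
})

test_that("class_trend aggregates by date in chronological order", {
  classes <- bruit_classes()
  hard_day <- matrix(0.02, 6, 5, dimnames = list(NULL, classes))
  hard_day[, "hard"] <- 0.92
  one <- class_trend(list(`2024-03-01` = hard_day))
  expect_equal(unname(one$argmax_share[one$class == "hard"]), 1.0)

  with_seed(9, {
    days <- sprintf("2024-03-%02d", 1:6)
    series <- lapply(1:6, function(d) {
      ramp <- 0.1 + 0.12 * d
      m <- matrix((1 - ramp) / 4, 8, 5, dimnames = list(NULL, classes))
      m[, "intermittent"] <- ramp
      m + matrix(runif(40, 0, 1e-3), 8, 5)
    })
    names(series) <- days
  })
  shuffled <- series[c(4, 1, 6, 2, 5, 3)]
  trend <- class_trend(shuffled)
  inter <- trend[trend$class == "intermittent", ]
  expect_equal(inter$date, as.Date(days))
  expect_true(all(diff(inter$mean_probability) > 0))
  expect_error(class_trend(list()), "empty")
})
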