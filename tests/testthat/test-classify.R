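# small helper: a feature frame whose six columns are filled from one
# discriminative column plus benign constants
toy_features <- function(f1_values) {
  df <- data.frame(window_start = seq_along(f1_values) * 5,
                   step_increment = f1_values, diag_dispersion = 0.1,
                   n_clusters = 1, st_area = 0.01, st_deviation = 0.005,
                   qrs_slope = 0.1, usable = TRUE)
  df$diag_dispersion <- df$diag_dispersion + seq_along(f1_values) * 1e-4
  df$st_area <- df$st_area + rev(seq_along(f1_values)) * 1e-5
  df$n_clusters <- df$n_clusters + (seq_along(f1_values) %% 2) * 1e-3
  df$st_deviation <- df$st_deviation + (seq_along(f1_values) %% 3) * 1e-4
  df$qrs_slope <- df$qrs_slope + (seq_along(f1_values) %% 5) * 1e-4
  df
}

test_that("a linearly separable toy problem trains to perfect accuracy", {
  feats <- toy_features(c(rep(0.1, 20), rep(0.9, 20)))
  labels <- c(rep("normal", 20), rep("afib", 20))
  model <- train_classifier(feats, labels)
  pred <- predict_windows(model, feats)
  expect_equal(as.character(pred), labels)
})

test_that("randomly shuffled labels cross-validate near chance", {
  feats <- toy_features(c(rep(0.1, 30), rep(0.9, 30)))
  set.seed(99)
  labels <- sample(c(rep("normal", 30), rep("afib", 30)))
  cv <- cross_validate(feats, labels, k = 10, seed = 3)
  acc <- (cv$pooled$tp + cv$pooled$tn) /
    (cv$pooled$tp + cv$pooled$tn + cv$pooled$fp + cv$pooled$fn)
  expect_lt(abs(acc - 0.5), 0.2)
})

test_that("training rejects single-class and mismatched input", {
  feats <- toy_features(rep(0.5, 10))
  expect_error(train_classifier(feats, rep("normal", 10)), "2 classes")
  expect_error(train_classifier(feats, rep("normal", 3)), "one entry per")
})

test_that("cross-validation partitions are balanced, exhaustive, reproducible", {
  feats <- toy_features(runif(47))
  labels <- rep(c("normal", "afib"), length.out = 47)
  cv <- cross_validate(feats, labels, k = 10, seed = 5)
  # pooled counts account for every window exactly once
  expect_equal(cv$pooled$tp + cv$pooled$fp + cv$pooled$tn + cv$pooled$fn, 47L)
  # fold sizes differ by at most one
  sizes <- with(cv$folds, tp + fp + tn + fn)
  expect_lte(max(sizes) - min(sizes), 1L)
  # same seed, same everything
  expect_identical(cv, cross_validate(feats, labels, k = 10, seed = 5))
  # different seed may differ, but stays a valid partition
  cv2 <- cross_validate(feats, labels, k = 10, seed = 6)
  expect_equal(cv2$pooled$tp + cv2$pooled$fp + cv2$pooled$tn + cv2$pooled$fn,
               47L)
  # a class smaller than k triggers the fallback warning
  labs3 <- c(rep("normal", 42), rep("afib", 5))
  expect_warning(cross_validate(feats, labs3, k = 10, seed = 1), "fewer than")
})

test_that("degenerate predictors force the boundary metric pairs", {
  truth <- c(rep("normal", 25), rep("afib", 15), rep("ischemia", 10))
  # an always-normal predictor: sensitivity 1, specificity 0
  m_all_normal <- confusion_metrics(count_confusion(truth, rep("normal", 50)))
  expect_equal(unname(m_all_normal), c(1, 0))
  # a perfectly inverted predictor: 0 and 0
  inverted <- ifelse(truth == "normal", "afib", "normal")
  expect_equal(unname(confusion_metrics(count_confusion(truth, inverted))),
               c(0, 0))
  # a perfect predictor: 1 and 1 (wrong-disease confusions still count TN)
  swapped <- ifelse(truth == "normal", "normal",
                    ifelse(truth == "afib", "ischemia", "afib"))
  expect_equal(unname(confusion_metrics(count_confusion(truth, swapped))),
               c(1, 1))
})

test_that("unusable windows get NA labels and are excluded from reports", {
  feats <- toy_features(c(rep(0.1, 10), rep(0.9, 10)))
  labels <- c(rep("normal", 10), rep("afib", 10))
  model <- train_classifier(feats, labels)
  feats$step_increment[3] <- NA
  pred <- predict_windows(model, feats)
  expect_true(is.na(pred[3]))
  expect_equal(sum(is.na(pred)), 1L)
  all_na <- feats; all_na$step_increment <- NA
  expect_true(all(is.na(predict_windows(model, all_na))))
})

test_that("minute report applies strict-majority disease flags", {
  mk_labels <- function(x) factor(x, levels = class_labels())
  feats <- toy_features(runif(12))
  feats$window_start <- seq(0, 55, by = 5)
  # 7 of 12 afib: flag set
  lab <- mk_labels(c(rep("afib", 7), rep("normal", 5)))
  rep1 <- minute_report(lab, feats, 0)
  expect_equal(rep1$af_flag, 1L)
  expect_equal(rep1$ischemia_flag, 0L)
  # exact 6/6 tie: strict majority not reached
  lab2 <- mk_labels(c(rep("afib", 6), rep("normal", 6)))
  expect_equal(minute_report(lab2, feats, 0)$af_flag, 0L)
  # all normal: both flags clear
  lab3 <- mk_labels(rep("normal", 12))
  rep3 <- minute_report(lab3, feats, 0)
  expect_equal(c(rep3$af_flag, rep3$ischemia_flag), c(0L, 0L))
  # empty minute: NA fields
  rep4 <- minute_report(lab3, feats, 3)
  expect_true(is.na(rep4$af_flag))
  # feature means cover usable windows only
  lab5 <- mk_labels(c(rep("afib", 11), NA))
  rep5 <- minute_report(lab5, feats, 0)
  expect_equal(rep5$n_windows, 11L)
  expect_equal(rep5$step_increment, mean(feats$step_increment[1:11]))
})

test_that("JSON persistence reproduces the in-memory decision function", {
  feats <- rbind(pipeline_features("normal", 21, duration = 60, fs = 360),
                 pipeline_features("afib", 22, duration = 60, fs = 360),
                 pipeline_features("ischemia", 23, duration = 60, fs = 360))
  model <- train_classifier(feats, feats$label)
  path <- withr::local_tempfile(fileext = ".json")
  save_classifier(model, path)
  back <- load_classifier(path)
  set.seed(31)
  probe <- feats[sample(nrow(feats)), ]
  expect_identical(predict_windows(back, probe),
                   predict_windows(model, probe))
  # the file is genuinely portable text
  expect_true(jsonlite::validate(paste(readLines(path), collapse = "")))
})

test_that("the trained pipeline classifies fresh generator records end to end", {
  train_feats <- rbind(pipeline_features("normal", 41, duration = 90, fs = 360),
                       pipeline_features("afib", 42, duration = 90, fs = 360),
                       pipeline_features("ischemia", 43, duration = 90, fs = 360))
  model <- train_classifier(train_feats, train_feats$label)
  rec <- generate_ecg(rhythm_spec("afib"), fs = 360, duration = 90, seed = 44)
  res <- classify_record(rec$signal, model)
  lab <- res$windows$label
  expect_gte(mean(lab == "afib", na.rm = TRUE), 0.8)
  expect_equal(res$minutes$af_flag[1], 1L)
  ev <- evaluate_pipeline(list(list(signal = rec$signal, label = "afib")),
                          model)
  expect_gte(ev$per_record$agreement[1], 0.8)
})
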