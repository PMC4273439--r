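#' Specification of the window classifier
#'
#' Two binary support-vector machines sharing the six normalized features:
#' one flags atrial fibrillation, the other myocardial ischemia, each
#' against all remaining windows (the device reports the two disease flags
#' independently).  A window is labeled normal when neither detector
#' fires; when both fire, the larger decision value wins.
#'
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param C regularization constant (> 0), default 1.
#' @param gamma RBF kernel width; default `NULL` means `1 / (p * mean
#'   feature variance)` computed from the training set (p = 6 features).
#' @return an object of class `svm_model_spec`.
#' @export
svm_model_spec <- function(kernel = c("rbf", "linear"), C = 1, gamma = NULL) {
  kernel <- match.arg(kernel)
  if (C <= 0) stop("`C` must be positive", call. = FALSE)
  if (!is.null(gamma) && gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  structure(list(kernel = kernel, C = C, gamma = gamma),
            class = "svm_model_spec")
}

resolve_gamma <- function(spec, x) {
  if (!is.null(spec$gamma)) return(spec$gamma)
  v <- mean(apply(x, 2, stats::var))
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(x) * v)
}

fit_binary_svm <- function(x, positive, spec) {
  y <- factor(ifelse(positive, "pos", "neg"), levels = c("pos", "neg"))
  g <- resolve_gamma(spec, x)
  e1071::svm(x, y,
             kernel = if (spec$kernel == "rbf") "radial" else "linear",
             cost = spec$C, gamma = g, scale = FALSE)
}

# decision values oriented so positive value = disease
binary_decision <- function(fit, x) {
  if (inherits(fit, "portable_svm")) return(portable_decision(fit, x))
  pr <- stats::predict(fit, x, decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  # e1071 orients the decision value toward the first class of the pair
  if (startsWith(colnames(attr(pr, "decision.values"))[1], "pos")) dv else -dv
}

#' Train the window classifier
#'
#' Fits the normalizer on the training features, then the two binary SVM
#' detectors on the normalized values.  Training is deterministic given
#' the data order and spec.
#'
#' @param features feature `data.frame` (raw scale; see
#'   [extract_features()]).  Unusable rows (any `NA` feature) are dropped
#'   together with their labels.
#' @param labels class labels, one per feature row (`"normal"`, `"afib"`,
#'   `"ischemia"`).
#' @param spec an [svm_model_spec()].
#' @return an object of class `ecg_classifier` holding the two detectors,
#'   the fitted normalizer, and the spec.
#' @export
train_classifier <- function(features, labels, spec = svm_model_spec()) {
  labels <- as_class_label(labels)
  if (length(labels) != nrow(features)) {
    stop("`labels` must have one entry per feature row", call. = FALSE)
  }
  keep <- stats::complete.cases(features[, feature_names()]) & !is.na(labels)
  features <- features[keep, , drop = FALSE]
  labels <- labels[keep]
  if (length(unique(labels)) < 2L) {
    stop("training needs at least 2 classes present", call. = FALSE)
  }
  norm <- fit_normalizer(features)
  x <- as.matrix(apply_normalizer(norm, features)[, feature_names()])
  detectors <- list()
  for (disease in c("afib", "ischemia")) {
    if (any(labels == disease)) {
      detectors[[disease]] <- fit_binary_svm(x, labels == disease, spec)
    }
  }
  structure(list(detectors = detectors, normalizer = norm, spec = spec,
                 gamma = resolve_gamma(spec, x)),
            class = "ecg_classifier")
}

#' @export
print.ecg_classifier <- function(x, ...) {
  cat(sprintf("<ecg_classifier> %s kernel, C=%g, detectors: %s\n",
              x$spec$kernel, x$spec$C,
              paste(names(x$detectors), collapse = ", ")))
  invisible(x)
}

#' Classify feature windows
#'
#' Applies the model's normalizer and the two disease detectors.  Unusable
#' windows (any `NA` feature) get an `NA` label.
#'
#' @param model an `ecg_classifier`.
#' @param features feature `data.frame` on the raw scale.
#' @return factor of window labels (levels [class_labels()]), `NA` for
#'   unusable windows.
#' @export
predict_windows <- function(model, features) {
  stopifnot(inherits(model, "ecg_classifier"))
  out <- factor(rep(NA_character_, nrow(features)), levels = class_labels())
  ok <- stats::complete.cases(features[, feature_names()])
  if (!any(ok)) return(out)
  x <- as.matrix(apply_normalizer(model$normalizer,
                                  features[ok, , drop = FALSE])[, feature_names()])
  dv <- sapply(c("afib", "ischemia"), function(d) {
    if (is.null(model$detectors[[d]])) rep(-Inf, nrow(x))
    else binary_decision(model$detectors[[d]], x)
  })
  dv <- matrix(dv, ncol = 2, dimnames = list(NULL, c("afib", "ischemia")))
  lab <- ifelse(dv[, "afib"] <= 0 & dv[, "ischemia"] <= 0, "normal",
                ifelse(dv[, "afib"] >= dv[, "ischemia"], "afib", "ischemia"))
  out[ok] <- lab
  out
}

#' Stratified k-fold cross-validation of the window classifier
#'
#' Shuffles within class under `seed`, deals the windows into `k` folds
#' (fold sizes differ by at most one), holds each fold out once, and pools
#' the per-fold confusion counts under the positive-equals-normal
#' convention.  The normalizer is refitted inside every fold, so no
#' information leaks from the held-out windows.  Reported sensitivity and
#' specificity are the means over folds (the pooled counts are also
#' returned).  Bit-reproducible for a fixed seed.
#'
#' @inheritParams train_classifier
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return list with `sensitivity`, `specificity` (fold means), `pooled`
#'   (`confusion_counts`), `pooled_metrics`, and `folds` (per-fold data
#'   frame).
#' @export
cross_validate <- function(features, labels, spec = svm_model_spec(),
                           k = 10L, seed = 1L) {
  labels <- as_class_label(labels)
  keep <- stats::complete.cases(features[, feature_names()]) & !is.na(labels)
  features <- features[keep, , drop = FALSE]
  labels <- droplevels(labels[keep])
  n <- nrow(features)
  if (n < k) stop("need at least k usable windows", call. = FALSE)
  small <- table(labels) < k
  if (any(small)) {
    warning("class(es) with fewer than k members: ",
            paste(names(which(small)), collapse = ", "),
            "; their members appear in fewer than k folds")
  }
  fold <- integer(n)
  nxt <- 0L
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- (nxt + seq_along(idx) - 1L) %% k + 1L
      nxt <- (nxt + length(idx)) %% k
    }
  })
  pooled <- confusion_counts()
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    te <- fold == f
    fit <- train_classifier(features[!te, , drop = FALSE], labels[!te], spec)
    pred <- predict_windows(fit, features[te, , drop = FALSE])
    cc <- count_confusion(labels[te], pred)
    for (nm in c("tp", "fp", "tn", "fn")) pooled[[nm]] <- pooled[[nm]] + cc[[nm]]
    m <- confusion_metrics(cc)
    rows[[f]] <- data.frame(fold = f, tp = cc$tp, fp = cc$fp, tn = cc$tn,
                            fn = cc$fn, sensitivity = m["sensitivity"],
                            specificity = m["specificity"])
  }
  folds <- do.call(rbind, rows)
  rownames(folds) <- NULL
  list(sensitivity = mean(folds$sensitivity, na.rm = TRUE),
       specificity = mean(folds$specificity, na.rm = TRUE),
       pooled = pooled,
       pooled_metrics = confusion_metrics(pooled),
       folds = folds)
}

#' Per-minute report: averaged features and disease flags
#'
#' Aggregates the windows whose start time falls in one minute of the
#' record, the way the device's data-description view summarises each
#' minute: per-feature means over usable windows, and one 0/1 flag per
#' disease, set by strict majority of the minute's usable window labels
#' (an exact tie leaves the flag 0).
#'
#' @param labels window labels (factor from [predict_windows()]).
#' @param features the windows' feature `data.frame`.
#' @param minute_index which minute (0-based) of the record to report.
#' @return a one-row `data.frame`: `minute`, `n_windows` (usable),
#'   `af_flag`, `ischemia_flag`, and the six mean features (all `NA` when
#'   the minute has no usable window).
#' @export
minute_report <- function(labels, features, minute_index = 0L) {
  in_min <- features$window_start >= 60 * minute_index &
    features$window_start < 60 * (minute_index + 1)
  use <- in_min & !is.na(labels)
  mf <- as.data.frame(as.list(
    if (any(use)) colMeans(features[use, feature_names(), drop = FALSE])
    else stats::setNames(rep(NA_real_, 6), feature_names())))
  n <- sum(use)
  data.frame(minute = minute_index, n_windows = n,
             af_flag = if (n > 0) as.integer(sum(labels[use] == "afib") > n / 2) else NA_integer_,
             ischemia_flag = if (n > 0) as.integer(sum(labels[use] == "ischemia") > n / 2) else NA_integer_,
             mf)
}

#' Classify a whole record and report per minute
#'
#' Runs the complete test-phase pipeline on a raw record: filter chain,
#' baseline removal, QRS detection and delineation, windowing, feature
#' extraction, window classification, and per-minute aggregation.
#'
#' @param signal a raw `ecg_signal`.
#' @param model a trained `ecg_classifier`.
#' @return list with `windows` (features + `label` column) and `minutes`
#'   (one [minute_report()] row per minute).
#' @export
classify_record <- function(signal, model) {
  filt <- apply_filter_bank(signal)
  det <- remove_baseline(filt)
  beats <- delineate(det, detect_qrs(det))
  feats <- extract_features(filt, beats)
  labels <- predict_windows(model, feats)
  mins <- do.call(rbind, lapply(
    0:max(0, floor((duration(signal) - 1e-9) / 60)),
    function(m) minute_report(labels, feats, m)))
  feats$label <- labels
  list(windows = feats, minutes = mins)
}

#' Save a trained classifier as portable JSON
#'
#' Writes a plain-text dump of both detectors (support vectors, dual
#' coefficients, intercept, kernel parameters) and the normalizer bounds,
#' inspectable and language-portable.  [load_classifier()] restores a
#' model whose predictions match the original exactly.
#'
#' @param model an `ecg_classifier`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "ecg_classifier"))
  dump_det <- function(fit) {
    if (is.null(fit)) return(NULL)
    list(kernel = if (fit$kernel == 2) "rbf" else "linear",
         gamma = fit$gamma,
         rho = as.numeric(fit$rho),
         sv = unname(as.matrix(fit$SV)),
         coefs = as.numeric(fit$coefs),
         # a positive decision value points at the first *internal* class,
         # which follows data order, not factor-level order
         positive_first = startsWith(fit$levels[fit$labels[1]], "pos"))
  }
  obj <- list(
    format = "ecgtriage-svm-1",
    spec = unclass(model$spec),
    gamma = model$gamma,
    normalizer = list(min = as.list(model$normalizer$min),
                      max = as.list(model$normalizer$max)),
    detectors = Filter(Negate(is.null), lapply(model$detectors, dump_det))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a classifier saved by [save_classifier()]
#'
#' @param path JSON file written by [save_classifier()].
#' @return an `ecg_classifier` whose predictions match the saved model.
#' @export
load_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "ecgtriage-svm-1")) {
    stop("not an ecgtriage classifier file", call. = FALSE)
  }
  norm <- structure(list(min = unlist(obj$normalizer$min),
                         max = unlist(obj$normalizer$max)),
                    class = "feature_normalizer")
  dets <- lapply(obj$detectors, function(d) {
    sv <- if (is.matrix(d$sv)) d$sv else matrix(unlist(d$sv),
                                                nrow = length(d$coefs))
    structure(list(kernel = d$kernel, gamma = d$gamma, rho = d$rho,
                   sv = sv, coefs = d$coefs,
                   positive_first = isTRUE(d$positive_first)),
              class = "portable_svm")
  })
  g <- unlist(obj$spec$gamma)
  if (!length(g) || !is.finite(g[1])) g <- NULL
  spec <- svm_model_spec(kernel = obj$spec$kernel, C = obj$spec$C, gamma = g)
  structure(list(detectors = dets, normalizer = norm, spec = spec,
                 gamma = obj$gamma),
            class = "ecg_classifier")
}

# decision function of a deserialized SVM: sum_i coef_i K(sv_i, x) - rho,
# oriented so positive = disease
portable_decision <- function(fit, x) {
  k <- if (fit$kernel == "rbf") {
    d2 <- outer(rowSums(x^2), rowSums(fit$sv^2), "+") - 2 * x %*% t(fit$sv)
    exp(-fit$gamma * pmax(d2, 0))
  } else {
    x %*% t(fit$sv)
  }
  dv <- drop(k %*% fit$coefs) - fit$rho
  if (fit$positive_first) dv else -dv
}
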