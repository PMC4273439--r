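#' Names of the six window features
#'
#' Three rhythm-irregularity features from the Poincare plot of the
#' window's interbeat intervals (`step_increment`, `diag_dispersion`,
#' `n_clusters`) and three ST-morphology features averaged over the
#' window's delineated beats (`st_area`, `st_deviation`, `qrs_slope`).
#'
#' @return character vector of the six feature column names.
#' @export
feature_names <- function() {
  c("step_increment", "diag_dispersion", "n_clusters",
    "st_area", "st_deviation", "qrs_slope")
}

#' Split a record into 10-second sliding windows with 50% overlap
#'
#' Windows span `window_s` seconds and advance by half that (5 s steps by
#' default), so consecutive windows share half their span.  At a typical
#' resting rate each window holds roughly a dozen interbeat intervals.
#' Each window carries the intervals whose closing beat falls inside it and
#' the beats it contains.  A record shorter than one window yields a single
#' truncated window with a warning.
#'
#' @param ibis an `ibi_series` for the record.
#' @param beats the record's `beat_annotation`.
#' @param record_duration record length in seconds.
#' @param window_s window span in seconds (default 10).
#' @return a list of `analysis_window` objects, each with fields
#'   `start_time`, `end_time`, `ibis` (numeric intervals), `beat_rows`
#'   (row indices into `beats`).
#' @export
make_windows <- function(ibis, beats, record_duration, window_s = 10) {
  stopifnot(inherits(ibis, "ibi_series"), inherits(beats, "beat_annotation"))
  fs <- ibis$fs
  step <- window_s / 2
  if (record_duration < window_s) {
    warning("record shorter than one window; returning a single truncated window")
    starts <- 0
  } else {
    starts <- seq(0, record_duration - window_s, by = step)
  }
  anchor_t <- (ibis$anchors - 1) / fs
  beat_t <- (beats$qrs - 1) / fs
  lapply(starts, function(s0) {
    s1 <- min(s0 + window_s, record_duration)
    structure(list(
      start_time = s0, end_time = s1,
      ibis = ibis$intervals[anchor_t >= s0 & anchor_t < s1],
      beat_rows = which(beat_t >= s0 & beat_t < s1)
    ), class = "analysis_window")
  })
}

#' Poincare (lag-1 return) plot of an interbeat-interval series
#'
#' Point `k` is `(I_k, I_{k+1})`.  A regular rhythm collapses onto a tight
#' spot on the identity diagonal; atrial fibrillation scatters the points.
#'
#' @param intervals numeric vector of intervals (s), or an `ibi_series`.
#' @return a 2-column matrix (`x`, `y`) with `n - 1` rows (0 rows when
#'   fewer than 2 intervals).
#' @export
poincare <- function(intervals) {
  if (inherits(intervals, "ibi_series")) intervals <- intervals$intervals
  n <- length(intervals)
  if (n < 2L) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  }
  cbind(x = intervals[-n], y = intervals[-1L])
}

#' Simplified mean stepping increment (Poincare feature 1)
#'
#' The mean Euclidean distance between consecutive Poincare points,
#' normalized by the window's mean interbeat interval so the feature is
#' invariant to heart rate.  Zero for a perfectly regular rhythm (the
#' points coincide, so every step is zero); large for atrial fibrillation.
#'
#' @param points a Poincare point matrix from [poincare()].
#' @return non-negative scalar, or `NA` with fewer than 2 points.
#' @examples
#' feat_stepping(poincare(c(0.8, 0.8, 0.4, 0.8)))  # ~0.6898
#' @export
feat_stepping <- function(points) {
  m <- nrow(points)
  if (m < 2L) return(NA_real_)
  steps <- sqrt(diff(points[, "x"])^2 + diff(points[, "y"])^2)
  mean_ibi <- mean(c(points[1L, "x"], points[, "y"]))
  mean(steps) / mean_ibi
}

#' Diagonal dispersion (Poincare feature 2)
#'
#' The mean perpendicular distance of the Poincare points from the identity
#' diagonal, `mean(|y - x|) / sqrt(2)`.  Points on the diagonal mean
#' consecutive intervals are equal (regular rhythm); dispersion grows with
#' beat-to-beat irregularity.  The mean (rather than a raw sum) keeps
#' windows with different beat counts comparable.
#'
#' @param points a Poincare point matrix from [poincare()].
#' @return non-negative scalar, or `NA` with no points.
#' @export
feat_dispersion <- function(points) {
  if (nrow(points) < 1L) return(NA_real_)
  mean(abs(points[, "y"] - points[, "x"])) / sqrt(2)
}

#' Number of Poincare clusters by spectral eigengap (feature 3)
#'
#' Builds a Gaussian affinity graph on the points with locally scaled
#' widths, `A_ij = exp(-d_ij^2 / (s_i s_j))`, where `s_i` is the distance
#' from point `i` to its `n_local`-th nearest neighbour, floored at
#' `sigma_min`.  Local scaling keeps well-separated interval blobs
#' disconnected regardless of their spacing (a single global width bridges
#' them); the floor gives the affinity an absolute scale, because rhythm
#' regularity has one — interbeat-interval differences of a few tens of
#' milliseconds are ordinary sinus variability, not structure.  The
#' symmetric normalized graph Laplacian's eigenvalues then select the
#' cluster count `k` in `1..k_max` with the largest eigengap.  A regular
#' rhythm's single cloud gives 1; multimodal interval patterns and the
#' diffuse scatter of atrial fibrillation give more.
#'
#' @param points a Poincare point matrix (at least 2 rows).
#' @param k_max maximum cluster count considered (default 5).
#' @param n_local neighbour rank used for the local scale (default 2,
#'   capped at the number of other points).
#' @param sigma_min floor on the local scale in seconds (default 0.05).
#' @return integer cluster count in `1..k_max` (1 for degenerate
#'   all-identical points).
#' @export
feat_clusters <- function(points, k_max = 5L, n_local = 2L, sigma_min = 0.05) {
  m <- nrow(points)
  if (m < 2L) stop("`points` must contain at least 2 points", call. = FALSE)
  d <- as.matrix(stats::dist(points))
  pos <- d[upper.tri(d)]
  pos <- pos[pos > 0]
  if (!length(pos)) return(1L)  # all points coincide
  kth <- min(n_local, m - 1L)
  s <- apply(d, 1L, function(row) sort(row)[kth + 1L])  # drop self-distance
  s <- pmax(s, sigma_min)
  a <- exp(-d^2 / (s %o% s))
  diag(a) <- 0
  deg <- rowSums(a)
  if (any(deg == 0)) deg[deg == 0] <- .Machine$double.eps
  dm <- 1 / sqrt(deg)
  lsym <- diag(m) - (dm %o% dm) * a
  ev <- sort(eigen(lsym, symmetric = TRUE, only.values = TRUE)$values)
  kk <- seq_len(min(k_max, m - 1L))
  gaps <- ev[kk + 1L] - ev[kk]
  as.integer(which.max(gaps))
}

# Isoelectric reference voltage for ST measures: the mean over the 20 ms
# ending at the QRS onset.  A single onset sample would pick up whatever
# the delineator lands on (often the Q-wave downstroke); the short
# pre-onset patch is the usual isoelectric estimate.
onset_reference <- function(signal, onset) {
  a <- max(1L, onset - as.integer(round(0.02 * signal$fs)))
  mean(signal$samples[a:onset])
}

# find the T-wave onset sample for ST-window purposes: T peak minus twice
# the estimated T half-width (half-prominence width against the local
# ST level); falls back to the midpoint of [offset, t].
t_onset_sample <- function(v, offset, tpk, fs) {
  seg <- v[offset:tpk]
  base <- stats::median(seg)
  prom <- v[tpk] - base
  fallback <- offset + (tpk - offset) %/% 2L
  if (prom <= 0) return(fallback)
  half <- base + prom / 2
  below <- which(seg < half)
  below <- below[below < (tpk - offset + 1L)]
  if (!length(below)) return(fallback)
  left_cross <- offset + max(below) - 1L
  halfw <- tpk - left_cross
  ton <- tpk - 2L * halfw
  if (ton <= offset) fallback else ton
}

#' Cumulative ST--T voltage above the QRS-onset reference (feature 4)
#'
#' The signed area, in mV.s, of the signal between the QRS offset (J
#' point) and the T peak, measured relative to the isoelectric level at
#' the QRS onset (mean of the 20 ms ending at the onset):
#' `sum(v[s] - v_onset) / fs` over that span.  In a normal beat the ST
#' segment sits near the onset level and the area is small; ST elevation
#' inflates it (depression makes it negative).
#'
#' @param signal the filtered `ecg_signal` (use the filter-chain output:
#'   amplitude-sensitive ST measures need the record's low-frequency
#'   content intact, so do not measure them on the wavelet
#'   baseline-removed signal used for QRS detection).
#' @param beat one row of a delineated `beat_annotation` (needs `onset`,
#'   `offset`, `t`).
#' @return signed area in mV.s, or `NA` when a fiducial is missing.
#' @export
feat_cumulative_voltage <- function(signal, beat) {
  stopifnot(inherits(signal, "ecg_signal"))
  if (is.na(beat$onset) || is.na(beat$offset) || is.na(beat$t)) return(NA_real_)
  v <- signal$samples
  sum(v[beat$offset:beat$t] - onset_reference(signal, beat$onset)) / signal$fs
}

#' Voltage deviation within the ST segment (feature 5)
#'
#' Standard deviation of the signal over the ST window, from the QRS
#' offset to the estimated T-wave onset (T peak minus twice the estimated
#' T half-width; midpoint fallback).  A flat ST segment gives 0; sloped or
#' distorted ST segments give more.  Invariant to DC shifts.
#'
#' @inheritParams feat_cumulative_voltage
#' @return standard deviation in mV, or `NA` when the window has fewer
#'   than 3 samples or a fiducial is missing.
#' @export
feat_st_deviation <- function(signal, beat) {
  stopifnot(inherits(signal, "ecg_signal"))
  if (is.na(beat$offset) || is.na(beat$t)) return(NA_real_)
  ton <- t_onset_sample(signal$samples, beat$offset, beat$t, signal$fs)
  if (ton - beat$offset + 1L < 3L) return(NA_real_)
  stats::sd(signal$samples[beat$offset:ton])
}

#' Slope from QRS onset to offset (feature 6)
#'
#' `(v[offset] - v[onset]) / ((offset - onset) / fs)` in mV/s: the net
#' voltage trend across the QRS complex, which ST depression or elevation
#' tilts away from zero.
#'
#' @inheritParams feat_cumulative_voltage
#' @return slope in mV/s, or `NA` when onset/offset are missing or equal.
#' @export
feat_slope <- function(signal, beat) {
  stopifnot(inherits(signal, "ecg_signal"))
  if (is.na(beat$onset) || is.na(beat$offset) || beat$onset == beat$offset) {
    return(NA_real_)
  }
  v <- signal$samples
  (v[beat$offset] - v[beat$onset]) / ((beat$offset - beat$onset) / signal$fs)
}

#' Extract the six features of one analysis window
#'
#' Rhythm features come from the window's Poincare points; ST-morphology
#' features are averaged over the window's fully delineated beats.  A
#' window with fewer than 2 intervals or no delineated beat is flagged
#' unusable (`usable = FALSE`, features `NA`).
#'
#' @param signal the filtered `ecg_signal` (see [feat_cumulative_voltage()]
#'   for why ST features read the filter-chain output).
#' @param window an `analysis_window` from [make_windows()].
#' @param beats the record's delineated `beat_annotation`.
#' @return a one-row `data.frame`: `window_start`, the six features, and
#'   `usable`.
#' @export
extract_window_features <- function(signal, window, beats) {
  stopifnot(inherits(window, "analysis_window"))
  pts <- poincare(window$ibis)
  bi <- window$beat_rows
  full <- bi[!is.na(beats$onset[bi]) & !is.na(beats$offset[bi]) &
               !is.na(beats$t[bi])]
  out <- data.frame(window_start = window$start_time,
                    step_increment = NA_real_, diag_dispersion = NA_real_,
                    n_clusters = NA_real_, st_area = NA_real_,
                    st_deviation = NA_real_, qrs_slope = NA_real_,
                    usable = FALSE)
  if (length(window$ibis) < 2L || !length(full)) return(out)
  out$step_increment <- feat_stepping(pts)
  out$diag_dispersion <- feat_dispersion(pts)
  out$n_clusters <- as.numeric(feat_clusters(pts))
  st <- vapply(full, function(i) c(
    feat_cumulative_voltage(signal, beats[i, ]),
    feat_st_deviation(signal, beats[i, ]),
    feat_slope(signal, beats[i, ])), numeric(3))
  st <- rowMeans(st, na.rm = TRUE)
  out$st_area <- st[1]; out$st_deviation <- st[2]; out$qrs_slope <- st[3]
  out$usable <- all(is.finite(unlist(out[feature_names()])))
  out
}

#' Extract features for every window of a record
#'
#' Convenience wrapper: windows the record's interbeat intervals and runs
#' [extract_window_features()] on each.
#'
#' @inheritParams extract_window_features
#' @param ibis the record's `ibi_series` (computed from `beats` when
#'   omitted).
#' @return a `data.frame` with one row per window.
#' @export
extract_features <- function(signal, beats, ibis = NULL) {
  stopifnot(inherits(signal, "ecg_signal"))
  if (is.null(ibis)) ibis <- compute_ibis(beats, signal$fs)
  wins <- make_windows(ibis, beats, duration(signal))
  do.call(rbind, lapply(wins, function(w) extract_window_features(signal, w, beats)))
}

#' Fit a min--max feature normalizer
#'
#' Feature ranges differ by orders of magnitude (dimensionless increments
#' vs. mV.s areas), so each feature is mapped to \[0, 1\] by its training
#' range before classification.  A zero-range feature maps to 0.5 with a
#' warning.
#'
#' @param train a feature `data.frame` (only the [feature_names()] columns
#'   are used; non-usable rows dropped).
#' @return an object of class `feature_normalizer` holding per-feature
#'   `min` and `max`.
#' @export
fit_normalizer <- function(train) {
  x <- as.matrix(train[, feature_names(), drop = FALSE])
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 2L) stop("need at least 2 complete feature vectors", call. = FALSE)
  mins <- apply(x, 2, min); maxs <- apply(x, 2, max)
  if (any(maxs == mins)) {
    warning("zero-range feature(s): ",
            paste(feature_names()[maxs == mins], collapse = ", "),
            "; they will map to 0.5")
  }
  structure(list(min = mins, max = maxs), class = "feature_normalizer")
}

#' Apply (or invert) a min--max normalizer
#'
#' Values are scaled by the training range and clipped to \[0, 1\];
#' zero-range features map to 0.5.  `invert = TRUE` maps normalized values
#' back to the raw scale (the round trip is the identity on the training
#' range).
#'
#' @param norm a `feature_normalizer`.
#' @param features feature `data.frame` (or matrix with the feature
#'   columns).
#' @param invert undo the normalization instead (no clipping).
#' @return the `features` object with the six feature columns transformed.
#' @export
apply_normalizer <- function(norm, features, invert = FALSE) {
  stopifnot(inherits(norm, "feature_normalizer"))
  out <- features
  for (f in feature_names()) {
    rng <- norm$max[f] - norm$min[f]
    if (invert) {
      out[[f]] <- if (rng == 0) rep(norm$min[f], nrow(out)) else
        features[[f]] * rng + norm$min[f]
    } else {
      out[[f]] <- if (rng == 0) rep(0.5, nrow(out)) else
        pmin(1, pmax(0, (features[[f]] - norm$min[f]) / rng))
    }
  }
  out
}
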