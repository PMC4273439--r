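#' Protrusion score of a waveform
#'
#' Peak-to-median absolute amplitude ratio: how far the largest excursion
#' protrudes above the waveform's own typical level.  Scale-free, and
#' maximal for impulsive QRS-like content, so it ranks wavelet detail
#' scales by how cleanly they isolate the QRS complexes.
#'
#' @param x numeric vector (non-empty).
#' @param eps denominator guard (default 1e-12).
#' @return non-negative score; 0 for an all-zero input, approximately 1 for
#'   a constant input.
#' @export
protrusion_score <- function(x, eps = 1e-12) {
  x <- abs(as.numeric(x))
  if (!length(x)) stop("`x` must be non-empty", call. = FALSE)
  max(x) / (stats::median(x) + eps)
}

# Equivalent FIR detail filter of the a-trous (stationary) db8 cascade at
# `level`: hi upsampled by 2^(level-1), convolved with the upsampled lo
# filters of the shallower levels.  Normalised so band energy matches the
# decimated transform's.
atrous_detail_filter <- function(level) {
  upsample <- function(f, by) {
    if (by == 1L) return(f)
    u <- numeric((length(f) - 1L) * by + 1L)
    u[seq(1L, length(u), by = by)] <- f
    u
  }
  h <- upsample(DB8_HI, 2L^(level - 1L))
  if (level > 1L) {
    for (l in seq_len(level - 1L)) {
      h <- stats::convolve(h, rev(upsample(DB8_LO, 2L^(l - 1L))), type = "open")
    }
  }
  h / 2^(level / 2)
}

#' Shift-invariant wavelet band of a signal
#'
#' Output of the stationary (undecimated, a-trous) db8 wavelet transform at
#' one detail level: the signal convolved with that level's equivalent
#' band filter, centre-aligned to the input.  Unlike the decimated
#' transform, the result does not depend on how a beat happens to align
#' with the dyadic sampling grid, which makes it the right detection
#' statistic for QRS search.
#'
#' @param signal an `ecg_signal` (or numeric vector).
#' @param level detail level (>= 1).
#' @return same type as the input, band-limited to roughly
#'   `fs/2^(level+1)` .. `fs/2^level` Hz.
#' @export
stationary_band <- function(signal, level) {
  x <- if (inherits(signal, "ecg_signal")) signal$samples else as.numeric(signal)
  h <- atrous_detail_filter(level)
  if (length(h) >= length(x)) {
    stop("signal too short for stationary band at level ", level, call. = FALSE)
  }
  y <- stats::convolve(x, rev(h), type = "open")
  off <- (length(h) - 1L) %/% 2L
  y <- y[(off + 1L):(off + length(x))]
  if (inherits(signal, "ecg_signal")) with_samples(signal, y) else y
}

#' Select the QRS-dominant wavelet scale
#'
#' Computes the stationary wavelet band of every feasible detail level and
#' returns the level whose band has the highest protrusion score.  Levels
#' carrying almost no energy (root-mean-square below 2% of the signal's)
#' are excluded: a nearly empty scale can post an arbitrarily high
#' peak-to-median ratio on residue alone, yet cannot be the QRS carrier.
#'
#' @param signal an `ecg_signal` (preprocessed).
#' @param levels maximum level considered (default 8, reduced for short
#'   records).
#' @return list with `level` (selected detail level), `scores` (per-level
#'   score), and `band` (the selected level's stationary-band
#'   `ecg_signal`).
#' @export
select_qrs_scale <- function(signal, levels = 8L) {
  stopifnot(inherits(signal, "ecg_signal"))
  n <- length(signal$samples)
  J <- max_dwt_levels(n, as.integer(levels))
  while (J > 1L && length(atrous_detail_filter(J)) >= n) J <- J - 1L
  bands <- lapply(seq_len(J), function(j) stationary_band(signal, j))
  total_rms <- sqrt(mean(signal$samples^2))
  scores <- vapply(bands, function(b) {
    if (sqrt(mean(b$samples^2)) < 0.02 * total_rms) 0 else protrusion_score(b$samples)
  }, numeric(1))
  lvl <- which.max(scores)
  list(level = lvl, scores = scores, band = bands[[lvl]])
}

# moving-average smoother, centred, width w samples (odd-ified)
moving_avg <- function(x, w) {
  w <- max(1L, as.integer(w)); if (w %% 2L == 0L) w <- w + 1L
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2)) -> y
  y[is.na(y)] <- 0
  y
}

# contiguous runs of TRUE as a 2-column matrix (start, end)
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect QRS complexes by wavelet scale selection
#'
#' Pipeline: pick the detail scale whose stationary db8 wavelet band has
#' maximal protrusion ([select_qrs_scale()]), square that band, and
#' threshold it adaptively — 30% of the 98th
#' percentile of the squared reconstruction, computed per 10 s block so the
#' threshold tracks amplitude drift.  Each supra-threshold segment yields
#' one candidate; the R peak is refined to the sample of maximum absolute
#' amplitude of the *original* signal within 50 ms of the segment's energy
#' peak.  A 250 ms refractory period (240 bpm ceiling) suppresses double
#' detections, keeping the larger-amplitude candidate (earliest on ties).
#'
#' @param signal a preprocessed `ecg_signal`, at least 2 s long.
#' @param levels wavelet depth (default 8).
#' @param threshold_frac fraction of the per-block 98th percentile used as
#'   detection threshold (default 0.3).
#' @param refractory_s minimum beat spacing in seconds (default 0.25).
#' @param edge_guard_s margin at each record end excluded from detection
#'   (default 0.25 s): the wavelet transform treats the record as circular,
#'   so a start/end level mismatch produces spurious impulsive energy at
#'   the boundaries.
#' @return a `beat_annotation` with `qrs` filled (onset/offset/p/t `NA`;
#'   see [delineate()]); zero rows, with a warning, when nothing is found.
#' @export
detect_qrs <- function(signal, levels = 8L, threshold_frac = 0.3,
                       refractory_s = 0.25, edge_guard_s = 0.25) {
  stopifnot(inherits(signal, "ecg_signal"))
  fs <- signal$fs
  if (duration(signal) < 2) {
    stop("`signal` must be at least 2 s long", call. = FALSE)
  }
  if (all(signal$samples == signal$samples[1])) {
    warning("flat signal: no QRS complexes found")
    return(beat_annotation(integer(0)))
  }
  sel <- select_qrs_scale(signal, levels = levels)
  r <- sel$band$samples
  e <- r^2
  n <- length(e)
  block <- as.integer(round(10 * fs))
  thr <- numeric(n)
  for (a in seq(1L, n, by = block)) {
    b <- min(a + block - 1L, n)
    thr[a:b] <- threshold_frac * stats::quantile(e[a:b], 0.98, names = FALSE)
  }
  mask <- e > thr & thr > 0
  guard <- as.integer(round(edge_guard_s * fs))
  if (guard > 0L && 2L * guard < n) {
    mask[seq_len(guard)] <- FALSE
    mask[(n - guard + 1L):n] <- FALSE
  }
  if (!any(mask)) {
    warning("no QRS complexes found")
    return(beat_annotation(integer(0)))
  }
  runs <- true_runs(mask)
  half <- as.integer(round(0.05 * fs))
  cand <- apply(runs, 1L, function(seg) {
    peak <- seg[1] + which.max(e[seg[1]:seg[2]]) - 1L
    a <- max(1L, peak - half); b <- min(n, peak + half)
    a + which.max(abs(signal$samples[a:b])) - 1L
  })
  cand <- sort(unique(cand))
  amp <- abs(signal$samples[cand])
  # refractory: greedy by amplitude, earliest wins ties
  ord <- order(-amp, cand)
  keep <- logical(length(cand))
  taken <- rep(FALSE, length(cand))
  refr <- refractory_s * fs
  for (i in ord) {
    if (taken[i]) next
    keep[i] <- TRUE
    taken[abs(cand - cand[i]) < refr] <- TRUE
  }
  qrs <- sort(cand[keep])
  ann <- beat_annotation(qrs, n_samples = n)
  attr(ann, "scale_level") <- sel$level
  attr(ann, "scale_scores") <- sel$scores
  ann
}

#' Delineate detected beats: QRS onset/offset, T peak, P presence
#'
#' Works from the envelope (25 ms moving average of the absolute value) of
#' the selected scale's stationary wavelet band.  The QRS onset is the last sample
#' before the R peak, within a 100 ms search window, where the envelope
#' falls below a fraction `env_frac[1]` (default 5%) of its per-beat
#' maximum; the offset is found the same way after the peak at
#' `env_frac[2]` (default 25%).  The thresholds differ because the QRS
#' energy envelope is asymmetric: the leading (Q) deflection is small and
#' decays quickly, while the trailing (S) deflection keeps the envelope
#' high well past the R peak.  The T peak is the maximum of a 20 ms
#' smoothed copy of the signal between `offset + 40 ms` and
#' `offset + 400 ms`, clipped at the next beat's onset.  A P wave is marked
#' present when the smoothed amplitude in `(onset - 250 ms, onset - 50 ms)`
#' exceeds `p_min_mv`.  Fiducials whose search window is truncated by a
#' record edge are left `NA`.
#'
#' @param signal the preprocessed `ecg_signal` used for detection.
#' @param beats a `beat_annotation` from [detect_qrs()].
#' @param p_min_mv P-wave detection threshold in mV (default 0.05).
#' @param env_frac length-2 envelope fractions defining the QRS onset and
#'   offset boundaries (default `c(0.05, 0.25)`).
#' @return the `beat_annotation` with `onset`, `offset`, `t`, `p` filled.
#' @export
delineate <- function(signal, beats, p_min_mv = 0.05,
                      env_frac = c(0.05, 0.25)) {
  env_frac <- rep_len(env_frac, 2L)
  stopifnot(inherits(signal, "ecg_signal"), inherits(beats, "beat_annotation"))
  if (!nrow(beats)) return(beats)
  fs <- signal$fs
  n <- length(signal$samples)
  lvl <- attr(beats, "scale_level")
  if (is.null(lvl)) {
    sel <- select_qrs_scale(signal)
    lvl <- sel$level
    r <- sel$band$samples
  } else {
    r <- stationary_band(signal, lvl)$samples
  }
  env <- moving_avg(abs(r), round(0.025 * fs))
  smoo <- moving_avg(signal$samples, round(0.02 * fs))
  w100 <- as.integer(round(0.10 * fs))
  w50 <- as.integer(round(0.05 * fs))
  qrs <- beats$qrs
  onset <- offset <- tpk <- ppk <- rep(NA_integer_, length(qrs))
  for (i in seq_along(qrs)) {
    q <- qrs[i]
    bmax <- max(env[max(1L, q - w50):min(n, q + w50)])
    lo <- q - w100
    if (lo >= 1L) {
      idx <- lo:(q - 1L)
      below <- idx[env[idx] < env_frac[1] * bmax]
      onset[i] <- if (length(below)) max(below) else lo
    }
    hi <- q + w100
    if (hi <= n) {
      idx <- (q + 1L):hi
      below <- idx[env[idx] < env_frac[2] * bmax]
      offset[i] <- if (length(below)) min(below) else hi
    }
    if (!is.na(offset[i])) {
      ta <- offset[i] + as.integer(round(0.04 * fs))
      tb <- offset[i] + as.integer(round(0.40 * fs))
      if (i < length(qrs) && !is.na(qrs[i + 1L])) {
        nxt_on <- qrs[i + 1L] - w100
        tb <- min(tb, nxt_on - 1L)
      }
      if (tb <= n && tb > ta) {
        tpk[i] <- ta + which.max(smoo[ta:tb]) - 1L
      }
    }
    if (!is.na(onset[i])) {
      pa <- onset[i] - as.integer(round(0.25 * fs))
      pb <- onset[i] - as.integer(round(0.05 * fs))
      if (pa >= 1L && pb > pa) {
        pk <- pa + which.max(smoo[pa:pb]) - 1L
        if (smoo[pk] >= p_min_mv) ppk[i] <- pk
      }
    }
  }
  out <- beat_annotation(qrs, onset = onset, offset = offset, p = ppk,
                         t = tpk, n_samples = n)
  attr(out, "scale_level") <- lvl
  out
}

#' Interbeat intervals from detected beats
#'
#' Interval `i` is the time between QRS peaks `i` and `i + 1`:
#' `(qrs[i+1] - qrs[i]) / fs` seconds, anchored at the closing beat.
#'
#' @param beats a `beat_annotation`.
#' @param fs sampling rate of the record (Hz).
#' @return an `ibi_series` (empty when fewer than 2 beats).
#' @export
compute_ibis <- function(beats, fs) {
  stopifnot(inherits(beats, "beat_annotation"))
  if (nrow(beats) < 2L) {
    return(ibi_series(numeric(0), integer(0), fs))
  }
  ibi_series(diff(beats$qrs) / fs, anchors = beats$qrs[-1L], fs = fs)
}
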