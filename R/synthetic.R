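# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so generators are reproducible without clobbering the
# session stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Default beat template: five Gaussian bumps placed relative to the R peak.
# amplitude (mV), center offset from R (s), width sigma (s).
default_beat_template <- function() {
  data.frame(
    wave   = c("p", "q", "r", "s", "t"),
    amp    = c(0.15, -0.10, 1.00, -0.20, 0.30),
    center = c(-0.20, -0.03, 0.00, 0.03, 0.25),
    width  = c(0.025, 0.010, 0.010, 0.010, 0.040)
  )
}

#' Describe a rhythm for the synthetic generator
#'
#' @param kind `"normal"`, `"afib"`, or `"ischemia"`.
#' @param mean_rr mean interbeat interval in seconds (> 0.25); ignored for
#'   `"afib"`, whose intervals are drawn uniformly on \[0.35, 1.2\] s.
#' @param rr_jitter coefficient of variation of the RR interval for the
#'   sinus-rhythm classes (Gaussian, truncated at 3 standard deviations).
#'   Default 0.03, a typical resting short-term heart-rate variability.
#' @param st_offset ST-segment shift in mV (ischemia only; positive =
#'   elevation).  Default 0.2 mV for `"ischemia"`, 0 otherwise.
#' @param p_amplitude P-wave amplitude in mV; forced to 0 for `"afib"`
#'   (atrial fibrillation abolishes the organised P wave).
#' @return an object of class `rhythm_spec`.
#' @export
rhythm_spec <- function(kind = c("normal", "afib", "ischemia"),
                        mean_rr = 0.8, rr_jitter = 0.03,
                        st_offset = if (kind == "ischemia") 0.2 else 0,
                        p_amplitude = 0.15) {
  kind <- match.arg(kind)
  if (mean_rr <= 0.25) stop("`mean_rr` must exceed 0.25 s", call. = FALSE)
  if (rr_jitter < 0) stop("`rr_jitter` must be non-negative", call. = FALSE)
  if (kind == "afib") p_amplitude <- 0
  structure(list(kind = kind, mean_rr = mean_rr, rr_jitter = rr_jitter,
                 st_offset = st_offset, p_amplitude = p_amplitude),
            class = "rhythm_spec")
}

draw_rr <- function(spec, n) {
  if (spec$kind == "afib") {
    # independent, strongly irregular, P-free: uniform over the
    # physiological AF range
    stats::runif(n, 0.35, 1.2)
  } else {
    sd <- spec$rr_jitter * spec$mean_rr
    rr <- stats::rnorm(n, spec$mean_rr, sd)
    pmax(pmin(rr, spec$mean_rr + 3 * sd), pmax(spec$mean_rr - 3 * sd, 0.26))
  }
}

# Plateau of height 1 over [a, b] with raised-cosine ramps of length r
# *outside* the interval, so the full offset holds on all of [a, b].  Slow
# ramps (40 ms) emulate the smooth J-point take-off of real ST deviation
# and keep the transition's energy well below the QRS band.
st_plateau <- function(t, a, b, r = 0.04) {
  y <- numeric(length(t))
  y[t >= a & t <= b] <- 1
  up <- t >= a - r & t < a
  y[up] <- 0.5 * (1 - cos(pi * (t[up] - (a - r)) / r))
  dn <- t > b & t <= b + r
  y[dn] <- 0.5 * (1 + cos(pi * (t[dn] - b) / r))
  y
}

#' Generate a synthetic ECG record with ground-truth annotations
#'
#' Each beat is a sum of five Gaussian bumps (P, Q, R, S, T) placed relative
#' to the R peak; the RR sequence is drawn per rhythm class (see
#' [rhythm_spec()]).  For the ischemia class the segment between the QRS
#' offset and the T-wave onset is shifted by `st_offset` mV (raised-cosine
#' edges, so no spectral splatter).  The generator is a test harness
#' emulating textbook morphology, not a physiological simulator.
#'
#' Ground truth per beat: QRS onset/offset at R -/+ 60 ms (where the
#' template's QRS energy has decayed), P and T at their bump centers.
#'
#' @param spec a [rhythm_spec()].
#' @param fs sampling rate (Hz), default 1000.
#' @param duration record length in seconds; must cover at least two beats.
#' @param seed integer seed; the generator is bit-reproducible given a seed.
#' @param template beat template data frame (see source for the default).
#' @return a list with elements `signal` (`ecg_signal`), `beats`
#'   (`beat_annotation` of every fully contained beat) and `ibis`
#'   (`ibi_series` of the true RR intervals).
#' @examples
#' rec <- generate_ecg(rhythm_spec("normal", rr_jitter = 0), duration = 10, seed = 1)
#' rec$signal
#' @export
generate_ecg <- function(spec, fs = 1000, duration = 60, seed = NULL,
                         template = default_beat_template()) {
  stopifnot(inherits(spec, "rhythm_spec"))
  if (duration < 2 * spec$mean_rr) {
    stop("`duration` must cover at least two mean beats", call. = FALSE)
  }
  with_seed(seed, {
    n <- round(duration * fs)
    tgrid <- (seq_len(n) - 1) / fs
    # beat times: cumulative RR, starting half an interval in
    rr <- draw_rr(spec, ceiling(duration / 0.26) + 8L)
    r_times <- 0.4 + cumsum(c(0, rr))
    # keep beats whose full template (P through T) fits inside the record
    lead_in <- 0.30   # P center 0.20 s + 3 sigma margin
    tail_out <- 0.40  # T center 0.25 s + width margin
    keep <- r_times >= lead_in & r_times <= duration - tail_out
    r_times <- r_times[keep]
    if (length(r_times) < 2L) {
      stop("`duration` too short to place two beats", call. = FALSE)
    }
    tpl <- template
    tpl$amp[tpl$wave == "p"] <- spec$p_amplitude
    x <- numeric(n)
    for (rt in r_times) {
      for (k in seq_len(nrow(tpl))) {
        if (tpl$amp[k] == 0) next
        c0 <- rt + tpl$center[k]
        span <- which(tgrid >= c0 - 5 * tpl$width[k] & tgrid <= c0 + 5 * tpl$width[k])
        x[span] <- x[span] +
          tpl$amp[k] * exp(-(tgrid[span] - c0)^2 / (2 * tpl$width[k]^2))
      }
      if (spec$kind == "ischemia" && spec$st_offset != 0) {
        t_c <- tpl$center[tpl$wave == "t"]; t_w <- tpl$width[tpl$wave == "t"]
        x <- x + spec$st_offset * st_plateau(tgrid, rt + 0.06, rt + t_c - t_w)
      }
    }
    r_idx <- round(r_times * fs) + 1L
    t_c <- tpl$center[tpl$wave == "t"]
    p_c <- tpl$center[tpl$wave == "p"]
    beats <- beat_annotation(
      qrs = r_idx,
      onset = r_idx - round(0.06 * fs),
      offset = r_idx + round(0.06 * fs),
      p = if (spec$p_amplitude > 0) r_idx + round(p_c * fs) else NA_integer_,
      t = r_idx + round(t_c * fs),
      n_samples = n
    )
    ibis <- ibi_series(diff(r_times), anchors = r_idx[-1L], fs = fs)
    # AC-couple the output, as a real front-end does: a train of positive
    # bumps otherwise carries a DC pedestal no recorded ECG has
    x <- x - mean(x)
    list(signal = ecg_signal(x, fs = fs, lead = "synthetic"),
         beats = beats, ibis = ibis)
  })
}

#' Generate one of the three noise-stress noise types
#'
#' Emulations of the MIT-BIH Noise Stress Test noise classes:
#' * `"bw"` (baseline wander): a sum of five sinusoids with random
#'   frequencies below 0.45 Hz, amplitudes and phases — respiration-band
#'   drift.
#' * `"ma"` (muscle artifact): broadband Gaussian noise band-passed to
#'   5--100 Hz (upper edge clipped below Nyquist).
#' * `"em"` (electrode motion): intermittent low-frequency transients —
#'   Hann-windowed random-walk bursts covering roughly a fifth of the
#'   record.
#'
#' All outputs are zero-mean; absolute scale is irrelevant because
#' [mix_at_snr()] rescales exactly.
#'
#' @param kind `"bw"`, `"ma"`, or `"em"`.
#' @param fs sampling rate (Hz).
#' @param n_samples number of samples (>= 1).
#' @param seed integer seed (bit-reproducible).
#' @return numeric vector of length `n_samples`.
#' @export
generate_noise <- function(kind = c("bw", "ma", "em"), fs, n_samples,
                           seed = NULL) {
  kind <- match.arg(kind)
  if (n_samples < 1L) stop("`n_samples` must be >= 1", call. = FALSE)
  with_seed(seed, {
    t <- (seq_len(n_samples) - 1) / fs
    x <- switch(kind,
      bw = {
        f <- stats::runif(5, 0.05, 0.45)
        a <- stats::runif(5, 0.5, 1.0)
        ph <- stats::runif(5, 0, 2 * pi)
        rowSums(vapply(1:5, function(k) a[k] * sin(2 * pi * f[k] * t + ph[k]),
                       numeric(n_samples)))
      },
      ma = {
        hi <- min(100, 0.45 * fs)
        bp <- signal::butter(4, c(5, hi) / (fs / 2), type = "pass")
        as.numeric(signal::filtfilt(bp$b, bp$a, stats::rnorm(n_samples)))
      },
      em = {
        y <- numeric(n_samples)
        pos <- 1L
        while (pos < n_samples) {
          gap <- round(stats::runif(1, 2, 6) * fs)
          blen <- round(stats::runif(1, 0.5, 2) * fs)
          a <- pos + gap
          b <- min(a + blen - 1L, n_samples)
          if (a >= n_samples) break
          len <- b - a + 1L
          if (len >= 8L) {
            burst <- cumsum(stats::rnorm(len)) / sqrt(len)
            w <- 0.5 * (1 - cos(2 * pi * (seq_len(len) - 1) / (len - 1)))
            y[a:b] <- y[a:b] + burst * w
          }
          pos <- b + 1L
        }
        if (all(y == 0)) {
          # record shorter than the first inter-burst gap: single burst
          len <- n_samples
          burst <- cumsum(stats::rnorm(len)) / sqrt(max(len, 1))
          w <- if (len > 1) 0.5 * (1 - cos(2 * pi * (seq_len(len) - 1) / (len - 1))) else 1
          y <- burst * w
        }
        y
      })
    x - mean(x)
  })
}

#' Mix noise into a clean signal at an exact target SNR
#'
#' Rescales `noise` so that `10 * log10(P_signal / P_noise)` equals
#' `snr_db` exactly (P = mean squared amplitude) and adds it to the clean
#' signal.
#'
#' @param clean an `ecg_signal`.
#' @param noise numeric vector, same length as the signal.
#' @param snr_db target signal-to-noise ratio in dB.
#' @return the noisy `ecg_signal`.
#' @export
mix_at_snr <- function(clean, noise, snr_db) {
  stopifnot(inherits(clean, "ecg_signal"))
  noise <- as.numeric(noise)
  if (length(noise) != length(clean$samples)) {
    stop("`clean` and `noise` must have equal length", call. = FALSE)
  }
  p_sig <- mean(clean$samples^2)
  p_noi <- mean(noise^2)
  if (p_sig == 0 || p_noi == 0) {
    stop("zero-power signal or noise cannot be mixed at a target SNR",
         call. = FALSE)
  }
  alpha <- sqrt(p_sig / (p_noi * 10^(snr_db / 10)))
  with_samples(clean, clean$samples + alpha * noise)
}

#' Signal-to-noise ratio of a test signal against a reference
#'
#' `10 * log10( sum(ref^2) / sum((test - ref)^2) )` in dB.  Identical
#' signals return `+Inf` (no residual error).
#'
#' @param reference,test `ecg_signal`s (or bare numeric vectors) of equal
#'   length.
#' @return SNR in dB (possibly `Inf`).
#' @export
snr_db <- function(reference, test) {
  r <- if (inherits(reference, "ecg_signal")) reference$samples else as.numeric(reference)
  s <- if (inherits(test, "ecg_signal")) test$samples else as.numeric(test)
  if (length(r) != length(s)) {
    stop("`reference` and `test` must have equal length", call. = FALSE)
  }
  err <- sum((s - r)^2)
  if (err == 0) return(Inf)
  10 * log10(sum(r^2) / err)
}
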