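#' Design the ECG digital filter chain
#'
#' The chain a portable single-lead monitor applies in software: a 0.05 Hz
#' Butterworth highpass (electrode offset / drift rejection), a mains notch
#' (60 Hz by default, 50 Hz selectable), and a 40 Hz Butterworth lowpass
#' (muscle artifact and residual interference).  All three are IIR sections
#' in transfer-function form.
#'
#' Orders: highpass order 2 and lowpass order 6 by default.  Order 6 keeps
#' the passband within 1 dB of unity up to 35 Hz while still attenuating
#' strongly above the cutoff; lower lowpass orders sag noticeably below
#' 35 Hz, which distorts QRS amplitudes.
#'
#' @param fs sampling rate in Hz; must exceed twice the lowpass cutoff and
#'   the notch frequency.
#' @param hp_cutoff highpass cutoff (Hz), default 0.05.
#' @param notch_freq mains frequency to reject (Hz), default 60.
#' @param lp_cutoff lowpass cutoff (Hz), default 40.
#' @param hp_order,lp_order Butterworth orders (defaults 2 and 6).
#' @param notch_q notch quality factor, default 30 (bandwidth
#'   `notch_freq / notch_q`).
#' @return an object of class `filter_bank`: three `list(b=, a=)` sections
#'   (`hp`, `notch`, `lp`) plus the design parameters.
#' @examples
#' bank <- design_filter_bank(1000)
#' filter_bank_response(bank, c(0.05, 10, 60))
#' @export
design_filter_bank <- function(fs, hp_cutoff = 0.05, notch_freq = 60,
                               lp_cutoff = 40, hp_order = 2L, lp_order = 6L,
                               notch_q = 30) {
  nyq <- fs / 2
  if (!(hp_cutoff > 0 && hp_cutoff < lp_cutoff && lp_cutoff < nyq)) {
    stop("cutoffs must satisfy 0 < hp_cutoff < lp_cutoff < fs/2", call. = FALSE)
  }
  if (notch_freq >= nyq) {
    stop("notch frequency must lie below the Nyquist frequency", call. = FALSE)
  }
  hp <- signal::butter(hp_order, hp_cutoff / nyq, type = "high")
  lp <- signal::butter(lp_order, lp_cutoff / nyq, type = "low")
  nt <- design_notch(notch_freq, fs, notch_q)
  bank <- structure(
    list(hp = list(b = hp$b, a = hp$a),
         notch = nt,
         lp = list(b = lp$b, a = lp$a),
         fs = fs, hp_cutoff = hp_cutoff, notch_freq = notch_freq,
         lp_cutoff = lp_cutoff, hp_order = as.integer(hp_order),
         lp_order = as.integer(lp_order), notch_q = notch_q),
    class = "filter_bank")
  for (s in c("hp", "notch", "lp")) {
    if (any(Mod(polyroot(rev(bank[[s]]$a))) >= 1)) {
      stop("designed ", s, " section is unstable at fs = ", fs, call. = FALSE)
    }
  }
  bank
}

# Second-order IIR notch (constrained pole-zero placement): unit-circle
# zeros at +/- the mains frequency, poles pulled inward by the -3 dB
# bandwidth w0/Q.
design_notch <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  beta <- tan(w0 / (2 * q))
  gain <- 1 / (1 + beta)
  list(b = gain * c(1, -2 * cos(w0), 1),
       a = c(1, -2 * gain * cos(w0), 2 * gain - 1))
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf(
    "<filter_bank> fs=%g Hz: HP %g Hz (order %d) -> notch %g Hz (Q=%g) -> LP %g Hz (order %d)\n",
    x$fs, x$hp_cutoff, x$hp_order, x$notch_freq, x$notch_q,
    x$lp_cutoff, x$lp_order))
  invisible(x)
}

#' Single-pass frequency response of the filter cascade
#'
#' Evaluates `|H_hp(f) H_notch(f) H_lp(f)|` at the requested frequencies.
#'
#' @param bank a `filter_bank`.
#' @param freqs frequencies in Hz.
#' @param dB return magnitude in decibels (default) or linear.
#' @return numeric vector of magnitudes.
#' @export
filter_bank_response <- function(bank, freqs, dB = TRUE) {
  stopifnot(inherits(bank, "filter_bank"))
  w <- 2 * pi * freqs / bank$fs
  h <- rep(1 + 0i, length(w))
  for (s in c("hp", "notch", "lp")) {
    b <- bank[[s]]$b; a <- bank[[s]]$a
    z <- exp(-1i * w)
    num <- Reduce(function(acc, k) acc * z + b[k], seq_along(b)[-1],
                  init = rep(b[1] + 0i, length(z)))
    den <- Reduce(function(acc, k) acc * z + a[k], seq_along(a)[-1],
                  init = rep(a[1] + 0i, length(z)))
    h <- h * num / den
  }
  mag <- Mod(h)
  if (dB) 20 * log10(mag) else mag
}

#' Apply the filter chain to a signal
#'
#' Runs the cascade highpass -> notch -> lowpass.  `zero_phase` (the
#' default, for offline analysis) applies each section forward and backward
#' so the output has no group delay; `causal` is the single-pass streaming
#' variant a real-time device would run.
#'
#' @param signal an `ecg_signal`.
#' @param bank a `filter_bank` designed at the signal's sampling rate
#'   (designed on the fly from defaults when omitted).
#' @param mode `"zero_phase"` or `"causal"`.
#' @return the filtered `ecg_signal`.
#' @export
apply_filter_bank <- function(signal, bank = NULL,
                              mode = c("zero_phase", "causal")) {
  stopifnot(inherits(signal, "ecg_signal"))
  mode <- match.arg(mode)
  if (is.null(bank)) bank <- design_filter_bank(signal$fs)
  if (!isTRUE(all.equal(bank$fs, signal$fs))) {
    stop("filter bank was designed for fs = ", bank$fs,
         " but signal has fs = ", signal$fs, call. = FALSE)
  }
  longest <- max(length(bank$hp$a), length(bank$notch$a), length(bank$lp$a)) - 1L
  if (length(signal$samples) <= 3L * longest) {
    stop("signal too short to filter (need > 3x the longest filter order)",
         call. = FALSE)
  }
  x <- signal$samples
  for (s in c("hp", "notch", "lp")) {
    b <- bank[[s]]$b; a <- bank[[s]]$a
    x <- if (mode == "zero_phase") {
      as.numeric(signal::filtfilt(b, a, x))
    } else {
      as.numeric(signal::filter(b, a, x))
    }
  }
  with_samples(signal, x)
}

#' Full preprocessing chain: filter cascade plus baseline removal
#'
#' Convenience wrapper running [apply_filter_bank()] followed by
#' [remove_baseline()]; this is the preprocessing every downstream stage
#' (QRS detection, feature extraction) assumes.
#'
#' @inheritParams apply_filter_bank
#' @param levels wavelet depth for baseline removal.
#' @return the preprocessed `ecg_signal`.
#' @export
preprocess <- function(signal, bank = NULL, mode = c("zero_phase", "causal"),
                       levels = 8L) {
  remove_baseline(apply_filter_bank(signal, bank, mode), levels = levels)
}
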