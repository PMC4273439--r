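#' Construct an ECG signal object
#'
#' An `ecg_signal` is a uniformly sampled single-lead voltage trace.  It is
#' the object every pipeline stage consumes and returns: the synthetic
#' generator produces one, the filter chain and baseline remover transform
#' it, and the QRS detector reads fiducials off it.
#'
#' Conventions used throughout the package: voltages are millivolts, times
#' are seconds, sample indices are 1-based (sample `i` occurs at time
#' `t0 + (i - 1)/fs`).
#'
#' @param samples numeric vector of voltages (mV); must be finite, length >= 1.
#' @param fs sampling rate in Hz, > 0.
#' @param lead lead label (free text, default `"I"`).
#' @param t0 start time of the first sample in seconds (default 0).
#' @return an object of class `ecg_signal` with fields `samples`, `fs`,
#'   `lead`, `t0`.
#' @examples
#' sig <- ecg_signal(sin(2 * pi * 1 * seq(0, 1, by = 1/250)), fs = 250)
#' duration(sig)
#' @export
ecg_signal <- function(samples, fs, lead = "I", t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("`samples` must contain at least one sample", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("`samples` must be finite", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  structure(
    list(samples = samples, fs = as.numeric(fs),
         lead = as.character(lead)[1L], t0 = as.numeric(t0)[1L]),
    class = "ecg_signal"
  )
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> lead %s: %d samples @ %g Hz (%.3f s), range [%.3f, %.3f] mV\n",
              x$lead, length(x$samples), x$fs, duration(x),
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.ecg_signal <- function(x) length(x$samples)

#' Duration of an ECG signal in seconds
#' @param x an `ecg_signal`.
#' @return length of the record in seconds (`n / fs`).
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "ecg_signal"))
  length(x$samples) / x$fs
}

#' Sample times of an ECG signal
#' @param x an `ecg_signal`.
#' @return numeric vector of times (s), one per sample.
#' @export
sample_times <- function(x) {
  stopifnot(inherits(x, "ecg_signal"))
  x$t0 + (seq_along(x$samples) - 1) / x$fs
}

# Replace the samples of a signal, keeping metadata.  Internal.
with_samples <- function(x, samples) {
  ecg_signal(samples, fs = x$fs, lead = x$lead, t0 = x$t0)
}

#' Construct a beat annotation table
#'
#' Per-beat fiducials in 1-based sample coordinates.  `onset` and `offset`
#' bracket the QRS complex, `qrs` is the R-peak sample, `p` and `t` are the
#' P-wave and T-wave peaks (NA when absent or undetectable, e.g. truncated
#' at a record edge or a P wave suppressed by atrial fibrillation).
#'
#' @param qrs integer vector of R-peak sample indices (strictly increasing).
#' @param onset,offset QRS onset/offset sample indices (NA allowed).
#' @param p,t optional P-peak and T-peak sample indices (NA allowed).
#' @param n_samples optional signal length for bounds checking.
#' @return a `data.frame` of class `beat_annotation` with columns
#'   `onset`, `qrs`, `offset`, `p`, `t`.
#' @export
beat_annotation <- function(qrs, onset = NA_integer_, offset = NA_integer_,
                            p = NA_integer_, t = NA_integer_,
                            n_samples = NULL) {
  qrs <- as.integer(round(qrs))
  nb <- length(qrs)
  rec <- function(v) {
    v <- as.integer(round(v))
    rep_len(v, nb)
  }
  ann <- data.frame(onset = rec(onset), qrs = qrs, offset = rec(offset),
                    p = rec(p), t = rec(t))
  if (nb > 1L && any(diff(qrs) <= 0L)) {
    stop("`qrs` indices must be strictly increasing", call. = FALSE)
  }
  ok <- function(cond) all(cond, na.rm = TRUE)
  if (!ok(ann$onset < ann$qrs) || !ok(ann$qrs < ann$offset)) {
    stop("beat fiducials must satisfy onset < qrs < offset", call. = FALSE)
  }
  if (!ok(ann$p < ann$onset) || !ok(ann$t > ann$offset)) {
    stop("P must precede onset and T must follow offset", call. = FALSE)
  }
  if (!is.null(n_samples)) {
    idx <- unlist(ann, use.names = FALSE)
    if (!ok(idx >= 1L & idx <= n_samples)) {
      stop("annotation indices out of signal bounds", call. = FALSE)
    }
  }
  class(ann) <- c("beat_annotation", "data.frame")
  ann
}

#' Construct an interbeat-interval series
#'
#' The RR (interbeat) interval series: interval `i` is the time between
#' QRS peak `i` and QRS peak `i + 1`.  `anchors` holds the sample index of
#' the beat that *ends* each interval, so an interval can be assigned to the
#' analysis window containing its closing beat.
#'
#' @param intervals numeric vector of intervals in seconds, all > 0.
#' @param anchors integer vector of closing-beat sample indices (same length).
#' @param fs sampling rate the anchors refer to (Hz).
#' @return an object of class `ibi_series`.
#' @export
ibi_series <- function(intervals, anchors, fs) {
  intervals <- as.numeric(intervals)
  anchors <- as.integer(round(anchors))
  if (length(intervals) != length(anchors)) {
    stop("`intervals` and `anchors` must have equal length", call. = FALSE)
  }
  if (length(intervals) && any(!is.finite(intervals) | intervals <= 0)) {
    stop("all interbeat intervals must be positive and finite", call. = FALSE)
  }
  structure(list(intervals = intervals, anchors = anchors, fs = as.numeric(fs)),
            class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("<ibi_series> %d intervals, mean %.3f s (%.1f bpm)\n",
              length(x$intervals), mean(x$intervals), 60 / mean(x$intervals)))
  invisible(x)
}

#' @export
length.ibi_series <- function(x) length(x$intervals)

#' The three window classes the classifier distinguishes
#'
#' @return character vector `c("normal", "afib", "ischemia")`.
#' @export
class_labels <- function() c("normal", "afib", "ischemia")

as_class_label <- function(x) {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% class_labels())
  if (any(bad)) {
    stop("unknown class label(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  factor(x, levels = class_labels())
}
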