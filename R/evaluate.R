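#' SNR before/after filtering over noise types and input levels
#'
#' For every combination of noise type, input SNR level, and seed: mix the
#' noise into the clean signal at exactly the requested SNR, run the full
#' preprocessing chain (filter cascade plus wavelet baseline removal), and
#' measure the output SNR of the result against the clean signal, with the
#' first and last second excluded so filter edge transients do not count.
#' The improvement is `snr_out - snr_in`.
#'
#' Denoising improvements shrink as the input gets cleaner: at low input
#' SNR the removable out-of-band noise dominates the error, while at high
#' input SNR the chain's own passband distortion becomes the floor.
#'
#' @param clean a clean `ecg_signal`, at least 30 s long.
#' @param kinds noise types (default all three).
#' @param snr_levels input SNR levels in dB (default `c(6, 10, 14)`).
#' @param seeds integer vector of noise seeds (one run per seed).
#' @param trim_s seconds trimmed from each end before SNR measurement
#'   (default 1).
#' @return a `data.frame` with columns `noise_kind`, `snr_in`, `seed`,
#'   `snr_out`, `improvement`.
#' @export
snr_experiment <- function(clean, kinds = c("bw", "em", "ma"),
                           snr_levels = c(6, 10, 14), seeds = 1:10,
                           trim_s = 1) {
  stopifnot(inherits(clean, "ecg_signal"))
  if (duration(clean) < 30) stop("`clean` must be at least 30 s", call. = FALSE)
  fs <- clean$fs
  n <- length(clean$samples)
  core <- (round(trim_s * fs) + 1L):(n - round(trim_s * fs))
  ref <- clean$samples[core]
  grid <- expand.grid(seed = seeds, snr_in = snr_levels, noise_kind = kinds,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    noise <- generate_noise(g$noise_kind, fs, n, seed = g$seed)
    noisy <- mix_at_snr(clean, noise, g$snr_in)
    out <- preprocess(noisy)
    snr_out <- snr_db(ref, out$samples[core])
    data.frame(noise_kind = g$noise_kind, snr_in = g$snr_in, seed = g$seed,
               snr_out = snr_out, improvement = snr_out - g$snr_in)
  })
  do.call(rbind, rows)
}

#' Summarise an SNR experiment per noise type and input level
#'
#' @param rows output of [snr_experiment()].
#' @return a `data.frame` with per-(noise, level) mean output SNR and mean
#'   improvement, plus per-noise and overall means as attributes
#'   `by_kind` and `overall`.
#' @export
summarise_snr <- function(rows) {
  agg <- stats::aggregate(cbind(snr_out, improvement) ~ noise_kind + snr_in,
                          data = rows, FUN = mean)
  agg <- agg[order(agg$noise_kind, agg$snr_in), ]
  rownames(agg) <- NULL
  attr(agg, "by_kind") <- stats::aggregate(improvement ~ noise_kind,
                                           data = rows, FUN = mean)
  attr(agg, "overall") <- mean(rows$improvement)
  agg
}

#' Spectral-shape distance between two signals (periodogram RMSE)
#'
#' Periodogram PSD of each signal (truncated to the shorter length so the
#' frequency grids match), each normalized to unit total power, then the
#' root-mean-square error across the shared grid.  Unit-power
#' normalization makes this a measure of spectral shape, insensitive to
#' overall amplitude.  Identical signals give 0; the metric is symmetric.
#'
#' @param a,b `ecg_signal`s with equal sampling rates.
#' @return non-negative RMSE between the normalized PSDs.
#' @export
psd_rmse <- function(a, b) {
  stopifnot(inherits(a, "ecg_signal"), inherits(b, "ecg_signal"))
  if (!isTRUE(all.equal(a$fs, b$fs))) {
    stop("`a` and `b` must share a sampling rate", call. = FALSE)
  }
  n <- min(length(a$samples), length(b$samples))
  pg <- function(x) {
    sp <- stats::spec.pgram(stats::ts(x[seq_len(n)], frequency = a$fs),
                            taper = 0, detrend = FALSE, plot = FALSE)
    sp$spec / sum(sp$spec)
  }
  pa <- pg(a$samples); pb <- pg(b$samples)
  sqrt(mean((pa - pb)^2))
}

#' End-to-end evaluation of a classifier on labeled records
#'
#' Runs [classify_record()] on each record, pools the window-level
#' confusion counts under the positive-equals-normal convention, and
#' returns the counts with sensitivity/specificity.  Records without a
#' label are skipped with a warning.
#'
#' @param records list of `list(signal = <ecg_signal>, label = <class>)`.
#' @param model a trained `ecg_classifier`.
#' @return list with `counts` (`confusion_counts`), `metrics`
#'   (sensitivity/specificity), and `per_record` summary `data.frame`.
#' @export
evaluate_pipeline <- function(records, model) {
  truth_all <- character(0)
  pred_all <- character(0)
  per <- list()
  for (i in seq_along(records)) {
    rec <- records[[i]]
    if (is.null(rec$label) || is.na(rec$label)) {
      warning("record ", i, " has no label; skipped")
      next
    }
    res <- classify_record(rec$signal, model)
    lab <- as.character(res$windows$label)
    ok <- !is.na(lab)
    truth_all <- c(truth_all, rep(as.character(rec$label), sum(ok)))
    pred_all <- c(pred_all, lab[ok])
    per[[length(per) + 1L]] <- data.frame(
      record = i, label = as.character(rec$label),
      n_windows = sum(ok),
      agreement = mean(lab[ok] == as.character(rec$label)))
  }
  counts <- count_confusion(truth_all, pred_all)
  list(counts = counts, metrics = confusion_metrics(counts),
       per_record = do.call(rbind, per))
}
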