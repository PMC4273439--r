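# Daubechies-8 analysis filters (orthonormal, 16 taps).  The standard
# published coefficients; the synthesis filters are their adjoints, so only
# the analysis pair is stored.
DB8_LO <- c(
  -1.1747678412476953e-04,  6.7544940645056930e-04, -3.9174037337694705e-04,
  -4.8703529934515740e-03,  8.7460940474057770e-03,  1.3981027917398282e-02,
  -4.4088253930794755e-02, -1.7369301001807547e-02,  1.2874742662047847e-01,
   4.7248457391328280e-04, -2.8401554296154690e-01, -1.5829105256349306e-02,
   5.8535468365420670e-01,  6.7563073629728980e-01,  3.1287159091429995e-01,
   5.4415842243104010e-02)
# Quadrature mirror: hi[k] = (-1)^k lo[L-1-k]
DB8_HI <- rev(DB8_LO) * rep_len(c(-1, 1), length(DB8_LO))

# One periodized analysis step.  x must have even length n >= 16.
# ca[i] = sum_k lo[k] x[(2(i-1) + k - 1) mod n + 1]; the transform matrix is
# orthogonal (rows are even circular shifts of the orthonormal filter pair),
# so the synthesis step below is its exact adjoint/inverse.
dwt_step <- function(x) {
  n <- length(x)
  m <- n %/% 2L
  ca <- numeric(m); cd <- numeric(m)
  base <- 2L * (seq_len(m) - 1L)
  for (k in seq_along(DB8_LO)) {
    xi <- x[(base + (k - 1L)) %% n + 1L]
    ca <- ca + DB8_LO[k] * xi
    cd <- cd + DB8_HI[k] * xi
  }
  list(ca = ca, cd = cd)
}

# Adjoint of dwt_step: returns the length-2m vector x with
# x[j] = sum_{i,k : 2(i-1)+k-1 = j-1 (mod n)} lo[k] ca[i] + hi[k] cd[i].
idwt_step <- function(ca, cd) {
  m <- length(ca)
  n <- 2L * m
  x <- numeric(n)
  base <- 2L * (seq_len(m) - 1L)
  for (k in seq_along(DB8_LO)) {
    idx <- (base + (k - 1L)) %% n + 1L
    x[idx] <- x[idx] + DB8_LO[k] * ca + DB8_HI[k] * cd
  }
  x
}

max_dwt_levels <- function(n, levels = 8L) {
  # each level needs at least one full filter span after halving
  j <- 0L
  while (j < levels && n >= 2L * length(DB8_LO)) {
    n <- (n + n %% 2L) %/% 2L
    j <- j + 1L
  }
  j
}

#' Multilevel discrete wavelet decomposition (Daubechies-8)
#'
#' Decomposes an ECG signal into detail coefficient sequences `d1..dJ`
#' (finest to coarsest) and a final approximation `aJ`, by default J = 8
#' levels (fewer when the record is too short).  The transform is the
#' orthogonal db8 filter bank with periodized boundaries; odd-length
#' stages are padded by repeating the last sample, and the padding is
#' stripped again on reconstruction, so
#' `dwt_reconstruct(dwt_decompose(x))` reproduces `x` to machine precision.
#'
#' db8 is used because its shape resembles a QRS complex: QRS energy
#' concentrates in a few mid detail levels, while the final approximation
#' (roughly the band below `fs / 2^(J+1)` Hz) carries baseline wander.
#'
#' @param signal an `ecg_signal` (or bare numeric vector).
#' @param levels requested decomposition depth (default 8).
#' @return an object of class `dwt_decomposition` with fields `details`
#'   (list `d1..dJ`), `approx`, `levels`, and the bookkeeping needed to
#'   invert the transform.
#' @seealso [dwt_reconstruct()], [single_scale_reconstruct()],
#'   [remove_baseline()]
#' @export
dwt_decompose <- function(signal, levels = 8L) {
  x <- if (inherits(signal, "ecg_signal")) signal$samples else as.numeric(signal)
  meta <- if (inherits(signal, "ecg_signal")) {
    signal[c("fs", "lead", "t0")]
  } else {
    list(fs = NA_real_, lead = NA_character_, t0 = 0)
  }
  n <- length(x)
  if (n < 2L * length(DB8_LO)) {
    stop("signal shorter than one wavelet filter span at the first level",
         call. = FALSE)
  }
  J <- max_dwt_levels(n, as.integer(levels))
  details <- vector("list", J)
  pads <- logical(J)
  cur <- x
  for (j in seq_len(J)) {
    if (length(cur) %% 2L == 1L) {
      pads[j] <- TRUE
      cur <- c(cur, cur[length(cur)])
    }
    st <- dwt_step(cur)
    details[[j]] <- st$cd
    cur <- st$ca
  }
  names(details) <- paste0("d", seq_len(J))
  structure(list(wavelet = "db8", levels = J, details = details, approx = cur,
                 pads = pads, n = n, meta = meta),
            class = "dwt_decomposition")
}

#' @export
print.dwt_decomposition <- function(x, ...) {
  cat(sprintf("<dwt_decomposition> db8, %d levels, input length %d\n",
              x$levels, x$n))
  cat("  detail lengths:", vapply(x$details, length, 1L),
      "| approx:", length(x$approx), "\n")
  invisible(x)
}

#' Invert a discrete wavelet decomposition
#'
#' @param dec a `dwt_decomposition`.
#' @return an `ecg_signal` when the decomposition came from one (metadata
#'   preserved), otherwise a numeric vector, equal to the decomposed input
#'   to machine precision.
#' @export
dwt_reconstruct <- function(dec) {
  stopifnot(inherits(dec, "dwt_decomposition"))
  cur <- dec$approx
  for (j in rev(seq_len(dec$levels))) {
    cur <- idwt_step(cur, dec$details[[j]])
    if (dec$pads[j]) cur <- cur[-length(cur)]
  }
  if (is.finite(dec$meta$fs)) {
    ecg_signal(cur, fs = dec$meta$fs, lead = dec$meta$lead, t0 = dec$meta$t0)
  } else {
    cur
  }
}

#' Reconstruct a single detail scale
#'
#' Inverse transform with every coefficient sequence zeroed except one
#' detail level: the result isolates the band of the signal carried by that
#' scale (detail `j` spans roughly `fs/2^(j+1)` to `fs/2^j` Hz).  Because
#' the transform is linear, the single-scale reconstructions over all levels
#' plus the approximation-only reconstruction sum to the original signal.
#'
#' @param dec a `dwt_decomposition`.
#' @param level detail level to retain, `1..dec$levels`; `0` retains only
#'   the approximation.
#' @return same type as [dwt_reconstruct()].
#' @export
single_scale_reconstruct <- function(dec, level) {
  stopifnot(inherits(dec, "dwt_decomposition"))
  level <- as.integer(level)
  if (level < 0L || level > dec$levels) {
    stop("`level` must be in 0..", dec$levels, call. = FALSE)
  }
  for (j in seq_len(dec$levels)) {
    if (j != level) dec$details[[j]] <- numeric(length(dec$details[[j]]))
  }
  if (level != 0L) dec$approx <- numeric(length(dec$approx))
  dwt_reconstruct(dec)
}

#' Remove baseline wander by zeroing the final approximation
#'
#' Sub-hertz baseline drift (respiration, electrode motion) lands in the
#' final approximation of an 8-level db8 decomposition (the band below
#' about `fs/512` Hz), while beat morphology lives in the detail sequences.
#' Dropping the approximation and inverting therefore removes the wander
#' and keeps the beats.
#'
#' @param signal an `ecg_signal`.
#' @param levels decomposition depth (default 8; deeper keeps more
#'   low-frequency content in the signal).
#' @return the wander-free `ecg_signal`.
#' @export
remove_baseline <- function(signal, levels = 8L) {
  dec <- dwt_decompose(signal, levels = levels)
  dec$approx <- numeric(length(dec$approx))
  dwt_reconstruct(dec)
}
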