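# Shared fixtures and independent oracles for the test suite.
# Oracles here are deliberately naive (loops, closed forms) and share no
# code with the package implementation they check.

# Greedy one-to-one matching of detected against true beats within a
# tolerance; returns sensitivity and positive predictive value.
match_beats <- function(truth, detected, fs, tol_s = 0.025) {
  tol <- tol_s * fs
  used <- rep(FALSE, length(detected))
  tp <- 0L
  for (q in truth) {
    d <- abs(detected - q)
    ok <- which(!used & d <= tol)
    if (length(ok)) {
      used[ok[which.min(d[ok])]] <- TRUE
      tp <- tp + 1L
    }
  }
  c(sens = tp / length(truth),
    ppv = if (length(detected)) tp / length(detected) else NA_real_)
}

# Dense, loop-based eigengap cluster-count oracle: independently rebuilds
# the locally scaled affinity, the normalized Laplacian entry by entry,
# and scans the eigengaps.
oracle_cluster_count <- function(points, k_max = 5, n_local = 2,
                                 sigma_min = 0.05) {
  m <- nrow(points)
  d <- matrix(0, m, m)
  for (i in 1:m) for (j in 1:m) {
    d[i, j] <- sqrt(sum((points[i, ] - points[j, ])^2))
  }
  if (all(d == 0)) return(1L)
  s <- numeric(m)
  for (i in 1:m) {
    others <- sort(d[i, -i])
    s[i] <- max(others[min(n_local, m - 1)], sigma_min)
  }
  a <- matrix(0, m, m)
  for (i in 1:m) for (j in 1:m) {
    if (i != j) a[i, j] <- exp(-d[i, j]^2 / (s[i] * s[j]))
  }
  deg <- rowSums(a)
  deg[deg == 0] <- .Machine$double.eps
  l <- matrix(0, m, m)
  for (i in 1:m) for (j in 1:m) {
    l[i, j] <- (i == j) - a[i, j] / sqrt(deg[i] * deg[j])
  }
  ev <- sort(eigen(l, symmetric = TRUE)$values)
  gaps <- numeric(min(k_max, m - 1))
  for (k in seq_along(gaps)) gaps[k] <- ev[k + 1] - ev[k]
  which.max(gaps)
}

# Generate, preprocess and feature-extract one synthetic record; returns
# the window feature frame with a label column.
pipeline_features <- function(kind, seed, duration = 60, fs = 360) {
  rec <- generate_ecg(rhythm_spec(kind), fs = fs, duration = duration,
                      seed = seed)
  filt <- apply_filter_bank(rec$signal)
  detsig <- remove_baseline(filt)
  beats <- delineate(detsig, detect_qrs(detsig))
  feats <- extract_features(filt, beats)
  feats$label <- kind
  feats
}
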