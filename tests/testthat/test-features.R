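test_that("window construction follows the 10 s / 50% overlap scheme", {
  rec <- generate_ecg(rhythm_spec("normal", rr_jitter = 0), fs = 500,
                      duration = 60, seed = 1)
  wins <- make_windows(rec$ibis, rec$beats, 60)
  expect_equal(length(wins), 11L)
  expect_equal(vapply(wins, `[[`, numeric(1), "start_time"), seq(0, 50, by = 5))
  # ~12 intervals per window at a 0.8 s rhythm
  counts <- vapply(wins, function(w) length(w$ibis), integer(1))
  expect_true(all(counts[2:10] %in% 10:14))
  # 10 s record: exactly one window; shorter: one truncated window + warning
  w1 <- make_windows(rec$ibis, rec$beats, 10)
  expect_equal(length(w1), 1L)
  expect_warning(ws <- make_windows(rec$ibis, rec$beats, 7), "truncated")
  expect_equal(ws[[1]]$end_time, 7)
})

test_that("poincare embedding equals the brute-force lag-1 zip", {
  expect_equal(unname(poincare(c(0.8, 0.8, 0.8))),
               unname(cbind(c(0.8, 0.8), c(0.8, 0.8))))
  expect_equal(unname(poincare(c(0.6, 1.0))), unname(cbind(0.6, 1.0)))
  expect_equal(nrow(poincare(0.7)), 0L)
  set.seed(2)
  x <- runif(30, 0.4, 1.2)
  p <- poincare(x)
  for (k in 1:(length(x) - 1)) {
    expect_equal(unname(p[k, ]), c(x[k], x[k + 1]))
  }
})

test_that("stepping increment matches hand arithmetic and its invariances", {
  # constant intervals: every step is zero
  expect_equal(feat_stepping(poincare(rep(0.8, 10))), 0)
  # worked example: intervals [0.8, 0.8, 0.4, 0.8]
  p <- poincare(c(0.8, 0.8, 0.4, 0.8))
  expected <- mean(c(0.4, sqrt(0.4^2 + 0.4^2))) / 0.7
  expect_equal(feat_stepping(p), expected, tolerance = 1e-6)
  # scale invariance: doubling all intervals changes nothing
  set.seed(3)
  x <- runif(15, 0.4, 1.2)
  expect_equal(feat_stepping(poincare(x)), feat_stepping(poincare(2 * x)),
               tolerance = 1e-12)
  # order sensitivity: stepping depends on the sequence, not just the set
  y <- c(0.4, 0.8, 0.4, 0.8, 0.4, 0.8)
  expect_gt(feat_stepping(poincare(y)),
            feat_stepping(poincare(sort(y))) + 0.1)
  expect_true(is.na(feat_stepping(poincare(c(0.5, 0.9)))))
})

test_that("diagonal dispersion matches hand arithmetic and is permutation-invariant", {
  expect_equal(feat_dispersion(poincare(rep(0.73, 8))), 0)
  expect_equal(feat_dispersion(cbind(x = 0.6, y = 1.0)), 0.4 / sqrt(2),
               tolerance = 1e-12)
  set.seed(4)
  p <- cbind(x = runif(12), y = runif(12))
  expect_equal(feat_dispersion(p), feat_dispersion(p[sample(12), ]),
               tolerance = 1e-12)
})

test_that("stepping and dispersion are zero iff intervals are constant", {
  set.seed(5)
  for (rep in 1:10) {
    x <- runif(12, 0.4, 1.2)
    p <- poincare(x)
    expect_gt(feat_stepping(p), 0)
    expect_gt(feat_dispersion(p), 0)
  }
  expect_equal(feat_stepping(poincare(rep(0.61, 12))), 0)
  expect_equal(feat_dispersion(poincare(rep(0.61, 12))), 0)
})

test_that("cluster count matches the dense eigengap oracle on small instances", {
  set.seed(6)
  for (rep in 1:20) {
    m <- sample(4:12, 1)
    pts <- cbind(x = runif(m, 0.3, 1.3), y = runif(m, 0.3, 1.3))
    expect_equal(feat_clusters(pts), oracle_cluster_count(pts),
                 label = paste("instance", rep))
  }
})

test_that("cluster count reflects designed ground truth", {
  set.seed(7)
  blob <- function(cx, cy, n = 20, s = 0.005) {
    cbind(x = rnorm(n, cx, s), y = rnorm(n, cy, s))
  }
  expect_equal(feat_clusters(rbind(blob(0.6, 0.6), blob(1.0, 1.0))), 2L)
  expect_equal(feat_clusters(blob(0.8, 0.8)), 1L)
  # all points inside a 5 ms ball collapse to one cluster
  ball <- cbind(x = 0.8 + runif(15, -0.0025, 0.0025),
                y = 0.8 + runif(15, -0.0025, 0.0025))
  expect_equal(feat_clusters(ball), 1L)
  expect_equal(feat_clusters(cbind(x = rep(0.8, 6), y = rep(0.8, 6))), 1L)
  # diffuse AFib-like scatter splits in the vast majority of draws
  hits <- vapply(1:50, function(seed) {
    set.seed(seed)
    feat_clusters(cbind(x = runif(12, 0.4, 1.2), y = runif(12, 0.4, 1.2))) > 1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("ST area matches a rectangle and responds to designed elevation", {
  fs <- 1000
  # flat ST at the onset level: zero area
  v <- rep(0.1, 1000)
  sig <- ecg_signal(v, fs)
  beat <- beat_annotation(qrs = 450, onset = 400, offset = 500, t = 700)
  expect_equal(feat_cumulative_voltage(sig, beat[1, ]), 0)
  # constant +0.2 mV over the 0.2 s window: area 0.2 * 0.2 = 0.04 mV.s
  v2 <- rep(0, 1000); v2[500:700] <- 0.2
  sig2 <- ecg_signal(v2, fs)
  expect_equal(feat_cumulative_voltage(sig2, beat[1, ]), 0.2 * 201 / 1000,
               tolerance = 1e-12)
  expect_true(is.na(feat_cumulative_voltage(
    sig2, beat_annotation(qrs = 450, onset = 400, offset = 500)[1, ])))
})

test_that("ST deviation matches the ramp closed form and ignores DC", {
  fs <- 1000
  beat <- beat_annotation(qrs = 450, onset = 400, offset = 500, t = 701)
  flat <- ecg_signal(rep(0.3, 1000), fs)
  expect_equal(feat_st_deviation(flat, beat[1, ]), 0)
  # linear ramp 0 -> 0.2 mV across the ST window: sd = 0.2 / sqrt(12)
  # (t_onset falls back to the window midpoint on a monotone segment)
  v <- rep(0, 1000)
  v[500:701] <- seq(0, 0.4, length.out = 202)  # 0 -> 0.2 by the midpoint
  sig <- ecg_signal(v, fs)
  got <- feat_st_deviation(sig, beat[1, ])
  expect_lt(abs(got - 0.2 / sqrt(12)) / (0.2 / sqrt(12)), 0.05)
  # DC shifts do not change a standard deviation
  sig_dc <- ecg_signal(v + 5, fs)
  expect_equal(feat_st_deviation(sig_dc, beat[1, ]), got, tolerance = 1e-12)
})

test_that("QRS slope matches arithmetic and is antisymmetric under reversal", {
  fs <- 1000
  v <- rep(0, 1000); v[480] <- 0; v[560] <- 0.1
  sig <- ecg_signal(v, fs)
  beat <- beat_annotation(qrs = 500, onset = 480, offset = 560)
  expect_equal(feat_slope(sig, beat[1, ]), 0.1 / 0.08, tolerance = 1e-12)
  rsig <- ecg_signal(rev(v), fs)
  rbeat <- beat_annotation(qrs = 1000 - 500 + 1, onset = 1000 - 560 + 1,
                           offset = 1000 - 480 + 1)
  expect_equal(feat_slope(rsig, rbeat[1, ]), -feat_slope(sig, beat[1, ]),
               tolerance = 1e-12)
  # degenerate zero-width complex: undefined, not a division crash
  expect_true(is.na(feat_slope(sig, list(onset = 480L, offset = 480L))))
  # equal end voltages: slope zero
  expect_equal(feat_slope(flat <- ecg_signal(rep(0.2, 1000), fs),
                          beat[1, ]), 0)
})

test_that("window features compose: regular windows are quiet, AF windows loud", {
  feats_n <- pipeline_features("normal", seed = 1, duration = 60, fs = 500)
  feats_a <- pipeline_features("afib", seed = 2, duration = 60, fs = 500)
  expect_true(all(feats_n$usable))
  un <- feats_n[feats_n$usable, ]
  ua <- feats_a[feats_a$usable, ]
  expect_gt(mean(ua$step_increment), 5 * mean(un$step_increment))
  expect_gt(mean(ua$diag_dispersion), 5 * mean(un$diag_dispersion))
  # zero-jitter rhythm: the irregularity features vanish entirely
  feats_0 <- pipeline_features("normal", seed = 3, duration = 30, fs = 500)
  rec0 <- generate_ecg(rhythm_spec("normal", rr_jitter = 0), fs = 500,
                       duration = 30, seed = 3)
  w0 <- make_windows(rec0$ibis, rec0$beats, 30)
  f0 <- extract_window_features(rec0$signal, w0[[2]], rec0$beats)
  expect_equal(f0$step_increment, 0)
  expect_equal(f0$diag_dispersion, 0)
  expect_equal(f0$n_clusters, 1)
})

test_that("ischemia windows differ from normal in the designed direction", {
  feats_n <- pipeline_features("normal", seed = 4, duration = 60, fs = 500)
  feats_i <- pipeline_features("ischemia", seed = 5, duration = 60, fs = 500)
  expect_gt(mean(feats_i$st_area), mean(feats_n$st_area))
  expect_gt(mean(feats_i$qrs_slope), mean(feats_n$qrs_slope))
})

test_that("a window without enough beats is flagged unusable", {
  rec <- generate_ecg(rhythm_spec("normal", rr_jitter = 0), fs = 500,
                      duration = 30, seed = 6)
  w <- make_windows(rec$ibis, rec$beats, 30)[[1]]
  w$ibis <- w$ibis[1]      # starve the window of intervals
  f <- extract_window_features(rec$signal, w, rec$beats)
  expect_false(f$usable)
  expect_true(is.na(f$step_increment))
})

test_that("min-max normalization maps, clips and round-trips as specified", {
  train <- data.frame(matrix(0, nrow = 2, ncol = 6))
  names(train) <- feature_names()
  train[2, ] <- 2
  train$step_increment <- c(0, 2)
  norm <- fit_normalizer(train)
  probe <- train[1, ]; probe$step_increment <- 1
  expect_equal(apply_normalizer(norm, probe)$step_increment, 0.5)
  probe$step_increment <- 5
  expect_equal(apply_normalizer(norm, probe)$step_increment, 1)  # clipped
  probe$step_increment <- -3
  expect_equal(apply_normalizer(norm, probe)$step_increment, 0)
  # round trip on the training range
  set.seed(8)
  big <- data.frame(matrix(runif(60), ncol = 6)); names(big) <- feature_names()
  nb <- fit_normalizer(big)
  back <- apply_normalizer(nb, apply_normalizer(nb, big), invert = TRUE)
  expect_lt(max(abs(as.matrix(back) - as.matrix(big))), 1e-12)
  # zero-range features warn and map to 0.5
  degen <- big; degen$qrs_slope <- 7
  expect_warning(nd <- fit_normalizer(degen), "zero-range")
  expect_true(all(apply_normalizer(nd, degen)$qrs_slope == 0.5))
})
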