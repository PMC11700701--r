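test_that("PCA-score outlier filter flags offset spectra and survives degeneracy", {
  # identical spectra: every score equal, SD = 0 on every axis, none flagged
  grid <- 500:549
  m <- matrix(rep(sin(grid / 20), 10), nrow = 10, byrow = TRUE)
  meta <- data.frame(spectrum_id = sprintf("s%d", 1:10),
                     sample_id = sprintf("m%d", 1:10),
                     patient_id = sprintf("p%d", 1:10),
                     replicate = 1L, class = "control")
  set <- spectra_set(grid, m, meta)
  fl <- flag_outliers(set)
  expect_equal(nrow(fl$report), 0)
  expect_equal(n_spectra(fl$kept), 10)

  # 20 baseline-only spectra + 1 with a +1000 constant offset: exactly that
  # one flagged; cross-checked against a direct eigendecomposition
  set.seed(3)
  n <- 21
  m2 <- t(vapply(1:n, function(i) 0.001 * grid + rnorm(50, sd = 0.5),
                 numeric(50)))
  m2[7, ] <- m2[7, ] + 1000
  meta2 <- data.frame(spectrum_id = sprintf("s%d", 1:n),
                      sample_id = sprintf("m%d", 1:n),
                      patient_id = sprintf("p%d", 1:n),
                      replicate = 1L, class = "control")
  set2 <- spectra_set(grid, m2, meta2)
  fl2 <- flag_outliers(set2, z = 2.58, n_pcs = 2)
  expect_identical(fl2$report$spectrum_id, "s7")

  # oracle: scores from an explicit covariance eigendecomposition
  xc <- sweep(m2, 2, colMeans(m2))
  ev <- eigen(cov(xc))$vectors[, 1:2]
  sc <- xc %*% ev
  flag_oracle <- rowSums(abs(sweep(sc, 2, colMeans(sc))) >
                           matrix(2.58 * apply(sc, 2, sd), n, 2,
                                  byrow = TRUE)) > 0
  expect_identical(which(flag_oracle), 7L)
  expect_error(flag_outliers(set2[1:2]), "at least 3")
})

test_that("rolling-ball baseline equals the brute-force morphological opening", {
  # constant spectrum: baseline is the constant, corrected is zero
  rb <- rolling_ball_baseline(rep(5, 100), 11, 5)
  expect_equal(rb$baseline, rep(5, 100))
  expect_equal(rb$corrected, rep(0, 100))

  # narrow peak on a flat floor: baseline ~ 0 under the peak, peak recovered
  y <- numeric(50)
  y[25] <- 10
  rb2 <- rolling_ball_baseline(y, 15, 1)
  orc <- oracle_rolling_ball(y, 15, 1)
  expect_equal(rb2$baseline, orc$baseline, tolerance = 1e-12)
  expect_equal(rb2$corrected[25], 10)
  expect_lt(max(abs(rb2$baseline[20:30])), 1e-12)

  # straight line with no baseline smoothing: corrected zero away from edges
  x <- seq_len(50)
  ramp <- 2 + 0.3 * x
  rb3 <- rolling_ball_baseline(ramp, 9, 1)
  orc3 <- oracle_rolling_ball(ramp, 9, 1)
  expect_equal(rb3$baseline, orc3$baseline, tolerance = 1e-12)
  expect_equal(rb3$corrected[10:41], rep(0, 32), tolerance = 1e-12)

  # random spectra vs the oracle, and the opening never exceeds the signal
  set.seed(9)
  for (i in 1:5) {
    y <- cumsum(rnorm(60)) + 3 * exp(-(1:60 - 30)^2 / 8)
    rb <- rolling_ball_baseline(y, 13, 5)
    orc <- oracle_rolling_ball(y, 13, 5)
    expect_equal(rb$baseline, orc$baseline, tolerance = 1e-10)
    expect_true(all(rb$opening <= y + 1e-12))
  }
  expect_error(rolling_ball_baseline(1:5, 11), "exceeds")
})

test_that("centering and global standardization meet their contract and replay", {
  v <- rnorm(30)
  grid <- 1:30 + 499
  meta <- data.frame(spectrum_id = c("a", "b"), sample_id = c("a", "b"),
                     patient_id = c("a", "b"), replicate = 1L,
                     class = "control")
  sym <- spectra_set(grid, rbind(v, -v), meta)
  cs <- center_standardize(sym)
  expect_equal(colMeans(cs$set$intensities), setNames(rep(0, 30), NULL),
               tolerance = 1e-10)
  expect_equal(cs$set$intensities[1, ] / cs$set$intensities[1, 1],
               v / v[1], tolerance = 1e-10)

  set <- tiny_set()
  cs2 <- center_standardize(set)
  expect_equal(max(abs(colMeans(cs2$set$intensities))), 0, tolerance = 1e-10)
  expect_equal(sd(as.vector(cs2$set$intensities)), 1, tolerance = 1e-10)

  # replaying the learned transform reproduces the output exactly
  replay <- center_standardize(set, cs2$mean_spectrum, cs2$scale)
  expect_identical(replay$set$intensities, cs2$set$intensities)

  const <- spectra_set(grid, rbind(rep(1, 30), rep(1, 30)), meta)
  expect_error(center_standardize(const), "degenerate")
})

test_that("despiking flags exactly the injected channel and repairs it", {
  grid <- seq(500, 699)
  smooth <- 100 * exp(-(grid - 600)^2 / (2 * 15^2))

  # clean input: no flags, identity
  ds <- despike(smooth, 4, 2)
  expect_length(ds$spike_channels, 0)
  expect_identical(ds$cleaned, smooth)

  # one injected 100x-noise spike: exactly that channel flagged, repaired
  set.seed(4)
  noisy <- smooth + rnorm(200, sd = 1)
  y <- noisy
  y[80] <- y[80] + 100
  ds2 <- despike(y, 4, 2)
  expect_identical(ds2$spike_channels, 80L)
  expect_lt(abs(ds2$cleaned[80] - noisy[80]), 3)
  expect_identical(ds2$cleaned[-80], y[-80])

  # infinite threshold: identity
  ds3 <- despike(y, Inf, 2)
  expect_length(ds3$spike_channels, 0)
  expect_identical(ds3$cleaned, y)

  # constant spectrum: no flags even though MAD = 0
  ds4 <- despike(rep(2, 10), 4, 2)
  expect_length(ds4$spike_channels, 0)
})

test_that("Whittaker smoother solves the penalized least-squares system", {
  y <- rnorm(12)
  expect_identical(whittaker_smooth(y, 0), y)

  # constants lie in the null space of the order-2 penalty
  expect_equal(whittaker_smooth(rep(3, 30), 1e4, 2), rep(3, 30),
               tolerance = 1e-8)
  # so do straight lines
  line <- 1 + 0.5 * (1:30)
  expect_equal(whittaker_smooth(line, 1e4, 2), line, tolerance = 1e-6)

  # dense direct solve oracle at the reference lambda
  set.seed(8)
  y12 <- rnorm(12)
  expect_equal(whittaker_smooth(y12, 1e4, 2), oracle_whittaker(y12, 1e4, 2),
               tolerance = 1e-8)
  y50 <- cumsum(rnorm(50))
  expect_equal(whittaker_smooth(y50, 123.4, 2),
               oracle_whittaker(y50, 123.4, 2), tolerance = 1e-8)
  expect_equal(whittaker_smooth(y50, 7, 1), oracle_whittaker(y50, 7, 1),
               tolerance = 1e-8)
  expect_error(whittaker_smooth(c(1, NA, 3), 1), "non-finite")
})

test_that("Whittaker output roughness is non-increasing in lambda", {
  set.seed(10)
  y <- cumsum(rnorm(80))
  rough <- vapply(c(0, 1, 10, 100, 1e3, 1e4, 1e5), function(l)
    sum(diff(whittaker_smooth(y, l, 2), differences = 2)^2), numeric(1))
  expect_true(all(diff(rough) <= 1e-10))
})

test_that("the full preprocessing pipeline honours stage order and ground truth", {
  cfg <- fast_config(seed = 21, spike_prob = 2e-3, outlier_prob = 0.04,
                     n_samples = c(control = 10L, `HR+HER2-` = 5L,
                                   `HR+HER2+` = 5L, `HR-HER2+` = 5L,
                                   `HR-HER2-` = 5L))
  set <- simulate_spectra(cfg)
  expect_gt(length(set$truth$outliers), 0)
  expect_gt(nrow(set$truth$spikes), 0)

  pp <- preprocess_spectra(set, preprocess_config())
  expect_identical(pp$report$stages,
                   c("outlier_filter", "baseline", "standardize", "despike",
                     "smooth"))
  # all injected outlier spectra removed
  expect_true(all(set$truth$outliers %in% pp$report$outliers$spectrum_id))
  # >= 90% of injected spike channels (in retained spectra) flagged
  kept <- set$truth$spikes[!set$truth$spikes$spectrum_id %in%
                             pp$report$outliers$spectrum_id, ]
  found <- mapply(function(id, ch) ch %in% pp$report$spikes[[id]],
                  kept$spectrum_id, kept$channel)
  expect_gte(mean(found), 0.9)
  # baseline + corrected reconstruct the raw retained spectra
  kept_ids <- pp$set$meta$spectrum_id
  raw <- set$intensities[kept_ids, ]
  corrected <- raw - pp$report$baseline[kept_ids, ]
  expect_equal(raw, pp$report$baseline[kept_ids, ] + corrected,
               tolerance = 1e-9)

  # fully disabled pipeline is the identity
  off <- preprocess_config(outlier_z = Inf, ball_width = 0,
                           standardize = FALSE, despike_threshold = Inf,
                           whittaker_lambda = 0)
  idn <- preprocess_spectra(set, off)
  expect_identical(idn$set$intensities, set$intensities)
  expect_identical(idn$report$stages, "outlier_filter")

  # determinism
  pp2 <- preprocess_spectra(set, preprocess_config())
  expect_identical(pp$set$intensities, pp2$set$intensities)
})
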