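test_that("statistical features match closed forms on a simple series", {
  f <- statistical_features(c(1, 2, 3, 4, 5))
  expect_equal(f$mean, 3)
  expect_equal(f$median, 3)
  expect_equal(f$min, 1)
  expect_equal(f$max, 5)
  expect_equal(f$p25, 2)
  expect_equal(f$p75, 4)
  expect_equal(f$skewness, 0)
  expect_error(statistical_features(c(1, NA)), "2 non-missing")
})

test_that("beta shape fit recovers known parameters", {
  withr::with_seed(11, {
    s <- 10 + 5 * rbeta(10000, 2, 2)   # scaled/shifted Beta(2,2)
    f <- statistical_features(s)
    expect_lt(abs(f$beta_alpha - 2), 0.2)
    expect_lt(abs(f$beta_beta - 2), 0.2)
    # excess kurtosis of Beta(2,2) is -6/7
    expect_lt(abs(f$kurtosis - (-6 / 7)), 0.1)
  })
})

test_that("histogram entropy is maximal for a uniform spread", {
  # equal mass in every occupied bin -> entropy log(k) for the k bins
  # the histogram rule actually produces
  s <- rep(seq(0.005, 0.995, by = 0.01), each = 20)
  f <- statistical_features(s)
  h <- hist(s, breaks = "FD", plot = FALSE)
  k <- sum(h$counts > 0)
  expect_equal(f$entropy, log(k), tolerance = 1e-6)
  # any other series of the same length cannot beat the uniform bound
  withr::with_seed(12, {
    g <- statistical_features(rbeta(length(s), 5, 1))
    expect_lt(g$entropy, log(length(s)))
  })
})

test_that("constant series degrade gracefully", {
  f <- statistical_features(rep(4, 100))
  expect_equal(f$sd, 0)
  expect_equal(f$skewness, 0)
  expect_equal(f$kurtosis, 0)
  expect_true(is.na(f$beta_alpha) && is.na(f$beta_beta))
})

test_that("a pure daily sinusoid concentrates in the 1 cycle/day bin", {
  mins <- 0:1439
  s <- 5 + 2 * sin(2 * pi * mins / 1440)
  f <- harmonic_features(s)
  expect_equal(f$fft_freq_01, 1)
  expect_equal(f$fft_amp_01, 2, tolerance = 1e-9)
  amps <- as.numeric(f[paste0("fft_amp_", sprintf("%02d", 2:15))])
  expect_true(all(amps < 1e-9))
  expect_equal(f$fft_entropy, 0, tolerance = 1e-6)
  expect_equal(f$pgram_freq_mean, 1, tolerance = 1e-6)
})

test_that("white noise has near-flat spectral entropy and exact RMS", {
  withr::with_seed(13, {
    s <- rnorm(1440)
    f <- harmonic_features(s)
    K <- 720
    expect_gt(f$fft_entropy, 0.9 * log(K))
    expect_lte(f$fft_entropy, log(K))
    expect_equal(f$rms_amp, sqrt(mean(s^2)))
  })
})

test_that("top-15 amplitudes are sorted and phase-invariant", {
  withr::with_seed(14, {
    s <- as.numeric(arima.sim(list(ar = 0.9), 1440))
    f <- harmonic_features(s)
    amps <- as.numeric(f[sprintf("fft_amp_%02d", 1:15)])
    expect_true(all(diff(amps) <= 1e-12))
    # circular time shift changes phases, not magnitudes
    g <- harmonic_features(c(s[301:1440], s[1:300]))
    expect_equal(as.numeric(g[sprintf("fft_amp_%02d", 1:15)]), amps)
    expect_equal(g$fft_entropy, f$fft_entropy)
  })
})

test_that("degenerate spectra follow the documented conventions", {
  f <- harmonic_features(rep(3, 1440))
  expect_equal(as.numeric(f[sprintf("fft_amp_%02d", 1:15)]), rep(0, 15))
  expect_equal(as.numeric(f[sprintf("fft_freq_%02d", 1:15)]), 1:15)
  expect_equal(f$fft_entropy, 0)
  expect_true(is.na(f$pgram_freq_mean))
})

test_that("activity percentiles use linear interpolation over present minutes", {
  p <- activity_percentile(rep(3, 10), rep(5, 10))
  expect_equal(unname(p), c(3, 5))
  s <- as.numeric(1:1440)
  # type-7 linear interpolation oracle: 1 + 0.75 * (n - 1)
  expect_equal(activity_percentile(s, s)[["cpm75"]], 1 + 0.75 * 1439)
  with_na <- c(s[1:100], rep(NA, 1340))
  expect_equal(activity_percentile(with_na, with_na)[["cpm75"]],
               1 + 0.75 * 99)
})

test_that("cohort quartile binning assigns four ordinal levels", {
  lv <- categorize_cohort(c(1, 2, 3, 4))
  expect_equal(as.integer(lv), 1:4)
  expect_equal(levels(lv), activity_levels())
  expect_warning(same <- categorize_cohort(rep(2, 10)), "degenerate")
  expect_true(all(as.integer(same) == 1))
  withr::with_seed(15, {
    v <- rlnorm(1000)
    counts <- table(categorize_cohort(v))
    expect_true(all(abs(counts - 250) <= 1))
  })
  # boundary values land in the lower bin
  expect_equal(as.integer(categorize_cohort(c(5, 10), cuts = c(5, 10, 20))),
               c(1L, 2L))
})

test_that("feature bank emits exactly the 98 accelerometry measures", {
  prof <- device_profile("wrist")
  sim <- simulate_cohort(sim_config("wrist", n_subjects = 8, seed = 16,
                                    wear_days = 2))
  sig <- compute_minute_signals(sim$recordings, prof)
  bank <- build_feature_bank(sig)
  expect_equal(nrow(bank), 8)
  expect_true(all(accel_feature_names() %in% names(bank)))
  expect_equal(length(accel_feature_names()), 98)
  expect_equal(length(signal_feature_names()), 96)

  # identical minute signals give identical signal features
  twin <- dplyr::mutate(dplyr::filter(sig, subject_id == "s0001"),
                        subject_id = "twin")
  bank2 <- build_feature_bank(dplyr::bind_rows(sig, twin))
  a <- bank2[bank2$subject_id == "s0001", signal_feature_names()]
  b <- bank2[bank2$subject_id == "twin", signal_feature_names()]
  expect_equal(as.numeric(a), as.numeric(b))
})

test_that("per-subject features are invariant to cohort order", {
  prof <- device_profile("wrist")
  sim <- simulate_cohort(sim_config("wrist", n_subjects = 8, seed = 17,
                                    wear_days = 2))
  sig <- compute_minute_signals(sim$recordings, prof)
  bank <- build_feature_bank(sig)
  shuffled <- withr::with_seed(18, {
    ids <- unique(sig$subject_id)
    dplyr::arrange(sig, match(subject_id, sample(ids)), minute)
  })
  bank2 <- dplyr::arrange(build_feature_bank(shuffled),
                          match(subject_id, bank$subject_id))
  expect_equal(as.data.frame(bank2[, signal_feature_names()]),
               as.data.frame(bank[, signal_feature_names()]))
  expect_equal(bank2$c4, bank$c4)
  expect_equal(bank2$v4, bank$v4)
})
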