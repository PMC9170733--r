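# Fixture builders shared across the suite. Everything is generated in
# code; scaled device profiles keep the tests at desk size.

midnight <- function(date = "2024-03-04") {
  as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
}

# hip-like profile at a reduced sampling rate (default 1 Hz -> H = 60)
hip_small <- function(rate = 1) device_profile("hip", sampling_rate = rate)

# A continuous tri-axial recording of `days` full days at the profile rate,
# device at rest (x = y = 0, z = 1) unless values are supplied.
rest_recording <- function(profile, days = 1, subject = "s1",
                           start = midnight()) {
  n <- days * profile$samples_per_day
  ts <- start + (seq_len(n) - 1) / profile$sampling_rate
  tibble::tibble(subject_id = subject, timestamp = ts,
                 x = 0, y = 0, z = 1)
}

# An epoch-count recording with all-wear flags.
epoch_recording <- function(magnitude, subject = "s1", start = midnight(),
                            wear = TRUE) {
  n <- length(magnitude)
  tibble::tibble(subject_id = subject,
                 timestamp = start + (seq_len(n) - 1) * 15,
                 magnitude = magnitude,
                 wear_flag = rep_len(wear, n))
}

# A ready-made model cohort without touching the accelerometry pipeline:
# base covariates plus one planted signal column among the feature names.
toy_model_cohort <- function(n = 60, separable = FALSE, seed = 1,
                             profile = device_profile("wrist")) {
  withr::with_seed(seed, {
    declined <- sample(rep(c(FALSE, TRUE), length.out = n))
    cols <- c(tier_features(profile, "full"), "cpm75", "vmc75")
    d <- tibble::tibble(subject_id = sprintf("t%03d", seq_len(n)))
    for (cl in cols) d[[cl]] <- stats::rnorm(n)
    if (separable) d$age <- ifelse(declined, 1, -1) + stats::rnorm(n, 0, 0.1)
    d$declined <- declined
    d$delta <- ifelse(declined, -1, 1)
    d
  })
}
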