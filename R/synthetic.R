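#' Configuration for a synthetic accelerometry cohort
#'
#' Bundles every knob of the synthetic-cohort generator. Profile-specific
#' defaults emulate the two study designs the pipeline targets:
#'
#' * **hip-like**: n = 115, outcome ratio 67 stable : 48 declined over a
#'   1-year follow-up with integer MoCA change in \[-8, 6\], age
#'   76 +/- 6-ish years with a standardized mean difference (Cohen's D) of
#'   0.457 between classes, baseline MoCA difference 0.572, continuous
#'   7-day wear, no non-wear.
#' * **wrist-like**: n = 575, ratio 279 : 296 over a 5-year follow-up with
#'   continuous MoCA change in \[-14.9, 14.9\], age effect 0.284, baseline
#'   MoCA effect 0.418, 72-h wear, 0.17% of epochs flagged non-wear.
#'
#' Each subject's free-living activity is a rectified sum of circadian
#' harmonics (1, 2 and 4 cycles/day by default) with subject-level
#' amplitude variation; declined subjects carry a reduced circadian
#' amplitude and a spectral tilt toward the fundamental, both scaled by
#' `accel_signal_strength` (0 = no accelerometry signal). Minute-level
#' noise scales with the subject amplitude so the rest case stays exactly
#' at gravity.
#'
#' @param profile `"hip"` or `"wrist"`, or a [device_profile()] (pass a
#'   scaled profile, e.g. `device_profile("hip", sampling_rate = 1)`, to
#'   simulate at reduced sampling rates).
#' @param n_subjects Number of subjects.
#' @param class_counts Named vector `c(stable = , declined = )` giving the
#'   target outcome ratio; scaled to `n_subjects` by proportional
#'   rounding.
#' @param effect_age,effect_moca Standardized mean differences between the
#'   declined and stable classes for age and baseline MoCA.
#' @param accel_signal_strength Multiplier on the between-class circadian
#'   amplitude difference; >= 0.
#' @param noise_level Minute-level noise standard deviation as a fraction
#'   of the cohort amplitude scale (default 0.25).
#' @param wear_days Number of simulated wear days (profile default).
#' @param nonwear_rate Fraction of wrist epochs flagged non-wear.
#' @param seed Integer seed; all cohort randomness derives from it.
#' @return A list of class `sim_config`.
#' @examples
#' sim_config("hip", n_subjects = 16, seed = 1)
#' @export
sim_config <- function(profile = c("hip", "wrist"), n_subjects = NULL,
                       class_counts = NULL, effect_age = NULL,
                       effect_moca = NULL, accel_signal_strength = 1,
                       noise_level = 0.25, wear_days = NULL,
                       nonwear_rate = NULL, seed = 1) {
  prof <- if (is_device_profile(profile)) profile
          else device_profile(match.arg(profile))
  hip <- prof$name == "hip"
  cfg <- list(
    profile = prof,
    n_subjects = if (is.null(n_subjects)) (if (hip) 115L else 575L)
                 else as.integer(n_subjects),
    class_counts = if (is.null(class_counts)) {
      if (hip) c(stable = 67, declined = 48) else c(stable = 279, declined = 296)
    } else class_counts,
    effect_age = if (is.null(effect_age)) (if (hip) 0.457 else 0.284)
                 else effect_age,
    effect_moca = if (is.null(effect_moca)) (if (hip) 0.572 else 0.418)
                  else effect_moca,
    accel_signal_strength = accel_signal_strength,
    noise_level = noise_level,
    wear_days = if (is.null(wear_days)) prof$wear_days_expected
                else as.integer(wear_days),
    nonwear_rate = if (is.null(nonwear_rate)) (if (hip) 0 else 0.0017)
                   else nonwear_rate,
    age_mean = if (hip) 73.2 else 67.0,
    age_sd = if (hip) 5.9 else 7.9,
    moca_mean = if (hip) 25.4 else 23.4,
    moca_sd = if (hip) 2.6 else 4.0,
    delta_range = if (hip) c(-8, 6) else c(-14.9, 14.9),
    amplitude_scale = if (hip) 0.2 else 800,
    seed = as.integer(seed)
  )
  stopifnot(cfg$n_subjects >= 8, cfg$accel_signal_strength >= 0,
            all(cfg$class_counts >= 1))
  structure(cfg, class = "sim_config")
}

#' Simulate one subject's accelerometer recording
#'
#' Generates a device-dialect recording from a circadian intensity model:
#' the minute-level activity intensity is the rectified sum of K harmonics
#' (`amplitude * sum(weights * cos(...))` around a `baseline` level,
#' peaking at `peak_hour`) plus Gaussian minute noise. On tri-axial (hip)
#' profiles each sample maps the minute intensity onto a randomly oriented
#' acceleration vector added to unit gravity, so the Euclidean norm of a
#' resting device is exactly 1; on count (wrist) profiles the intensity is
#' emitted per 15-s epoch, floored at zero, with optional non-wear gaps.
#'
#' @param params List with elements `subject_id`, `amplitude`, and
#'   optionally `baseline` (default `0.5 * amplitude`), `harmonics`
#'   (cycles/day, default `c(1, 2, 4)`), `weights` (default
#'   `c(1, 0.4, 0.2)`), `peak_hour` (default 14), `noise_sd` (default 0),
#'   `nonwear_rate` (default 0), `start` (default 2024-03-04 midnight UTC).
#' @param profile A [device_profile()].
#' @param seed Integer seed; the recording is a deterministic function of
#'   `(params, profile, seed)`.
#' @param wear_days Number of full days to simulate (profile default).
#' @return A recording tibble in the matching dialect (see
#'   [read_recording()]).
#' @examples
#' prof <- device_profile("wrist")
#' rec <- simulate_activity(list(subject_id = "s1", amplitude = 500),
#'                          prof, seed = 1)
#' nrow(rec)  # 3 days x 5760 epochs
#' @export
simulate_activity <- function(params, profile, seed, wear_days = NULL) {
  assert_profile(profile)
  p <- params
  stopifnot(!is.null(p$subject_id), !is.null(p$amplitude))
  if (is.null(p$baseline)) p$baseline <- 0.5 * p$amplitude
  if (is.null(p$harmonics)) p$harmonics <- c(1, 2, 4)
  if (is.null(p$weights)) p$weights <- c(1, 0.4, 0.2)
  if (is.null(p$peak_hour)) p$peak_hour <- 14
  if (is.null(p$noise_sd)) p$noise_sd <- 0
  if (is.null(p$nonwear_rate)) p$nonwear_rate <- 0
  if (is.null(p$start)) {
    p$start <- as.POSIXct("2024-03-04 00:00:00", tz = "UTC")
  }
  days <- if (is.null(wear_days)) profile$wear_days_expected else wear_days
  n_min <- days * 1440L
  tod <- (seq_len(n_min) - 1) %% 1440

  withr::with_seed(seed, {
    circ <- rowSums(vapply(seq_along(p$harmonics), function(k) {
      p$weights[k] * cos(2 * pi * p$harmonics[k] * (tod - p$peak_hour * 60) / 1440)
    }, numeric(n_min)))
    intensity <- pmax(0, p$baseline + p$amplitude * circ +
                           stats::rnorm(n_min, 0, p$noise_sd))
    H <- profile$window_samples
    n_samp <- n_min * H
    ts <- p$start + (seq_len(n_samp) - 1) / profile$sampling_rate
    a <- rep(intensity, each = H)
    if (profile$raw_form == "triaxial") {
      # random orientation on the unit sphere, gravity along +z
      u <- matrix(stats::rnorm(3 * n_samp), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      tibble::tibble(
        subject_id = p$subject_id, timestamp = ts,
        x = a * u[, 1], y = a * u[, 2], z = 1 + a * u[, 3]
      )
    } else {
      # epoch-level fluctuation so within-minute variability (hence VMC)
      # is nonzero whenever minute noise is
      mag <- pmax(0, a + stats::rnorm(n_samp, 0, p$noise_sd))
      wear <- stats::runif(n_samp) >= p$nonwear_rate
      tibble::tibble(
        subject_id = p$subject_id, timestamp = ts,
        magnitude = mag, wear_flag = wear
      )
    }
  })
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate a full synthetic cohort
#'
#' Draws a cohort of subjects with demographic/clinical covariates,
#' baseline and follow-up MoCA scores consistent with their decline class,
#' and device-faithful accelerometer recordings whose circadian structure
#' differs between classes in proportion to the configured
#' `accel_signal_strength`. Class counts follow the configured ratio
#' exactly (proportional rounding); age and baseline MoCA are shifted
#' between classes by the configured standardized effect sizes (declined
#' subjects older and with higher baseline scores); follow-up scores are
#' generated so that `delta < 0` exactly for the declined class, with
#' `delta` confined to the profile's observed range.
#'
#' @param config A [sim_config()].
#' @param include_recordings Set `FALSE` to draw covariates, labels and
#'   generative parameters only (e.g. for effect-size calibration checks);
#'   the covariate draw is unchanged, `recordings` is then `NULL`.
#' @return A list of class `sim_cohort`: `recordings` (one tibble, all
#'   subjects, device dialect), `covariates` (raw covariate table incl.
#'   `moca_baseline`, `moca_followup`), `truth` (per-subject generative
#'   parameters and true class) and `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config("wrist", n_subjects = 8, seed = 42))
#' table(cohort$truth$declined_true)
#' @export
simulate_cohort <- function(config, include_recordings = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  prof <- cfg$profile
  hip <- prof$name == "hip"
  n <- cfg$n_subjects
  n_dec <- round(n * cfg$class_counts[["declined"]] / sum(cfg$class_counts))
  ids <- sprintf("s%04d", seq_len(n))

  base_seed <- (cfg$seed %% 90000L) * 20011L

  cov <- withr::with_seed(cfg$seed, {
    dec <- sample(rep(c(FALSE, TRUE), c(n - n_dec, n_dec)))
    shift <- ifelse(dec, 0.5, -0.5)
    age <- stats::rnorm(n, cfg$age_mean + shift * cfg$effect_age * cfg$age_sd,
                        cfg$age_sd)
    moca0 <- clamp(stats::rnorm(
      n, cfg$moca_mean + shift * cfg$effect_moca * cfg$moca_sd, cfg$moca_sd
    ), 10, 30)
    if (hip) moca0 <- round(moca0)

    if (hip) {
      gender <- sample(c("male", "female"), n, TRUE, prob = c(0.191, 0.809))
      race <- sample(c("Other", "African American/Black"), n, TRUE,
                     prob = c(0.183, 0.817))
      education <- sample(covariate_dictionary("hip")$education, n, TRUE,
                          prob = c(0.035, 0.096, 0.319, 0.235, 0.244))
      income <- sample(covariate_dictionary("hip")$income, n, TRUE,
                       prob = c(0.50, 0.308, 0.123, 0.069))
      charlson <- pmin(stats::rpois(n, 1), 12)
      d_neg <- -sample(1:8, n, TRUE, prob = 0.55^(1:8))
      d_pos <- sample(0:6, n, TRUE, prob = 0.55^(1:7))
    } else {
      gender <- sample(c("male", "female"), n, TRUE, prob = c(0.409, 0.591))
      race <- sample(covariate_dictionary("wrist")$race, n, TRUE,
                     prob = c(0.736, 0.113, 0.117, 0.034))
      education <- sample(covariate_dictionary("wrist")$education, n, TRUE,
                          prob = c(0.160, 0.235, 0.367, 0.238))
      income <- NULL
      charlson <- pmin(stats::rpois(n, 0.9), 12)
      d_neg <- -clamp(0.1 + stats::rexp(n, 1 / 2.5), 0.1, -cfg$delta_range[1])
      d_pos <- clamp(stats::rexp(n, 1 / 2.5) - 0.5, 0, cfg$delta_range[2])
    }
    delta <- ifelse(dec, d_neg, d_pos)
    moca1 <- clamp(moca0 + delta, 0, 30)

    s <- cfg$accel_signal_strength
    amplitude <- cfg$amplitude_scale * exp(stats::rnorm(n, 0, 0.25)) *
      ifelse(dec, exp(-0.35 * s), 1)
    tilt <- ifelse(dec, exp(-0.25 * s), 1)
    peak_hour <- stats::rnorm(n, 14, 0.75)

    out <- tibble::tibble(
      subject_id = ids, declined_true = dec, age = age, gender = gender,
      race = race, education = education, charlson = charlson,
      moca_baseline = moca0, moca_followup = moca1,
      amplitude = amplitude, tilt = tilt, peak_hour = peak_hour
    )
    if (hip) out$income <- income
    out
  })

  recs <- if (!include_recordings) NULL else purrr::map(seq_len(n), function(i) {
    simulate_activity(
      params = list(
        subject_id = ids[i], amplitude = cov$amplitude[i],
        weights = c(1, 0.4 * cov$tilt[i], 0.2 * cov$tilt[i]),
        peak_hour = cov$peak_hour[i],
        noise_sd = cfg$noise_level * cov$amplitude[i],
        nonwear_rate = cfg$nonwear_rate
      ),
      profile = prof, seed = base_seed + i, wear_days = cfg$wear_days
    )
  })

  covariate_cols <- c("subject_id", covariate_names(prof)[
    covariate_names(prof) != "moca_baseline"
  ], "moca_baseline", "moca_followup")
  structure(list(
    recordings = if (is.null(recs)) NULL else dplyr::bind_rows(recs),
    covariates = cov[, covariate_cols],
    truth = cov[, c("subject_id", "declined_true", "amplitude", "tilt",
                    "peak_hour")],
    config = cfg
  ), class = "sim_cohort")
}

#' Run the full feature pipeline on a cohort
#'
#' Convenience chain from raw recordings to the model-ready cohort table:
#' valid-day filtering, minute-level ENMO/CPM/VMC, the 98-measure feature
#' bank, covariate encoding and decline labeling.
#'
#' @param x Either a `sim_cohort` from [simulate_cohort()], or a recording
#'   tibble (then `covariates` must be given).
#' @param profile A [device_profile()] matching the recordings.
#' @param covariates Raw covariate table when `x` is a recording tibble.
#' @param ... Passed to [compute_minute_signals()].
#' @return A model-ready cohort tibble (see [assemble_cohort()]).
#' @examples
#' \donttest{
#' prof <- device_profile("wrist")
#' cohort <- simulate_cohort(sim_config("wrist", n_subjects = 16, seed = 9))
#' dat <- process_cohort(cohort, prof)
#' dim(dat)
#' }
#' @export
process_cohort <- function(x, profile, covariates = NULL, ...) {
  assert_profile(profile)
  if (inherits(x, "sim_cohort")) {
    covariates <- x$covariates
    x <- x$recordings
  }
  if (is.null(covariates)) {
    stop("`covariates` must be supplied when `x` is a recording tibble",
         call. = FALSE)
  }
  sig <- compute_minute_signals(x, profile, ...)
  bank <- build_feature_bank(sig)
  assemble_cohort(bank, covariates, profile)
}
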