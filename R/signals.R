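#' Euclidean norm of a tri-axial sample stream
#'
#' `r(t) = sqrt(x(t)^2 + y(t)^2 + z(t)^2)`, the magnitude of the measured
#' acceleration vector. A device at rest reads magnitude 1 (gravity) in
#' dimensionless device units. Wrist epoch counts are already magnitudes and
#' skip this step.
#'
#' @param x,y,z Equal-length numeric vectors of axis values.
#' @return Numeric vector of per-sample magnitudes.
#' @examples
#' vector_magnitude(3, 4, 0)  # 5
#' @export
vector_magnitude <- function(x, y, z) {
  if (length(x) != length(y) || length(y) != length(z)) {
    stop("x, y and z must have equal length", call. = FALSE)
  }
  sqrt(x^2 + y^2 + z^2)
}

#' Across-day average magnitude profile
#'
#' Collapses a D x T day matrix (D wear days, T samples per day, all days
#' aligned on time-of-day) to a single representative day by the columnwise
#' mean. Missing samples (non-wear) are dropped from each column's mean; a
#' column with no observation in any day stays missing.
#'
#' @param R Numeric matrix, days in rows, time-of-day slots in columns.
#' @return Numeric vector of length `ncol(R)`: the average day.
#' @export
average_day <- function(R) {
  if (!is.matrix(R) || nrow(R) < 1) {
    stop("R must be a matrix with at least one wear day", call. = FALSE)
  }
  out <- colMeans(R, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

# Shared minute-window engine. rbar is the average-day magnitude sampled at
# the profile rate; windows are non-overlapping, minute-aligned, H samples
# long; a trailing partial window is dropped. A minute with fewer than
# min_window_frac * H present samples is emitted as missing.
window_stats <- function(rbar, H, vmc_reference = c("mean", "first_sample"),
                         min_window_frac = 0.5) {
  vmc_reference <- match.arg(vmc_reference)
  n_min <- length(rbar) %/% H
  if (n_min < 1) stop("series shorter than one window", call. = FALSE)
  M <- matrix(rbar[seq_len(n_min * H)], nrow = H)
  present <- !is.na(M)
  n_pres <- colSums(present)
  ok <- n_pres >= min_window_frac * H & n_pres > 0

  enmo <- colMeans(pmax(M - 1, 0), na.rm = TRUE)
  ref <- if (vmc_reference == "mean") {
    colMeans(M, na.rm = TRUE)
  } else {
    # literal window reference: the first (present) sample of each window
    apply(M, 2, function(w) w[which(!is.na(w))[1]])
  }
  vmc <- colMeans(abs(sweep(M, 2, ref, "-")), na.rm = TRUE)
  enmo[!ok] <- NA_real_
  vmc[!ok] <- NA_real_
  tibble::tibble(minute = seq_len(n_min), enmo = enmo,
                 cpm = H * enmo, vmc = vmc)
}

#' Minute-level ENMO, CPM and VMC
#'
#' The three minute-level activity signals, each computed over
#' non-overlapping one-minute windows of H samples taken from the average
#' day \eqn{\bar r(t)}:
#'
#' * **ENMO** (Euclidean norm minus one):
#'   \eqn{\mathrm{ENMO}(t) = \frac{1}{H}\sum_{h=0}^{H-1}
#'   \max[\bar r(t+h) - 1, 0]}. Subtracting 1 removes the static gravity
#'   component; the clamp keeps the result non-negative sample by sample.
#' * **CPM** (counts per minute): \eqn{\mathrm{CPM}(t) = H \cdot
#'   \mathrm{ENMO}(t)}, the window-sum form of ENMO.
#' * **VMC** (vector magnitude count): the mean amplitude deviation of the
#'   window, \eqn{\frac{1}{H}\sum_h |\bar r(t+h) - \mathrm{ref}|}. The
#'   default reference is the window mean (the standard mean-amplitude-
#'   deviation statistic); `vmc_reference = "first_sample"` instead
#'   subtracts the window's first sample.
#'
#' The gravity subtraction in ENMO is applied identically on both device
#' profiles; note that wrist activity counts are not gravity-calibrated, so
#' on that profile the "- 1" is a fixed baseline shift rather than a
#' physical gravity removal.
#'
#' @param rbar Average-day magnitude vector (see [average_day()]), sampled
#'   at the profile rate; its length must cover at least one full minute and
#'   any trailing partial window is dropped.
#' @param profile A [device_profile()] supplying H (`window_samples`).
#' @param enmo_series A minute series produced by `enmo()`.
#' @param vmc_reference `"mean"` (default) or `"first_sample"`.
#' @return A numeric minute series (length `floor(length(rbar) / H)`).
#' @examples
#' prof <- device_profile("wrist")
#' enmo(rep(1.5, 8), prof)  # 0.5 0.5
#' vmc(c(0, 2, 0, 2), prof) # 1
#' @export
enmo <- function(rbar, profile) {
  assert_profile(profile)
  window_stats(rbar, profile$window_samples)$enmo
}

#' @rdname enmo
#' @export
cpm <- function(enmo_series, profile) {
  assert_profile(profile)
  profile$window_samples * enmo_series
}

#' @rdname enmo
#' @export
vmc <- function(rbar, profile, vmc_reference = c("mean", "first_sample")) {
  assert_profile(profile)
  window_stats(rbar, profile$window_samples,
               vmc_reference = match.arg(vmc_reference))$vmc
}

#' Minute-level activity signals for every subject in a recording
#'
#' Runs the full signal-preparation chain per subject: magnitude (hip) or
#' flagged epoch counts (wrist), restriction to valid wear days, alignment
#' of days on the time-of-day grid, the across-day average
#' \eqn{\bar r(t)}, and the minute-level ENMO / CPM / VMC signals over
#' non-overlapping one-minute windows.
#'
#' Missing samples (wrist non-wear) are dropped and each grid slot averages
#' the samples actually present; a minute with fewer than
#' `min_window_frac` of its H samples present is emitted as missing and is
#' excluded from downstream feature statistics.
#'
#' @param rec A recording tibble from [read_recording()] (any number of
#'   subjects).
#' @param profile The [device_profile()].
#' @param days Optional day table; defaults to
#'   `filter_valid_days(split_days(rec, profile))`. Subjects without valid
#'   days are omitted (with the warning raised by [filter_valid_days()]).
#' @param vmc_reference Passed to [vmc()].
#' @param min_window_frac Minimum fraction of window samples that must be
#'   present; default 0.5.
#' @inheritParams split_days
#' @return A tibble with columns `subject_id`, `minute` (1--1440), `enmo`,
#'   `cpm`, `vmc`; 1440 rows per eligible subject.
#' @examples
#' prof <- device_profile("wrist")
#' cohort <- simulate_cohort(sim_config("wrist", n_subjects = 2, seed = 1))
#' sig <- compute_minute_signals(cohort$recordings, prof)
#' dplyr::count(sig, subject_id)
#' @export
compute_minute_signals <- function(rec, profile, days = NULL,
                                   daytime = c(6, 22), min_daytime_hours = 10,
                                   vmc_reference = c("mean", "first_sample"),
                                   min_window_frac = 0.5) {
  assert_profile(profile)
  vmc_reference <- match.arg(vmc_reference)
  if (is.null(days)) {
    days <- filter_valid_days(
      split_days(rec, profile, daytime, min_daytime_hours)
    )
  }
  keep_key <- paste(days$subject_id, days$date)

  r <- if (profile$raw_form == "triaxial") {
    vector_magnitude(rec$x, rec$y, rec$z)
  } else {
    ifelse(rec$wear_flag, rec$magnitude, NA_real_)
  }
  secs <- as.numeric(rec$timestamp)
  date <- as.Date(floor(secs / 86400), origin = "1970-01-01")
  keep <- paste(rec$subject_id, date) %in% keep_key
  slot <- as.integer(floor((secs %% 86400) * profile$sampling_rate + 1e-6)) + 1L

  dat <- tibble::tibble(subject_id = rec$subject_id[keep],
                        slot = slot[keep], r = r[keep])
  N <- profile$samples_per_day
  per_subject <- function(d) {
    ok <- !is.na(d$r)
    cnt <- tabulate(d$slot[ok], nbins = N)
    sums <- numeric(N)
    if (any(ok)) {
      agg <- rowsum(d$r[ok], d$slot[ok])
      sums[as.integer(rownames(agg))] <- agg[, 1]
    }
    rbar <- ifelse(cnt > 0, sums / cnt, NA_real_)
    window_stats(rbar, profile$window_samples,
                 vmc_reference = vmc_reference,
                 min_window_frac = min_window_frac)
  }
  dat |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(~ per_subject(.x)) |>
    dplyr::ungroup()
}
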