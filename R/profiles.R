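#' Device wear profiles
#'
#' A device profile captures everything the pipeline needs to know about how
#' a wearable was worn and sampled: the body location, whether the raw stream
#' is tri-axial or already a magnitude, the sampling rate, the number of
#' samples per calendar day (`samples_per_day`, often written N), the number
#' of samples in a one-minute window (`window_samples`, H), and the expected
#' wear length in days.
#'
#' Two canonical profiles are built in:
#'
#' * `"hip"` — raw tri-axial recording at 30 Hz worn continuously for 7 days,
#'   giving N = 2,592,000 samples/day and H = 1800 samples/minute.
#' * `"wrist"` — activity counts summed into 15-second epochs worn for 72 h
#'   (3 days), giving N = 5760 epochs/day and H = 4 epochs/minute.
#'
#' A reduced `sampling_rate` (hip) or a longer `epoch_seconds` (wrist) may be
#' supplied to build scaled profiles for simulation studies; the window is
#' always exactly one minute, so H is recomputed accordingly and must come
#' out a positive whole number.
#'
#' @param name `"hip"` or `"wrist"`.
#' @param sampling_rate Samples per second for tri-axial (hip-like) profiles.
#'   Defaults to 30. Must give a whole number of samples per minute.
#' @param epoch_seconds Epoch length in seconds for count (wrist-like)
#'   profiles. Defaults to 15. Must divide 60.
#' @param wear_days Expected wear length in days (hip default 7, wrist 3).
#'
#' @return An object of class `device_profile`: a list with elements `name`,
#'   `raw_form` (`"triaxial"` or `"magnitude"`), `sampling_rate` (samples per
#'   second), `samples_per_day`, `window_samples`, `wear_days_expected`,
#'   `epoch_seconds` (NA for tri-axial profiles).
#' @examples
#' device_profile("hip")
#' device_profile("wrist")
#' # a 1 Hz hip-like profile for desk-scale simulation
#' device_profile("hip", sampling_rate = 1)
#' @export
device_profile <- function(name = c("hip", "wrist"), sampling_rate = NULL,
                           epoch_seconds = NULL, wear_days = NULL) {
  name <- match.arg(name)
  if (name == "hip") {
    rate <- if (is.null(sampling_rate)) 30 else sampling_rate
    H <- rate * 60
    if (H < 1 || abs(H - round(H)) > 1e-9) {
      stop("hip sampling_rate must give a whole number of samples per minute",
           call. = FALSE)
    }
    H <- as.integer(round(H))
    prof <- list(
      name = "hip", raw_form = "triaxial", sampling_rate = rate,
      samples_per_day = H * 1440L, window_samples = H,
      wear_days_expected = if (is.null(wear_days)) 7L else as.integer(wear_days),
      epoch_seconds = NA_real_
    )
  } else {
    eps <- if (is.null(epoch_seconds)) 15 else epoch_seconds
    if (60 %% eps != 0) {
      stop("wrist epoch_seconds must divide one minute exactly", call. = FALSE)
    }
    H <- as.integer(60 / eps)
    prof <- list(
      name = "wrist", raw_form = "magnitude", sampling_rate = 1 / eps,
      samples_per_day = H * 1440L, window_samples = H,
      wear_days_expected = if (is.null(wear_days)) 3L else as.integer(wear_days),
      epoch_seconds = eps
    )
  }
  structure(prof, class = "device_profile")
}

#' @export
print.device_profile <- function(x, ...) {
  cat("<device_profile> ", x$name, " (", x$raw_form, ")\n", sep = "")
  cat("  sampling rate     : ", format(x$sampling_rate), " /s\n", sep = "")
  cat("  samples per day  N: ", x$samples_per_day, "\n", sep = "")
  cat("  window samples   H: ", x$window_samples, "\n", sep = "")
  cat("  expected wear days: ", x$wear_days_expected, "\n", sep = "")
  invisible(x)
}

is_device_profile <- function(x) inherits(x, "device_profile")

assert_profile <- function(profile) {
  if (!is_device_profile(profile)) {
    stop("`profile` must be a device_profile object; see device_profile()",
         call. = FALSE)
  }
  invisible(profile)
}
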