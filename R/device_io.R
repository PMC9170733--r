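#' Read a free-living accelerometer recording
#'
#' Reads one of the two supported CSV dialects into a canonical sample
#' stream. Tri-axial (hip) files have columns
#' `subject_id,timestamp,x,y,z`; epoch-count (wrist) files have columns
#' `subject_id,timestamp,magnitude,wear_flag`. Timestamps are ISO-8601
#' date-times, read in UTC; axis values are the dimensionless
#' acceleration-proportional numbers the device firmware emits.
#'
#' Hip devices are worn continuously, so every tri-axial sample is treated
#' as wear time. Wrist epochs carry an explicit wear flag (from the device's
#' galvanic skin sensor); non-wear epochs are kept in the returned stream,
#' flagged, and excluded from all downstream analysis.
#'
#' @param path Path to a CSV file in the matching dialect.
#' @param profile A [device_profile()]; its `raw_form` selects the dialect.
#' @return A tibble, one row per sample. Tri-axial: `subject_id`,
#'   `timestamp`, `x`, `y`, `z`. Epoch counts: `subject_id`, `timestamp`,
#'   `magnitude`, `wear_flag`.
#' @seealso [write_recording()], [split_days()]
#' @examples
#' prof <- device_profile("wrist")
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "subject_id,timestamp,magnitude,wear_flag",
#'   "s1,2024-01-01 12:00:00,10,TRUE",
#'   "s1,2024-01-01 12:00:15,12,TRUE"
#' ), f)
#' read_recording(f, prof)
#' @export
read_recording <- function(path, profile) {
  assert_profile(profile)
  if (profile$raw_form == "triaxial") {
    read_triaxial_csv(path)
  } else {
    read_epoch_csv(path)
  }
}

#' @rdname read_recording
#' @export
read_triaxial_csv <- function(path) {
  # readr raises its own generic "parsing issues" warning; the specific
  # error (with the offending line) comes from check_parse_problems()
  rec <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      timestamp = readr::col_datetime(),
      x = readr::col_double(),
      y = readr::col_double(),
      z = readr::col_double()
    ),
    locale = readr::locale(tz = "UTC"),
    progress = FALSE
  ))
  check_parse_problems(rec, path)
  check_stream(rec, c("x", "y", "z"))
  rec
}

#' @rdname read_recording
#' @export
read_epoch_csv <- function(path) {
  rec <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      timestamp = readr::col_datetime(),
      magnitude = readr::col_double(),
      wear_flag = readr::col_logical()
    ),
    locale = readr::locale(tz = "UTC"),
    progress = FALSE
  ))
  check_parse_problems(rec, path)
  check_stream(rec, "magnitude")
  if (any(rec$magnitude < 0, na.rm = TRUE)) {
    stop("epoch magnitudes must be non-negative in ", path, call. = FALSE)
  }
  rec
}

check_parse_problems <- function(rec, path) {
  probs <- readr::problems(rec)
  if (nrow(probs) > 0) {
    p <- probs[1, ]
    stop(sprintf("parse error in %s at line %d, column %d: expected %s, got '%s'",
                 path, p$row, p$col, p$expected, p$actual),
         call. = FALSE)
  }
  invisible(rec)
}

check_stream <- function(rec, value_cols) {
  if (anyNA(rec$timestamp)) {
    stop("recording contains unparseable timestamps", call. = FALSE)
  }
  for (cl in value_cols) {
    if (anyNA(rec[[cl]])) {
      stop("recording contains missing values in column '", cl, "'",
           call. = FALSE)
    }
  }
  bad <- rec |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$timestamp, strictly = TRUE),
                     .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    stop("timestamps must be strictly increasing within subject; offending subject(s): ",
         paste(bad$subject_id, collapse = ", "), call. = FALSE)
  }
  invisible(rec)
}

#' Write a recording back to its CSV dialect
#'
#' The inverse of [read_recording()]. Timestamps are written as
#' `YYYY-MM-DD HH:MM:SS` (with 6 fractional digits when any sample falls on
#' a sub-second instant), so `write` then `read` is a fixed point.
#'
#' @param rec A recording tibble as returned by [read_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  secs <- as.numeric(rec$timestamp)
  fmt <- if (all(abs(secs - round(secs)) < 1e-6)) "%Y-%m-%d %H:%M:%S"
         else "%Y-%m-%d %H:%M:%OS6"
  out <- rec
  out$timestamp <- format(rec$timestamp, fmt, tz = "UTC")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Partition a recording into calendar days
#'
#' Splits each subject's sample stream at local midnight and summarises each
#' calendar day: number of wear samples, hours of daytime recording, whether
#' the day is partial (fewer samples than a full device day), and whether it
#' is valid. A day is *valid* when it holds at least `min_daytime_hours`
#' (default 10) hours of recording inside the daytime window, by default
#' 06:00--22:00. Wrist epochs flagged non-wear do not count toward recorded
#' hours.
#'
#' @param rec A recording tibble from [read_recording()].
#' @param profile The [device_profile()] the recording was made with.
#' @param daytime Two clock hours `c(start, end)` delimiting daytime;
#'   default `c(6, 22)`.
#' @param min_daytime_hours Validity threshold in hours; default 10.
#' @return A tibble with one row per subject-day: `subject_id`, `day_index`
#'   (1-based within subject), `date`, `n_samples` (wear samples),
#'   `daytime_hours`, `is_partial`, `is_valid`.
#' @examples
#' prof <- device_profile("wrist")
#' cohort <- simulate_cohort(sim_config("wrist", n_subjects = 2, seed = 1))
#' split_days(cohort$recordings, prof)
#' @export
split_days <- function(rec, profile, daytime = c(6, 22),
                       min_daytime_hours = 10) {
  assert_profile(profile)
  if (nrow(rec) == 0) {
    return(tibble::tibble(subject_id = character(), day_index = integer(),
                          date = as.Date(character()), n_samples = integer(),
                          daytime_hours = double(), is_partial = logical(),
                          is_valid = logical()))
  }
  worn <- if ("wear_flag" %in% names(rec)) rec$wear_flag else TRUE
  secs <- as.numeric(rec$timestamp)
  date <- as.Date(floor(secs / 86400), origin = "1970-01-01")
  tod_h <- (secs %% 86400) / 3600
  in_day <- tod_h >= daytime[1] & tod_h < daytime[2]
  days <- tibble::tibble(subject_id = rec$subject_id, date = date,
                         worn = worn, in_day = in_day) |>
    dplyr::group_by(.data$subject_id, .data$date) |>
    dplyr::summarise(
      n_samples = sum(.data$worn),
      daytime_hours = sum(.data$worn & .data$in_day) /
        profile$sampling_rate / 3600,
      .groups = "drop_last"
    ) |>
    dplyr::arrange(.data$date, .by_group = TRUE) |>
    dplyr::mutate(day_index = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      is_partial = .data$n_samples < profile$samples_per_day,
      is_valid = .data$daytime_hours >= min_daytime_hours
    ) |>
    dplyr::select("subject_id", "day_index", "date", "n_samples",
                  "daytime_hours", "is_partial", "is_valid")
  days
}

#' Keep only valid wear days
#'
#' Filters a day table from [split_days()] down to valid days (at least 10
#' daytime hours by default, as configured in `split_days()`). Subjects left
#' with zero valid days are not silently dropped: they are recorded in the
#' `ineligible` attribute of the result and a warning names them, since such
#' subjects must be excluded from the analysis cohort explicitly.
#'
#' @param days A day table from [split_days()].
#' @return The valid rows of `days`, in their original order, with an
#'   `ineligible` attribute holding the subject ids that retained no valid
#'   day.
#' @export
filter_valid_days <- function(days) {
  kept <- dplyr::filter(days, .data$is_valid)
  ineligible <- setdiff(unique(days$subject_id), unique(kept$subject_id))
  if (length(ineligible) > 0) {
    warning("subject(s) with no valid wear day flagged ineligible: ",
            paste(ineligible, collapse = ", "), call. = FALSE)
  }
  attr(kept, "ineligible") <- ineligible
  kept
}
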