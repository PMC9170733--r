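test_that("tri-axial CSV round-trips losslessly", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "subject_id,timestamp,x,y,z",
    "s1,2024-03-04 00:00:00,0.1,-0.2,0.97",
    "s1,2024-03-04 00:00:01,0.05,0.0,1.01",
    "s1,2024-03-04 00:00:02,-0.3,0.4,0.9"
  ), f)
  rec <- read_triaxial_csv(f)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$x, c(0.1, 0.05, -0.3))
  expect_equal(rec$z, c(0.97, 1.01, 0.9))

  # write -> read is a fixed point of the dialect
  g <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, g)
  expect_equal(read_triaxial_csv(g), rec)
  h <- withr::local_tempfile(fileext = ".csv")
  write_recording(read_triaxial_csv(g), h)
  expect_identical(readLines(g), readLines(h))
})

test_that("epoch CSV round-trips and keeps non-wear flags", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "subject_id,timestamp,magnitude,wear_flag",
    "s2,2024-03-04 08:00:00,12.5,TRUE",
    "s2,2024-03-04 08:00:15,0,FALSE",
    "s2,2024-03-04 08:00:30,3.25,TRUE"
  ), f)
  rec <- read_epoch_csv(f)
  expect_equal(rec$wear_flag, c(TRUE, FALSE, TRUE))
  g <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, g)
  expect_equal(read_epoch_csv(g), rec)
})

test_that("non-wear epochs are excluded from the analysis stream", {
  prof <- device_profile("wrist")
  mag <- rep(2, 2 * 5760)
  rec <- epoch_recording(mag)
  rec$wear_flag[100] <- FALSE
  days <- split_days(rec, prof)
  # one 15-s epoch less of recorded time on day 1
  expect_equal(days$n_samples, c(5759, 5760))
  # and the flagged epoch's magnitude never reaches the minute signals:
  # minute 25 (epochs 97-100) averages the three wear epochs only
  sig <- compute_minute_signals(rec, prof)
  expect_equal(sig$enmo[25], 1)  # all present samples are 2 -> clamp to 1
  expect_equal(nrow(sig), 1440)
})

test_that("malformed CSV rows raise a parse error naming the line", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "subject_id,timestamp,x,y,z",
    "s1,2024-03-04 00:00:00,0.1,-0.2,0.97",
    "s1,2024-03-04 00:00:01,oops,0.0,1.01"
  ), f)
  expect_error(read_triaxial_csv(f), "line 3")
})

test_that("split_days partitions calendar days and flags partial days", {
  prof <- hip_small()
  rec <- rest_recording(prof, days = 2)
  days <- split_days(rec, prof)
  expect_equal(nrow(days), 2)
  expect_equal(days$n_samples, rep(prof$samples_per_day, 2))
  expect_false(any(days$is_partial))
  expect_equal(days$day_index, 1:2)

  rec15 <- rest_recording(prof, days = 1)
  extra <- rest_recording(prof, days = 1, start = midnight("2024-03-05"))
  rec15 <- dplyr::bind_rows(rec15, extra[seq_len(nrow(extra) / 2), ])
  days15 <- split_days(rec15, prof)
  expect_equal(days15$is_partial, c(FALSE, TRUE))

  expect_equal(nrow(split_days(rec[0, ], prof)), 0)
})

test_that("daytime hours match a brute-force per-sample count on gappy data", {
  prof <- hip_small()
  rec <- rest_recording(prof, days = 1)
  keep <- withr::with_seed(42, sort(sample(nrow(rec), 30000)))
  rec <- rec[keep, ]
  days <- split_days(rec, prof)
  # oracle: count samples whose clock hour lies in [6, 22), divide by rate
  hrs <- as.numeric(format(rec$timestamp, "%H", tz = "UTC")) +
    as.numeric(format(rec$timestamp, "%M", tz = "UTC")) / 60
  oracle <- sum(hrs >= 6 & hrs < 22) / prof$sampling_rate / 3600
  expect_equal(days$daytime_hours, oracle)
})

test_that("valid-day rule keeps >= 10 daytime hours, boundary excluded", {
  prof <- device_profile("wrist")
  # 12 daytime hours of epochs (07:00 -> 19:00)
  full <- epoch_recording(rep(1, 12 * 240),
                          start = midnight() + 7 * 3600)
  expect_true(split_days(full, prof)$is_valid)
  # 9.9 daytime hours -> excluded
  short <- epoch_recording(rep(1, round(9.9 * 240)),
                           start = midnight() + 7 * 3600)
  expect_false(split_days(short, prof)$is_valid)

  # mixed 7-day fixture: days 2, 4, 6 hold only 4 daytime hours
  parts <- lapply(1:7, function(d) {
    hours <- if (d %% 2 == 0) 4 else 12
    epoch_recording(rep(1, hours * 240), subject = "mix",
                    start = midnight() + (d - 1) * 86400 + 7 * 3600)
  })
  days <- split_days(dplyr::bind_rows(parts), prof)
  kept <- filter_valid_days(days)
  expect_equal(nrow(kept), 4)
  # idempotent and order-preserving
  expect_equal(filter_valid_days(kept)$date, kept$date)
  expect_equal(kept$day_index, sort(kept$day_index))
})

test_that("subjects with zero valid days are flagged, not dropped silently", {
  prof <- device_profile("wrist")
  good <- epoch_recording(rep(1, 12 * 240), subject = "ok",
                          start = midnight() + 7 * 3600)
  bad <- epoch_recording(rep(1, 2 * 240), subject = "none",
                         start = midnight() + 7 * 3600)
  days <- split_days(dplyr::bind_rows(good, bad), prof)
  expect_warning(kept <- filter_valid_days(days), "none")
  expect_equal(attr(kept, "ineligible"), "none")
})

test_that("a continuous 7-day hip recording yields 7 valid days", {
  prof <- hip_small(1 / 6)  # 1 sample / 6 s keeps this cheap
  rec <- rest_recording(prof, days = 7)
  days <- split_days(rec, prof)
  expect_equal(nrow(days), 7)
  expect_true(all(days$is_valid))
})
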