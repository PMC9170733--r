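#' Distributional statistics of a minute series
#'
#' The twelve statistical measures computed on each minute-level signal:
#' mean, median, standard deviation, minimum, maximum, 25th and 75th
#' percentiles, skewness, excess kurtosis, entropy, and the two shape
#' parameters of a beta distribution fitted to the series.
#'
#' Skewness is the standardized third central moment and kurtosis the
#' excess kurtosis (zero for a normal distribution). Entropy is estimated
#' from the histogram of the series (Freedman--Diaconis bin rule): the
#' Shannon entropy of the bin proportions, which is maximal, `log k`, when
#' the series spreads uniformly over `k` bins and drops as activity
#' concentrates. The beta shape pair is a method-of-moments fit after
#' rescaling the series to (0, 1) over its min--max range (clipped at
#' 1e-6); a constant or otherwise degenerate series yields missing shape
#' parameters, zero skewness/kurtosis and zero standard deviation.
#'
#' @param s Numeric minute series; missing minutes are ignored. At least
#'   two non-missing values are required.
#' @return A one-row tibble with columns `mean`, `median`, `sd`, `min`,
#'   `max`, `p25`, `p75`, `skewness`, `kurtosis`, `entropy`, `beta_alpha`,
#'   `beta_beta`.
#' @examples
#' statistical_features(c(1, 2, 3, 4, 5))
#' @export
statistical_features <- function(s) {
  v <- s[!is.na(s)]
  if (length(v) < 2) {
    stop("need at least 2 non-missing values", call. = FALSE)
  }
  m <- mean(v)
  cm <- v - m
  m2 <- mean(cm^2)
  skew <- if (m2 > 0) mean(cm^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean(cm^4) / m2^2 - 3 else 0
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)

  h <- graphics::hist(v, breaks = "FD", plot = FALSE)
  p <- h$counts / length(v)
  p <- p[p > 0]
  ent <- -sum(p * log(p))

  # method-of-moments beta shape on the min-max rescaled series
  rng <- range(v)
  if (rng[2] > rng[1]) {
    u <- pmin(pmax((v - rng[1]) / (rng[2] - rng[1]), 1e-6), 1 - 1e-6)
    mu <- mean(u)
    vu <- stats::var(u)
    if (vu > 0 && vu < mu * (1 - mu)) {
      k <- mu * (1 - mu) / vu - 1
      ab <- c(mu * k, (1 - mu) * k)
    } else {
      ab <- c(NA_real_, NA_real_)
    }
  } else {
    ab <- c(NA_real_, NA_real_)
  }

  tibble::tibble(
    mean = m, median = stats::median(v), sd = stats::sd(v),
    min = rng[1], max = rng[2], p25 = q[1], p75 = q[2],
    skewness = skew, kurtosis = kurt, entropy = ent,
    beta_alpha = ab[1], beta_beta = ab[2]
  )
}

#' Circadian harmonic features of a minute series
#'
#' The thirty-six harmonic measures of one minute-level signal, derived
#' from the discrete Fourier transform of the full 1440-minute day (mean
#' removed, missing minutes linearly interpolated first):
#'
#' * amplitudes of the 15 largest-magnitude FFT coefficients, in
#'   descending order (`fft_amp_01` ... `fft_amp_15`), with amplitude ties
#'   broken toward the lower frequency;
#' * the frequencies of those coefficients in cycles/day
#'   (`fft_freq_01` ... `fft_freq_15`);
#' * spectral (FFT) entropy: the Shannon entropy of the normalized power
#'   spectrum — near `log K` over the `K = 720` retained bins for
#'   noise-like series, 0 when all power sits in one harmonic;
#' * the power-weighted mean and standard deviation of frequency
#'   (`pgram_freq_mean`, `pgram_freq_sd`);
#' * the root-mean-square amplitude of the series (`rms_amp`);
#' * the power-weighted excess kurtosis and skewness of frequency
#'   (`pgram_freq_kurtosis`, `pgram_freq_skewness`).
#'
#' Amplitudes are reported on the signal scale (`2 |F_k| / n`), so a pure
#' sinusoid of amplitude *a* at *f* cycles/day contributes one coefficient
#' of amplitude *a* at frequency *f*. The constant (DC) term is excluded.
#' For an all-zero (or constant) series every amplitude is 0, the top-15
#' frequencies default to 1..15 cycles/day, entropy is 0 by convention and
#' the weighted moments are missing; when the spectrum is a single spike
#' (zero frequency spread) the weighted skewness/kurtosis are 0 by
#' convention.
#'
#' @param s Numeric series of length 1440 (one value per minute of the
#'   day); missing values allowed.
#' @return A one-row tibble with 36 columns as described above.
#' @examples
#' mins <- 0:1439
#' harmonic_features(sin(2 * pi * mins / 1440))[, c("fft_freq_01", "fft_amp_01")]
#' @export
harmonic_features <- function(s) {
  n <- 1440L
  if (length(s) != n) {
    stop("harmonic features are defined on a full 1440-minute day",
         call. = FALSE)
  }
  if (anyNA(s)) {
    idx <- which(!is.na(s))
    if (length(idx) < 2) stop("too few observed minutes", call. = FALSE)
    s <- stats::approx(idx, s[idx], xout = seq_len(n), rule = 2)$y
  }
  x <- s - mean(s)
  F <- stats::fft(x)
  K <- n %/% 2                      # retained positive-frequency bins
  freq <- seq_len(K)                # cycles/day on a one-day grid
  amp <- 2 * Mod(F[freq + 1L]) / n
  pow <- Mod(F[freq + 1L])^2

  ord <- order(-amp, freq)[1:15]
  top_amp <- amp[ord]
  top_freq <- freq[ord]

  tot <- sum(pow)
  if (tot > 0) {
    P <- pow / tot
    Ppos <- P[P > 0]
    fft_entropy <- -sum(Ppos * log(Ppos))
    fmean <- sum(P * freq)
    fvar <- sum(P * (freq - fmean)^2)
    fsd <- sqrt(fvar)
    if (fvar > 0) {
      z <- (freq - fmean) / fsd
      fskew <- sum(P * z^3)
      fkurt <- sum(P * z^4) - 3
    } else {
      fskew <- 0
      fkurt <- 0
    }
  } else {
    top_amp <- rep(0, 15)
    top_freq <- 1:15
    fft_entropy <- 0
    fmean <- NA_real_
    fsd <- NA_real_
    fskew <- NA_real_
    fkurt <- NA_real_
  }

  out <- c(
    stats::setNames(top_amp, sprintf("fft_amp_%02d", 1:15)),
    stats::setNames(as.double(top_freq), sprintf("fft_freq_%02d", 1:15)),
    fft_entropy = fft_entropy,
    pgram_freq_mean = fmean, pgram_freq_sd = fsd,
    rms_amp = sqrt(mean(s^2)),
    pgram_freq_kurtosis = fkurt, pgram_freq_skewness = fskew
  )
  tibble::as_tibble(as.list(out))
}

#' Per-subject 75th percentiles of CPM and VMC
#'
#' The subject-level activity summaries behind the C4 and V4 categories:
#' the 75th percentile of the minute-level CPM and VMC series (linear
#' interpolation percentiles over non-missing minutes).
#'
#' @param s_cpm,s_vmc Minute series for one subject.
#' @return A named numeric vector `c(cpm75 = ..., vmc75 = ...)`.
#' @export
activity_percentile <- function(s_cpm, s_vmc) {
  c(cpm75 = stats::quantile(s_cpm, 0.75, na.rm = TRUE, names = FALSE, type = 7),
    vmc75 = stats::quantile(s_vmc, 0.75, na.rm = TRUE, names = FALSE, type = 7))
}

#' Four-level activity categories from cohort quartiles
#'
#' Bins per-subject summary values (CPM75 or VMC75) into the four ordinal
#' activity levels — inactive (0--25%], moderately active (25--50%], active
#' (50--75%], extremely active (75--100%] — at the quartiles of the cohort
#' distribution. Values falling exactly on a cut-point go to the lower bin.
#' When `cuts` is supplied (e.g. quartiles fitted on a training cohort),
#' those cut-points are used instead of refitting, so held-out subjects are
#' binned consistently with the cohort the model was trained on.
#'
#' @param values Numeric vector of per-subject summaries.
#' @param cuts Optional numeric vector of three cut-points (25/50/75%).
#' @return An ordered factor with levels `inactive < moderately_active <
#'   active < extremely_active` and attribute `cuts` holding the
#'   cut-points used.
#' @examples
#' categorize_cohort(c(1, 2, 3, 4))
#' @export
categorize_cohort <- function(values, cuts = NULL) {
  if (is.null(cuts)) {
    if (length(values) < 4) {
      stop("need at least 4 subjects to fit cohort quartiles", call. = FALSE)
    }
    cuts <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE,
                            type = 7, na.rm = TRUE)
  }
  if (length(unique(cuts)) < 3) {
    warning("degenerate cohort distribution: quartile cut-points coincide",
            call. = FALSE)
  }
  code <- 1L + (values > cuts[1]) + (values > cuts[2]) + (values > cuts[3])
  out <- factor(activity_levels()[code], levels = activity_levels(),
                ordered = TRUE)
  attr(out, "cuts") <- cuts
  out
}

#' @rdname categorize_cohort
#' @export
activity_levels <- function() {
  c("inactive", "moderately_active", "active", "extremely_active")
}

#' Names of the accelerometry measures
#'
#' `signal_feature_names()` returns the 96 per-signal feature names (12
#' statistical + 36 harmonic, for ENMO and VMC); `accel_feature_names()`
#' appends the two categorical activity measures `c4` and `v4` for the
#' full bank of 98 accelerometry measures.
#'
#' @return Character vector of feature names in their canonical order.
#' @export
signal_feature_names <- function() {
  stat <- c("mean", "median", "sd", "min", "max", "p25", "p75",
            "skewness", "kurtosis", "entropy", "beta_alpha", "beta_beta")
  harm <- c(sprintf("fft_amp_%02d", 1:15), sprintf("fft_freq_%02d", 1:15),
            "fft_entropy", "pgram_freq_mean", "pgram_freq_sd", "rms_amp",
            "pgram_freq_kurtosis", "pgram_freq_skewness")
  c(paste0("ENMO_", c(stat, harm)), paste0("VMC_", c(stat, harm)))
}

#' @rdname signal_feature_names
#' @export
accel_feature_names <- function() {
  c(signal_feature_names(), "c4", "v4")
}

#' Build the 98-measure feature bank for a cohort
#'
#' Computes, for every subject in a minute-signal table, the 12 statistical
#' and 36 harmonic features of the ENMO and VMC series (96 signal
#' features), plus the two cohort-quartile activity categories C4 (from
#' each subject's CPM 75th percentile) and V4 (from the VMC 75th
#' percentile) — 98 accelerometry measures in all, in the stable order
#' given by [accel_feature_names()]. C4/V4 are stored as ordinal codes
#' 1--4 (see [activity_levels()]).
#'
#' The auxiliary columns `cpm75` and `vmc75` are kept in the output (they
#' are not part of the 98 measures) so that category cut-points can be
#' refitted on a training subset and applied to held-out subjects; the
#' cut-points actually used are attached as the `cuts` attribute.
#'
#' @param minute_signals Output of [compute_minute_signals()].
#' @param cuts Optional list with elements `cpm75` and `vmc75`, each three
#'   cut-points from a reference (training) cohort.
#' @return A tibble: `subject_id`, 96 signal feature columns, `cpm75`,
#'   `vmc75`, `c4`, `v4`; attribute `cuts`.
#' @examples
#' prof <- device_profile("wrist")
#' cohort <- simulate_cohort(sim_config("wrist", n_subjects = 8, seed = 1))
#' sig <- compute_minute_signals(cohort$recordings, prof)
#' bank <- build_feature_bank(sig)
#' dim(bank)
#' @export
build_feature_bank <- function(minute_signals, cuts = NULL) {
  one <- function(d) {
    fe <- dplyr::bind_cols(
      dplyr::rename_with(
        dplyr::bind_cols(statistical_features(d$enmo),
                         harmonic_features(d$enmo)),
        ~ paste0("ENMO_", .x)),
      dplyr::rename_with(
        dplyr::bind_cols(statistical_features(d$vmc),
                         harmonic_features(d$vmc)),
        ~ paste0("VMC_", .x))
    )
    p <- activity_percentile(d$cpm, d$vmc)
    fe$cpm75 <- p[["cpm75"]]
    fe$vmc75 <- p[["vmc75"]]
    fe
  }
  bank <- minute_signals |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()

  c4 <- categorize_cohort(bank$cpm75, cuts = cuts$cpm75)
  v4 <- categorize_cohort(bank$vmc75, cuts = cuts$vmc75)
  bank$c4 <- as.integer(c4)
  bank$v4 <- as.integer(v4)
  bank <- bank[, c("subject_id", signal_feature_names(),
                   "cpm75", "vmc75", "c4", "v4")]
  attr(bank, "cuts") <- list(cpm75 = attr(c4, "cuts"),
                             vmc75 = attr(v4, "cuts"))
  bank
}
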