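#' Covariate dictionaries per device profile
#'
#' The demographic and clinical covariates entering the classifiers, and
#' the category dictionaries used to encode them. The hip-cohort table has
#' 7 covariates (age, gender, race, education, monthly income category,
#' Charlson comorbidity index, baseline MoCA); the wrist-cohort table has 6
#' (no income category, and a different race/education dictionary), so the
#' encoded design matrices have 7 and 6 covariate columns respectively.
#'
#' @param profile A [device_profile()] or profile name.
#' @return `covariate_names()`: character vector of covariate column names.
#'   `covariate_dictionary()`: named list mapping each categorical
#'   covariate to its ordered category vector.
#' @export
covariate_names <- function(profile) {
  name <- if (is_device_profile(profile)) profile$name else profile
  if (name == "hip") {
    c("age", "gender", "race", "education", "income", "charlson",
      "moca_baseline")
  } else {
    c("age", "gender", "race", "education", "charlson", "moca_baseline")
  }
}

#' @rdname covariate_names
#' @export
covariate_dictionary <- function(profile) {
  name <- if (is_device_profile(profile)) profile$name else profile
  edu_common <- c("some high school", "high school graduate or GED",
                  "some college or junior college")
  if (name == "hip") {
    list(
      gender = c("male", "female"),
      race = c("Other", "African American/Black"),
      education = c(edu_common, "college graduate", "post-graduate"),
      income = c("<2000", "2000-3999", "4000-5999", ">=6000")
    )
  } else {
    list(
      gender = c("male", "female"),
      race = c("White", "Black", "Hispanic", "Other"),
      education = c(edu_common, "post-graduate")
    )
  }
}

#' Label cognitive decline from MoCA change
#'
#' Computes the cognitive change score `delta = moca_followup -
#' moca_baseline` for every subject and assigns the binary outcome:
#' `declined` is `TRUE` when `delta < 0` and `FALSE` otherwise, so subjects
#' with unchanged scores (`delta == 0`) count as non-declined. Both scores
#' must lie on the 0--30 MoCA scale; no education point correction is
#' applied (education enters the models as a covariate instead). Follow-up
#' scores may be non-integer (survey-estimated MoCA).
#'
#' Subjects with a missing baseline or follow-up score are removed from the
#' result, listed in the `excluded` attribute, and reported in a warning.
#'
#' @param covariates A data frame with columns `subject_id`,
#'   `moca_baseline`, `moca_followup`.
#' @return The input tibble with `delta` and `declined` columns added;
#'   attribute `excluded` holds the subject ids dropped for missing scores.
#' @examples
#' label_decline(tibble::tibble(subject_id = c("a", "b"),
#'                              moca_baseline = c(25, 25),
#'                              moca_followup = c(23, 25)))
#' @export
label_decline <- function(covariates) {
  stopifnot(all(c("subject_id", "moca_baseline", "moca_followup") %in%
                  names(covariates)))
  miss <- is.na(covariates$moca_baseline) | is.na(covariates$moca_followup)
  excluded <- covariates$subject_id[miss]
  if (length(excluded) > 0) {
    warning("excluding subject(s) with missing MoCA score: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  }
  out <- covariates[!miss, , drop = FALSE]
  rng <- range(c(out$moca_baseline, out$moca_followup))
  if (rng[1] < 0 || rng[2] > 30) {
    stop("MoCA scores must lie in [0, 30]", call. = FALSE)
  }
  out <- dplyr::mutate(tibble::as_tibble(out),
                       delta = .data$moca_followup - .data$moca_baseline,
                       declined = .data$delta < 0)
  attr(out, "excluded") <- excluded
  out
}

#' Encode covariates as a numeric design block
#'
#' Maps a raw covariate table to the numeric covariate columns used by the
#' classifiers: continuous covariates pass through, categorical covariates
#' are ordinal-coded against the profile's [covariate_dictionary()] (one
#' column per covariate, so the covariate block has exactly 7 columns on
#' the hip profile and 6 on the wrist profile). Gender is coded 0 = male,
#' 1 = female; other categoricals are coded 1, 2, ... in dictionary order.
#' `decode_covariates()` inverts the encoding.
#'
#' @param covariates Data frame with `subject_id` and the profile's
#'   covariate columns (see [covariate_names()]); categorical columns hold
#'   dictionary categories as strings.
#' @param profile A [device_profile()] or profile name.
#' @return A tibble: `subject_id` plus one numeric column per covariate.
#' @export
encode_covariates <- function(covariates, profile) {
  cn <- covariate_names(profile)
  dict <- covariate_dictionary(profile)
  missing_cols <- setdiff(cn, names(covariates))
  if (length(missing_cols) > 0) {
    stop("covariate table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(subject_id = covariates$subject_id)
  for (v in cn) {
    x <- covariates[[v]]
    if (v %in% names(dict)) {
      code <- match(as.character(x), dict[[v]])
      if (anyNA(code)) {
        bad <- unique(as.character(x)[is.na(code)])
        stop("unknown ", v, " category: ", paste(bad, collapse = ", "),
             "; allowed: ", paste(dict[[v]], collapse = ", "), call. = FALSE)
      }
      if (v == "gender") code <- code - 1L   # 0 = male, 1 = female
      out[[v]] <- as.double(code)
    } else {
      out[[v]] <- as.double(x)
    }
  }
  out
}

#' @rdname encode_covariates
#' @param encoded A tibble produced by `encode_covariates()`.
#' @export
decode_covariates <- function(encoded, profile) {
  dict <- covariate_dictionary(profile)
  out <- encoded
  for (v in intersect(names(dict), names(encoded))) {
    code <- encoded[[v]]
    if (v == "gender") code <- code + 1
    out[[v]] <- dict[[v]][as.integer(code)]
  }
  out
}

#' Assemble the model-ready cohort table
#'
#' Joins the accelerometry feature bank, the encoded covariates and the
#' decline labels into one row per subject: the design columns for all
#' model tiers plus the outcome. Subjects must appear in both inputs.
#'
#' @param bank Feature bank from [build_feature_bank()].
#' @param covariates Raw covariate table (with `moca_baseline`,
#'   `moca_followup`).
#' @param profile A [device_profile()].
#' @return A tibble: `subject_id`, encoded covariates, the 98 accelerometry
#'   measures (plus auxiliary `cpm75`, `vmc75`), `delta`, `declined`.
#' @export
assemble_cohort <- function(bank, covariates, profile) {
  labels <- label_decline(covariates)
  enc <- encode_covariates(labels, profile)
  enc |>
    dplyr::inner_join(bank, by = "subject_id") |>
    dplyr::inner_join(dplyr::select(labels, "subject_id", "delta", "declined"),
                      by = "subject_id")
}
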