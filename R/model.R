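#' Model tiers and their feature sets
#'
#' Three nested classifier tiers are compared:
#'
#' * `base` — demographic and clinical covariates only (7 columns on the
#'   hip profile, 6 on the wrist profile);
#' * `activity` — covariates plus the two categorical activity measures C4
#'   and V4 (9 / 8 columns);
#' * `full` — covariates, C4/V4 and the 96 per-signal statistical and
#'   harmonic features (105 / 104 columns).
#'
#' `tier_features()` returns the design column names for a tier;
#' `tier_feature_counts()` returns the expected column counts, which
#' [run_tiers()] asserts before fitting.
#'
#' @param profile A [device_profile()] or profile name.
#' @param tier `"base"`, `"activity"` or `"full"`.
#' @return `tier_features()`: character vector of design column names;
#'   `tier_feature_counts()`: named integer vector over the three tiers.
#' @export
tier_features <- function(profile, tier = c("base", "activity", "full")) {
  tier <- match.arg(tier)
  cov <- covariate_names(profile)
  switch(tier,
    base = cov,
    activity = c(cov, "c4", "v4"),
    full = c(cov, "c4", "v4", signal_feature_names())
  )
}

#' @rdname tier_features
#' @export
tier_feature_counts <- function(profile) {
  name <- if (is_device_profile(profile)) profile$name else profile
  if (name == "hip") {
    c(base = 7L, activity = 9L, full = 105L)
  } else {
    c(base = 6L, activity = 8L, full = 104L)
  }
}

#' Split a cohort into training and hold-out sets
#'
#' Randomly reserves a hold-out fraction of the cohort — 10% on the hip
#' profile, 15% on the wrist profile — for final evaluation; the rest is
#' the training set used for cross-validated tuning. The hold-out size is
#' `floor(fraction * n)`, allocated across the two outcome classes
#' proportionally (largest-remainder rounding) so a class cannot vanish
#' from the hold-out by chance. The split is a deterministic function of
#' `seed` and is recorded in the returned manifest.
#'
#' @param cohort A cohort tibble from [assemble_cohort()] (must contain
#'   `declined`).
#' @param profile A [device_profile()].
#' @param seed Integer seed controlling the split.
#' @param holdout_frac Override for the profile's hold-out fraction.
#' @return A list of class `cd_split`: `train`, `holdout` (tibbles) and
#'   `manifest` (seed, fraction, hold-out subject ids).
#' @export
make_split <- function(cohort, profile, seed, holdout_frac = NULL) {
  assert_profile(profile)
  frac <- if (!is.null(holdout_frac)) holdout_frac
          else if (profile$name == "hip") 0.10 else 0.15
  n <- nrow(cohort)
  n_hold <- floor(frac * n)
  if (n_hold < 1) {
    stop("cohort too small for a non-empty hold-out at fraction ", frac,
         call. = FALSE)
  }
  cls <- split(seq_len(n), cohort$declined)
  quota <- n_hold * vapply(cls, length, 1L) / n
  take <- floor(quota)
  rem <- order(quota - take, decreasing = TRUE)
  short <- n_hold - sum(take)
  if (short > 0) take[rem[seq_len(short)]] <- take[rem[seq_len(short)]] + 1L
  hold_idx <- withr::with_seed(seed, {
    sort(unlist(Map(function(idx, k) sample(idx, k), cls, take),
                use.names = FALSE))
  })
  structure(list(
    train = cohort[-hold_idx, , drop = FALSE],
    holdout = cohort[hold_idx, , drop = FALSE],
    manifest = list(seed = seed, holdout_frac = frac,
                    holdout_ids = cohort$subject_id[hold_idx])
  ), class = "cd_split")
}

#' Hyperparameter grids for gradient-boosted tuning
#'
#' `default_grid()` is the grid searched by [tune_and_train()]: tree depth
#' 2--4, learning rate 0.05/0.1/0.3, 50--200 boosting rounds, row
#' subsampling 0.8/1 — 54 configurations sized to cohorts of a few hundred
#' subjects. `quick_grid()` is a 4-configuration subset (depth 2--3,
#' learning rate 0.1, 50/100 rounds, no subsampling) for simulation
#' studies that refit models over many seeds.
#'
#' @return A data frame with columns `max_depth`, `eta`, `nrounds`,
#'   `subsample`, one row per configuration.
#' @export
default_grid <- function() {
  expand.grid(max_depth = 2:4, eta = c(0.05, 0.1, 0.3),
              nrounds = c(50L, 100L, 200L), subsample = c(0.8, 1),
              KEEP.OUT.ATTRS = FALSE)
}

#' @rdname default_grid
#' @export
quick_grid <- function() {
  expand.grid(max_depth = 2:3, eta = 0.1, nrounds = c(50L, 100L),
              subsample = 1, KEEP.OUT.ATTRS = FALSE)
}

design_matrix <- function(data, feats) {
  miss <- setdiff(feats, names(data))
  if (length(miss) > 0) {
    stop("design columns missing from cohort: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(data[, feats, drop = FALSE])
  storage.mode(X) <- "double"
  X
}

auc_score <- function(y, p) {
  if (length(unique(y)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = p,
                                 levels = c(FALSE, TRUE), direction = "<",
                                 quiet = TRUE)))
}

fit_booster <- function(X, y, params, nrounds, seed) {
  xgboost::xgb.train(
    params = c(params, list(objective = "binary:logistic",
                            eval_metric = "logloss",
                            nthread = 1, seed = seed)),
    data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
    nrounds = nrounds, verbose = 0
  )
}

#' Tune and fit a gradient-boosted decline classifier
#'
#' Fits an XGBoost binary classifier for one model tier. Hyperparameters
#' are selected over `grid` by stratified 5-fold cross-validation on the
#' training set, maximizing the mean fold AUC; ties go to the earlier grid
#' row. The winning configuration is then refit on the full training set.
#' The fold AUCs of the winning configuration are retained — their
#' standard deviation is the AUC spread reported alongside hold-out
#' performance.
#'
#' @param train Training tibble (from [make_split()]).
#' @param tier Model tier, see [tier_features()].
#' @param profile A [device_profile()].
#' @param seed Integer seed controlling folds and fitting.
#' @param grid Hyperparameter grid, see [default_grid()].
#' @param nfold Number of CV folds (default 5).
#' @return An object of class `cd_model`: the fitted booster plus tier,
#'   feature names, selected hyperparameters, CV fold AUCs and the seed.
#' @examples
#' \donttest{
#' prof <- device_profile("wrist")
#' cohort <- simulate_cohort(sim_config("wrist", n_subjects = 60, seed = 2))
#' dat <- process_cohort(cohort, prof)
#' sp <- make_split(dat, prof, seed = 2)
#' fit <- tune_and_train(sp$train, "base", prof, seed = 2, grid = quick_grid())
#' glance(evaluate(fit, sp$holdout))
#' }
#' @export
tune_and_train <- function(train, tier = c("base", "activity", "full"),
                           profile, seed, grid = default_grid(), nfold = 5) {
  tier <- match.arg(tier)
  assert_profile(profile)
  feats <- tier_features(profile, tier)
  X <- design_matrix(train, feats)
  y <- as.integer(train$declined)
  if (min(table(y)) < nfold) {
    stop("need at least ", nfold, " subjects per class to form stratified ",
         nfold, "-fold CV", call. = FALSE)
  }
  folds <- withr::with_seed(seed, {
    f <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      f[idx] <- sample(rep_len(seq_len(nfold), length(idx)))
    }
    f
  })

  cv_mat <- matrix(NA_real_, nrow = nrow(grid), ncol = nfold)
  for (g in seq_len(nrow(grid))) {
    pars <- list(max_depth = grid$max_depth[g], eta = grid$eta[g],
                 subsample = grid$subsample[g])
    for (k in seq_len(nfold)) {
      tr <- folds != k
      fit <- fit_booster(X[tr, , drop = FALSE], y[tr], pars,
                         grid$nrounds[g], seed)
      p <- predict(fit, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE],
                                             nthread = 1))
      cv_mat[g, k] <- auc_score(y[!tr] == 1L, p)
    }
  }
  mean_auc <- rowMeans(cv_mat)
  best <- which.max(mean_auc)
  best_pars <- list(max_depth = grid$max_depth[best], eta = grid$eta[best],
                    subsample = grid$subsample[best],
                    nrounds = grid$nrounds[best])
  booster <- fit_booster(X, y, best_pars[c("max_depth", "eta", "subsample")],
                         best_pars$nrounds, seed)
  structure(list(
    booster = booster, tier = tier, profile = profile$name,
    feature_names = feats, best_params = best_pars,
    cv_auc = cv_mat[best, ], cv_auc_mean = mean_auc[best],
    n_train = nrow(X), seed = seed
  ), class = "cd_model")
}

#' @export
print.cd_model <- function(x, ...) {
  cat("<cd_model> tier '", x$tier, "' (", x$profile, " profile), ",
      length(x$feature_names), " features, n_train = ", x$n_train, "\n",
      sep = "")
  cat("  CV AUC ", sprintf("%.3f (sd %.3f)", x$cv_auc_mean,
                           stats::sd(x$cv_auc)),
      "; params: depth ", x$best_params$max_depth,
      ", eta ", x$best_params$eta,
      ", rounds ", x$best_params$nrounds,
      ", subsample ", x$best_params$subsample, "\n", sep = "")
  invisible(x)
}

#' @export
predict.cd_model <- function(object, newdata, ...) {
  X <- design_matrix(newdata, object$feature_names)
  predict(object$booster, xgboost::xgb.DMatrix(X, nthread = 1))
}

#' Evaluate a fitted classifier on the hold-out set
#'
#' Scores hold-out subjects with a fitted [tune_and_train()] model and
#' assembles the standard report surface: accuracy at the 0.5 probability
#' threshold, ROC-AUC (with the CV-fold AUC spread carried over from
#' tuning), the 2x2 confusion matrix, and feature importances (total
#' gain) ranked in decreasing order with zero-importance features
#' excluded. If the hold-out happens to contain a single outcome class the
#' AUC is reported as missing with a warning.
#'
#' @param model A `cd_model`.
#' @param holdout Hold-out tibble, disjoint from the training set.
#' @return An object of class `cd_eval` with elements `tier`, `accuracy`,
#'   `auc`, `auc_sd`, `confusion` (2x2 matrix, predicted x actual),
#'   `importance` (tibble `feature`, `gain`), `predictions` (per-subject
#'   probabilities), `n_holdout`, `seed`.
#' @export
evaluate <- function(model, holdout) {
  stopifnot(inherits(model, "cd_model"))
  p <- predict(model, holdout)
  y <- holdout$declined
  pred <- p >= 0.5
  lv <- c("stable", "declined")
  confusion <- table(
    predicted = factor(ifelse(pred, "declined", "stable"), levels = lv),
    actual = factor(ifelse(y, "declined", "stable"), levels = lv)
  )
  auc <- auc_score(y, p)
  if (is.na(auc)) {
    warning("hold-out contains a single class; AUC undefined", call. = FALSE)
  }
  imp <- xgboost::xgb.importance(model = model$booster)
  importance <- tibble::tibble(feature = imp$Feature, gain = imp$Gain) |>
    dplyr::filter(.data$gain > 0) |>
    dplyr::arrange(dplyr::desc(.data$gain))
  structure(list(
    tier = model$tier, profile = model$profile,
    n_features = length(model$feature_names),
    accuracy = mean(pred == y), auc = auc,
    auc_sd = stats::sd(model$cv_auc),
    confusion = confusion, importance = importance,
    predictions = tibble::tibble(subject_id = holdout$subject_id,
                                 prob = p, actual = y),
    n_holdout = nrow(holdout), seed = model$seed
  ), class = "cd_eval")
}

#' @export
print.cd_eval <- function(x, ...) {
  cat("<cd_eval> tier '", x$tier, "' (", x$profile, " profile), hold-out n = ",
      x$n_holdout, "\n", sep = "")
  cat(sprintf("  accuracy %.3f, AUC %s (sd %.3f)\n", x$accuracy,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc)), x$auc_sd))
  print(x$confusion)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the ranked feature importances of an evaluation
#'
#' @param x A `cd_eval` object.
#' @param ... Unused.
#' @return A tibble `feature`, `gain` in decreasing importance.
#' @export
tidy.cd_eval <- function(x, ...) x$importance

#' One-row performance summary of an evaluation
#'
#' @param x A `cd_eval` object.
#' @param ... Unused.
#' @return A one-row tibble: `tier`, `n_features`, `n_holdout`,
#'   `accuracy`, `auc`, `auc_sd`.
#' @export
glance.cd_eval <- function(x, ...) {
  tibble::tibble(tier = x$tier, n_features = x$n_features,
                 n_holdout = x$n_holdout, accuracy = x$accuracy,
                 auc = x$auc, auc_sd = x$auc_sd)
}

#' Run the three model tiers on one cohort split
#'
#' The main modeling entry point: splits the cohort once (see
#' [make_split()]), then tunes, fits and evaluates the `base`, `activity`
#' and `full` tiers on that same split. Before each fit the design-column
#' count is asserted against [tier_feature_counts()] (7/9/105 on the hip
#' profile, 6/8/104 on the wrist profile); a mismatch is a hard error.
#'
#' By default the C4/V4 quartile cut-points are refitted on the training
#' subjects only and applied to the hold-out, so no information from
#' held-out subjects enters the design (`refit_cuts = FALSE` reproduces
#' cohort-wide binning instead).
#'
#' @param cohort Cohort tibble from [assemble_cohort()] /
#'   [process_cohort()].
#' @param profile A [device_profile()].
#' @param seed Integer seed for split, folds and fits.
#' @param grid Hyperparameter grid (see [default_grid()]).
#' @param tiers Tiers to run (default all three).
#' @param refit_cuts Refit C4/V4 cut-points on the training set only.
#' @return An object of class `cd_tier_report`: named list `reports` of
#'   [evaluate()] results, a `summary` tibble, and the split `manifest`.
#' @examples
#' \donttest{
#' prof <- device_profile("wrist")
#' cohort <- simulate_cohort(sim_config("wrist", n_subjects = 60, seed = 3))
#' rep <- run_tiers(process_cohort(cohort, prof), prof, seed = 3,
#'                  grid = quick_grid())
#' glance(rep)
#' }
#' @export
run_tiers <- function(cohort, profile, seed, grid = default_grid(),
                      tiers = c("base", "activity", "full"),
                      refit_cuts = TRUE) {
  assert_profile(profile)
  sp <- make_split(cohort, profile, seed)
  train <- sp$train
  holdout <- sp$holdout
  if (refit_cuts && all(c("cpm75", "vmc75") %in% names(cohort))) {
    cuts <- list(
      cpm75 = stats::quantile(train$cpm75, c(0.25, 0.5, 0.75),
                              names = FALSE, type = 7),
      vmc75 = stats::quantile(train$vmc75, c(0.25, 0.5, 0.75),
                              names = FALSE, type = 7)
    )
    rebin <- function(d) {
      d$c4 <- as.integer(categorize_cohort(d$cpm75, cuts = cuts$cpm75))
      d$v4 <- as.integer(categorize_cohort(d$vmc75, cuts = cuts$vmc75))
      d
    }
    train <- rebin(train)
    holdout <- rebin(holdout)
  }
  expected <- tier_feature_counts(profile)
  reports <- list()
  for (tier in tiers) {
    feats <- tier_features(profile, tier)
    if (length(feats) != expected[[tier]]) {
      stop("tier '", tier, "' has ", length(feats),
           " design columns; expected ", expected[[tier]], call. = FALSE)
    }
    model <- tune_and_train(train, tier, profile, seed, grid = grid)
    reports[[tier]] <- evaluate(model, holdout)
  }
  structure(list(
    reports = reports,
    summary = dplyr::bind_rows(lapply(reports, glance)),
    manifest = sp$manifest
  ), class = "cd_tier_report")
}

#' @export
print.cd_tier_report <- function(x, ...) {
  cat("<cd_tier_report> seed ", x$manifest$seed, ", hold-out n = ",
      length(x$manifest$holdout_ids), "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname run_tiers
#' @param x A `cd_tier_report`.
#' @param ... Unused.
#' @export
glance.cd_tier_report <- function(x, ...) x$summary
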