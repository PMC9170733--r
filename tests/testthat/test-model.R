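test_that("hold-out sizes follow the per-profile fractions", {
  hip <- device_profile("hip")
  wrist <- device_profile("wrist")
  co115 <- toy_model_cohort(115, profile = hip)
  sp <- make_split(co115, hip, seed = 1)
  expect_equal(nrow(sp$holdout), 11)   # floor(0.10 * 115)
  expect_equal(nrow(sp$train), 104)

  co575 <- toy_model_cohort(575, profile = wrist)
  sp2 <- make_split(co575, wrist, seed = 1)
  expect_equal(nrow(sp2$holdout), 86)  # floor(0.15 * 575)

  # both classes are represented in the hold-out
  expect_true(all(table(sp$holdout$declined) >= 1))
  expect_error(make_split(co115[1:5, ], hip, seed = 1), "too small")
})

test_that("splits are deterministic and leak-free", {
  hip <- device_profile("hip")
  co <- toy_model_cohort(115, profile = hip)
  a <- make_split(co, hip, seed = 7)
  b <- make_split(co, hip, seed = 7)
  expect_identical(a$manifest, b$manifest)
  expect_false(identical(a$manifest$holdout_ids,
                         make_split(co, hip, seed = 8)$manifest$holdout_ids))
  expect_length(intersect(a$train$subject_id, a$holdout$subject_id), 0)
  expect_setequal(c(a$train$subject_id, a$holdout$subject_id), co$subject_id)
})

test_that("CV tuning separates a planted signal and not a permuted one", {
  wrist <- device_profile("wrist")
  co <- toy_model_cohort(80, separable = TRUE, seed = 31, profile = wrist)
  fit <- tune_and_train(co, "base", wrist, seed = 31, grid = quick_grid())
  expect_gt(fit$cv_auc_mean, 0.95)

  # label permutation kills the signal: null CV AUC hovers at chance
  null_auc <- vapply(1:10, function(i) {
    perm <- co
    perm$declined <- withr::with_seed(100 + i, sample(co$declined))
    tune_and_train(perm, "base", wrist, seed = 31,
                   grid = quick_grid()[1, ])$cv_auc_mean
  }, 0)
  expect_gt(mean(null_auc), 0.35)
  expect_lt(mean(null_auc), 0.65)
})

test_that("tuning is a deterministic function of seed and grid", {
  wrist <- device_profile("wrist")
  co <- toy_model_cohort(60, seed = 32, profile = wrist)
  f1 <- tune_and_train(co, "activity", wrist, seed = 5, grid = quick_grid())
  f2 <- tune_and_train(co, "activity", wrist, seed = 5, grid = quick_grid())
  expect_identical(f1$best_params, f2$best_params)
  expect_identical(f1$cv_auc, f2$cv_auc)
  expect_error(tune_and_train(co[1:8, ], "base", wrist, seed = 1),
               "per class")
})

test_that("evaluation reports accuracy, AUC, confusion and importances", {
  wrist <- device_profile("wrist")
  co <- toy_model_cohort(100, separable = TRUE, seed = 33, profile = wrist)
  sp <- make_split(co, wrist, seed = 33)
  fit <- tune_and_train(sp$train, "base", wrist, seed = 33,
                        grid = quick_grid())
  ev <- evaluate(fit, sp$holdout)

  # a cleanly separable problem is classified perfectly on hold-out
  expect_equal(ev$accuracy, 1)
  expect_equal(sum(ev$confusion), ev$n_holdout)
  expect_equal(ev$confusion["stable", "declined"] +
                 ev$confusion["declined", "stable"], 0, ignore_attr = TRUE)
  expect_equal(ev$auc, 1)

  # accuracy always re-derives from the confusion matrix diagonal
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / ev$n_holdout)
  # importances are descending and strictly positive
  expect_true(all(diff(ev$importance$gain) <= 0))
  expect_true(all(ev$importance$gain > 0))
  expect_equal(glance(ev)$accuracy, ev$accuracy)
  expect_equal(nrow(tidy(ev)), nrow(ev$importance))
})

test_that("single-class hold-outs yield a missing AUC with a warning", {
  wrist <- device_profile("wrist")
  co <- toy_model_cohort(60, seed = 34, profile = wrist)
  sp <- make_split(co, wrist, seed = 34)
  fit <- tune_and_train(sp$train, "base", wrist, seed = 34,
                        grid = quick_grid()[1, ])
  onecls <- dplyr::filter(sp$holdout, !declined)
  expect_warning(ev <- evaluate(fit, onecls), "single class")
  expect_true(is.na(ev$auc))
})

test_that("run_tiers enforces the tier feature accounting", {
  wrist <- device_profile("wrist")
  expect_equal(unname(tier_feature_counts("hip")), c(7L, 9L, 105L))
  expect_equal(unname(tier_feature_counts("wrist")), c(6L, 8L, 104L))
  co <- toy_model_cohort(60, seed = 35, profile = wrist)
  rep1 <- run_tiers(co, wrist, seed = 35, grid = quick_grid()[1, ])
  expect_equal(rep1$summary$n_features, c(6L, 8L, 104L))
  expect_equal(nrow(rep1$summary), 3)

  # same seed -> identical reports
  rep2 <- run_tiers(co, wrist, seed = 35, grid = quick_grid()[1, ])
  expect_equal(rep1$summary, rep2$summary)
  expect_identical(rep1$manifest, rep2$manifest)

  # a cohort missing design columns is rejected
  broken <- dplyr::select(co, -dplyr::all_of("VMC_mean"))
  expect_error(run_tiers(broken, wrist, seed = 35, grid = quick_grid()[1, ]),
               "VMC_mean")
})

test_that("plot and summary methods return well-formed objects", {
  wrist <- device_profile("wrist")
  co <- toy_model_cohort(80, separable = TRUE, seed = 36, profile = wrist)
  rep <- run_tiers(co, wrist, seed = 36, grid = quick_grid()[1, ],
                   tiers = c("base", "full"))
  ev <- rep$reports$full
  expect_s3_class(autoplot(ev, "roc"), "ggplot")
  expect_s3_class(autoplot(ev, "importance"), "ggplot")
  expect_s3_class(autoplot(ev, "confusion"), "ggplot")
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(glance(rep), "tbl_df")
})
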