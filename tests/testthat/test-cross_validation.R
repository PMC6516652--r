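test_that("observed DI and the category partition behave at the bounds", {
  obs <- data.frame(extirpated = c(FALSE, TRUE, FALSE, FALSE),
                    rr = c(0, NA, log(0.3), 0.7))
  di <- observed_di(obs)
  expect_equal(di, c(0, 1, 0.7, 0))  # increases floor at 0
  expect_true(all(di >= 0 & di <= 1))

  expect_equal(as.character(categorize_di(c(0, 0.1, 0.100001, 0.7,
                                            0.700001, 1))),
               c("low", "low", "moderate", "moderate", "high", "high"))
  # every DI in [0,1] lands in exactly one category
  expect_false(anyNA(categorize_di(seq(0, 1, by = 0.001))))
})

test_that("kfold_split is deterministic, balanced, and honors grouping", {
  db <- generate_database(small_cfg(), seed = 41)
  obs <- db$records[1:100, ]
  f1 <- kfold_split(obs, k = 5, seed = 7)
  f2 <- kfold_split(obs, k = 5, seed = 7)
  expect_identical(f1, f2)
  expect_equal(unname(table(f1)), rep(20L, 5), ignore_attr = TRUE)
  expect_false(identical(f1, kfold_split(obs, k = 5, seed = 8)))

  fs <- kfold_split(db$records, k = 5, seed = 7, grouping = "study")
  straddle <- tapply(fs, db$records$study_id,
                     function(x) length(unique(x)))
  expect_true(all(straddle == 1))
  expect_error(kfold_split(obs[1:3, ], k = 5), "k exceeds")
  expect_error(kfold_split(data.frame(study_id = c("a", "b")), k = 5,
                           grouping = "study"), "k exceeds")
})

test_that("confusion-matrix metrics equal hand-computed one-vs-rest values", {
  cm <- matrix(c(8, 1, 1,
                 1, 5, 1,
                 1, 1, 7), 3, 3, byrow = TRUE,
               dimnames = list(predicted = c("low", "moderate", "high"),
                               observed = c("low", "moderate", "high")))
  met <- accuracy_metrics(cm)
  # low: TP=8, FN=2, FP=2, TN=14 (n=26)
  expect_equal(unname(met$sensitivity["low"]), 8 / 10)
  expect_equal(unname(met$specificity["low"]), 14 / 16)
  expect_equal(unname(met$balanced_accuracy["low"]),
               (8 / 10 + 14 / 16) / 2)
  expect_equal(unname(met$sensitivity["moderate"]), 5 / 7)
  expect_equal(unname(met$specificity["moderate"]), 17 / 19)
  expect_equal(unname(met$sensitivity["high"]), 7 / 9)
  expect_equal(unname(met$specificity["high"]), 15 / 17)
  expect_equal(met$overall_balanced_accuracy,
               mean(met$balanced_accuracy))

  # pooled metrics equal brute-force recomputation from raw pairs
  withr::with_seed(10, {
    pred <- sample(c("low", "moderate", "high"), 300, TRUE)
    obs <- sample(c("low", "moderate", "high"), 300, TRUE)
  })
  cm2 <- confusion_matrix(factor(pred), factor(obs))
  met2 <- accuracy_metrics(cm2)
  for (lev in c("low", "moderate", "high")) {
    expect_equal(unname(met2$sensitivity[lev]),
                 sum(pred == lev & obs == lev) / sum(obs == lev))
    expect_equal(unname(met2$specificity[lev]),
                 sum(pred != lev & obs != lev) / sum(obs != lev))
  }
})

test_that("a perfect predictor scores 1 everywhere; random ~0.5 balanced accuracy", {
  obs <- factor(rep(c("low", "moderate", "high"), times = c(20, 15, 25)),
                levels = c("low", "moderate", "high"))
  met <- accuracy_metrics(confusion_matrix(obs, obs))
  expect_equal(unname(met$sensitivity), rep(1, 3))
  expect_equal(unname(met$specificity), rep(1, 3))
  expect_equal(met$overall_balanced_accuracy, 1)

  withr::with_seed(2, {
    lev <- c("low", "moderate", "high")
    pred <- factor(sample(lev, 10000, TRUE), levels = lev)
    obs <- factor(sample(lev, 10000, TRUE), levels = lev)
  })
  met <- accuracy_metrics(confusion_matrix(pred, obs))
  expect_lt(abs(met$overall_balanced_accuracy - 0.5), 0.05)
})

test_that("evaluate_hurdle pools folds and reports a coherent accuracy report", {
  db <- generate_database(small_cfg(), seed = 43)
  rep <- suppressWarnings(evaluate_hurdle(db$records, k = 5, seed = 3))
  expect_s3_class(rep, "accuracy_report")
  expect_equal(sum(rep$confusion), nrow(db$records))
  expect_equal(rep$n_test, nrow(db$records))
  expect_false(rep$incomplete)
  expect_true(rep$pseudo_r2 > 0 && rep$pseudo_r2 <= 1)
  expect_equal(unname(rep$balanced_accuracy),
               unname((rep$sensitivity + rep$specificity) / 2))
  # pooled pairs reproduce the reported pseudo-R2 and it is affine invariant
  expect_equal(rep$pseudo_r2, cor(rep$predicted, rep$observed)^2)
  expect_equal(cor(2 * rep$predicted + 1, rep$observed)^2, rep$pseudo_r2,
               tolerance = 1e-12)
  # and the confusion matrix matches brute-force recomputation
  expect_identical(
    unname(as.matrix(rep$confusion)),
    unname(as.matrix(confusion_matrix(categorize_di(rep$predicted),
                                      categorize_di(rep$observed)))))
})

test_that("a degenerate predictor yields pseudo-R2 0 with a flag", {
  # a world where everything is extirpated: the gaussian stage cannot fit,
  # folds are skipped, and the report says so instead of inventing numbers
  cfg <- small_cfg(n_studies = 10, records_per_study = 10,
                   beta_binomial = c(intercept = -50))
  db <- generate_database(cfg, seed = 44)
  expect_true(all(db$records$extirpated))
  rep <- suppressWarnings(evaluate_hurdle(db$records, k = 2, seed = 1))
  expect_true(rep$incomplete)
  expect_equal(rep$pseudo_r2, 0)
  expect_true(rep$pseudo_r2_degenerate)
})
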