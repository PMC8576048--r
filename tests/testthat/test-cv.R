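test_that("improvement rate follows the pre/post definition", {
  expect_equal(improvement_rate(40, 10), 0.75)
  expect_equal(improvement_rate(50, 50), 0)
  # on the reported group-mean scores the ratio of means is ~0.649, which is
  # intentionally NOT the reported mean per-patient rate (~0.656): the mean
  # of ratios is not the ratio of means
  expect_equal(improvement_rate(43.79, 15.35), 28.44 / 43.79, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(improvement_rate(43.79, 15.35), 0.6562,
                                tolerance = 1e-3)))
  expect_equal(improvement_rate(c(40, 50), c(10, 50)), c(0.75, 0))
  expect_error(improvement_rate(0, 1), "positive")
  expect_error(improvement_rate(10, -2), "non-negative")
})

test_that("evaluate returns r, the t-transform p and squared correlation", {
  x <- c(0.3, 0.5, 0.9, 0.2, 0.7)
  ev <- evaluate(x, x)
  expect_equal(ev$pearson_r, 1)
  expect_lt(ev$pearson_p, 1e-10)
  ev2 <- evaluate(-x, x)
  expect_equal(ev2$pearson_r, -1)
  set.seed(30)
  a <- rnorm(20); b <- rnorm(20)
  ev3 <- evaluate(a, b)
  ct <- cor.test(a, b)
  expect_equal(ev3$pearson_r, unname(ct$estimate))
  expect_equal(ev3$pearson_p, ct$p.value)
  expect_equal(ev3$r_squared, ev3$pearson_r^2)
  expect_error(evaluate(rep(1, 5), rnorm(5)), "constant")
  expect_error(evaluate(1:2, 2:3), "at least 3")
})

test_that("the t-transform p at r = 0.37, N = 55 is of the reported order", {
  p <- pearson_p_from_r(0.37, 55)
  expect_equal(p, 0.0054, tolerance = 0.02)
  # same order of magnitude as the published 5.68e-3 pairing
  expect_lt(abs(log10(p / 5.68e-3)), 0.2)
})

test_that("the t-transform p matches a permutation p within Monte-Carlo error", {
  set.seed(31)
  n <- 25
  a <- rnorm(n)
  b <- 0.4 * a + rnorm(n, 0, 1)
  r_obs <- cor(a, b)
  perm <- replicate(2000, abs(cor(a, sample(b))))
  p_perm <- (1 + sum(perm >= abs(r_obs))) / 2001
  expect_lt(abs(pearson_p_from_r(r_obs, n) - p_perm),
            0.04 + 3 * sqrt(p_perm * (1 - p_perm) / 2000))
})

test_that("nested LOOCV recovers a planted signal out of sample", {
  hp <- small_planted_cohort(n_subjects = 30, seed = 11)
  cv <- nested_loocv(hp$features, hp$y, seed = 1)
  expect_gt(cv$pearson_r, 0.5)
  expect_equal(nrow(cv$predictions), 30)
  expect_equal(cv$predictions$subject_id, hp$cohort$subjects$subject_id)
  # planted edges selected in most folds
  planted <- paste(hp$planted$i, hp$planted$j, sep = "-")
  hits <- vapply(cv$fold_features, function(s) sum(planted %in% s$feature), 0)
  expect_gt(mean(hits == 2), 0.7)
})

test_that("nested LOOCV is deterministic and leak-free", {
  hp <- small_planted_cohort(n_subjects = 12, seed = 12)
  cv1 <- suppressMessages(nested_loocv(hp$features, hp$y, seed = 2))
  cv2 <- suppressMessages(nested_loocv(hp$features, hp$y, seed = 2))
  expect_identical(cv1$predictions, cv2$predictions)

  # corrupting a held-out subject's outcome must not change its prediction:
  # subject s is absent from every stage of its own training fold
  y_mut <- hp$y
  y_mut[5] <- 0.99
  cv3 <- suppressMessages(nested_loocv(hp$features, y_mut, seed = 2))
  expect_identical(cv3$predictions$predicted_rate[5],
                   cv1$predictions$predicted_rate[5])
})

test_that("duplicate subject ids are rejected", {
  hp <- small_planted_cohort(n_subjects = 12, seed = 14)
  x <- hp$features
  rownames(x)[2] <- rownames(x)[1]
  expect_error(nested_loocv(x, hp$y, seed = 1), "duplicate subject_id")
  expect_error(nested_loocv(hp$features[1:5, ], hp$y[1:5], seed = 1),
               "at least 10")
})

test_that("under shuffled outcomes LOOCV predictions do not show positive skill", {
  # Null Monte-Carlo: with outcomes permuted against features, cross-validated
  # predictions gravitate toward each fold's training mean, which is weakly
  # anti-correlated with the held-out outcome. r must therefore not be
  # significantly positive; strong negative values are an expected artifact
  # of correlation-evaluated LOOCV, not leakage.
  hp <- small_planted_cohort(n_subjects = 20, seed = 15)
  y_shuf <- hp$y[c(11:20, 1:10)] # fixed derangement-style shuffle
  cv <- suppressMessages(nested_loocv(hp$features, y_shuf, seed = 3))
  expect_lt(cv$pearson_r, 0.3)
})

test_that("global selection scope selects once and reuses the edge set", {
  hp <- small_planted_cohort(n_subjects = 14, seed = 16)
  cv <- suppressMessages(
    nested_loocv(hp$features, hp$y, selection_scope = "global", seed = 4))
  sets <- unique(vapply(cv$fold_features,
                        function(s) paste(s$feature, collapse = ","), ""))
  expect_length(sets, 1)
  # supplying a precomputed selection gives the same result
  fc <- forest_control()
  fc$seed <- derive_seed(4, "global-selection")
  fit <- fit_forest(hp$features, hp$y, fc)
  sel <- select_features(oob_importance(fit, hp$features, hp$y, fc))
  cv2 <- suppressMessages(nested_loocv(hp$features, hp$y, selected = sel, seed = 4))
  expect_identical(cv$predictions, cv2$predictions)
})

test_that("cpm wraps CV and final model with working methods", {
  hp <- small_planted_cohort(n_subjects = 20, seed = 17)
  fit <- suppressMessages(cpm(hp$features, hp$y, seed = 5))
  expect_s3_class(fit, "cpm")
  expect_output(print(fit), "Pearson r")
  expect_output(print(summary(fit)), "selection scope")
  expect_named(coef(fit)[1], "(Intercept)")
  expect_equal(unname(fitted(fit)), fit$cv$predictions$predicted_rate)
  expect_equal(unname(residuals(fit)),
               hp$y - fit$cv$predictions$predicted_rate)
  # predict on the training features reproduces the final in-sample fit
  pr <- predict(fit, hp$features)
  expect_length(pr, 20)
  expect_true(all(is.finite(pr)))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
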