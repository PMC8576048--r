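# Random-forest OOB permutation importance: determinism, the importance
# statistic against an independent loop-based oracle, and the selection rule.

make_regression_data <- function(n, d, seed, signal_cols = 1L, noise_sd = 0.2) {
  set.seed(seed)
  x <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("f", 1:d)))
  y <- rowSums(x[, signal_cols, drop = FALSE]) * 0.3 + rnorm(n, 0, noise_sd)
  list(x = x, y = y)
}

test_that("forest fits are deterministic given the seed", {
  dat <- make_regression_data(20, 4, seed = 1)
  ctl <- forest_control(n_trees = 10, seed = 42)
  f1 <- fit_forest(dat$x, dat$y, ctl)
  f2 <- fit_forest(dat$x, dat$y, ctl)
  expect_identical(f1$inbag, f2$inbag)
  expect_identical(f1$oob, f2$oob)
  i1 <- oob_importance(f1, dat$x, dat$y)
  i2 <- oob_importance(f2, dat$x, dat$y)
  expect_identical(i1$importance, i2$importance)
})

test_that("bootstrap OOB fraction matches the (1 - 1/N)^N expectation", {
  dat <- make_regression_data(20, 2, seed = 2)
  fit <- fit_forest(dat$x, dat$y, forest_control(n_trees = 300, seed = 3))
  frac <- mean(lengths(fit$oob)) / 20
  expect_lt(abs(frac - (1 - 1 / 20)^20), 0.03)
  expect_true(all(lengths(fit$oob) > 0))
})

test_that("empty OOB sets are redrawn at small N", {
  # at N = 5 a bootstrap covers all subjects ~3.8% of the time, so 200 trees
  # exercise the redraw path with near-certainty
  dat <- make_regression_data(5, 2, seed = 4)
  fit <- fit_forest(dat$x, dat$y, forest_control(n_trees = 200, seed = 5))
  expect_true(all(lengths(fit$oob) > 0))
  expect_error(fit_forest(dat$x[1:4, ], dat$y[1:4]), "at least 5")
})

test_that("a perfectly learnable signal is fitted to near-zero training error", {
  set.seed(6)
  x <- matrix(rnorm(40), 40, 1, dimnames = list(NULL, "f1"))
  y <- 2 * x[, 1]
  fit <- fit_forest(x, y, forest_control(n_trees = 50, seed = 6))
  pred <- predict(fit$forest, data = x, num.threads = 1)$predictions
  expect_lt(mean((pred - y)^2), 0.05 * var(y))
})

test_that("importance of a constant feature is exactly zero under permutation", {
  dat <- make_regression_data(25, 3, seed = 7)
  x <- cbind(dat$x, flat = rep(1.5, 25))
  fit <- fit_forest(x, dat$y, forest_control(n_trees = 20, seed = 7))
  imp <- oob_importance(fit, x, dat$y)
  expect_identical(imp$importance[imp$feature == "flat"], 0)
})

test_that("an outcome-independent feature has importance below the threshold", {
  # outcome on the improvement-rate scale (total SD ~0.2 as for UPDRS
  # rates); a single draw sits at the noise floor, so average a few seeds
  imp4 <- vapply(8:12, function(seed) {
    set.seed(seed)
    x <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("f", 1:4)))
    y <- 0.12 * x[, 1] + rnorm(60, 0, 0.16)
    fit <- fit_forest(x, y, forest_control(n_trees = 20, seed = seed))
    oob_importance(fit, x, y)$importance[4]
  }, 0)
  expect_lt(abs(mean(imp4)), 0.005)
})

test_that("importance matches the independent loop-based oracle to 1e-12", {
  dat <- make_regression_data(10, 3, seed = 9)
  ctl <- forest_control(n_trees = 3, max_depth = 2, seed = 10)
  fit <- fit_forest(dat$x, dat$y, ctl)
  imp <- oob_importance(fit, dat$x, dat$y, ctl)
  oracle <- brute_force_importance(fit, dat$x, dat$y, ctl)
  expect_equal(imp$importance, oracle, tolerance = 1e-12)
  expect_equal(mean(vapply(seq_len(3), function(t) {
    oob <- fit$oob[[t]]
    p <- predict(fit$forest, data = dat$x, predict.all = TRUE,
                 num.threads = 1)$predictions[oob, t]
    mean((p - dat$y[oob])^2)
  }, 0)), imp$err_oob_baseline[1], tolerance = 1e-12)
})

test_that("planted features dominate noise features across seeds", {
  planted_imp <- c()
  noise_imp <- c()
  for (seed in 1:20) {
    dat <- make_regression_data(40, 6, seed = 100 + seed,
                                signal_cols = 1:2, noise_sd = 0.1)
    fit <- fit_forest(dat$x, dat$y, forest_control(n_trees = 20, seed = seed))
    imp <- oob_importance(fit, dat$x, dat$y)
    planted_imp <- c(planted_imp, imp$importance[1:2])
    noise_imp <- c(noise_imp, imp$importance[3:6])
  }
  expect_lt(wilcox.test(planted_imp, noise_imp,
                        alternative = "greater")$p.value, 0.01)
})

test_that("gaussian perturbation with vanishing SD zeroes all importances", {
  dat <- make_regression_data(30, 3, seed = 11)
  ctl <- forest_control(n_trees = 10, perturbation = "gaussian_noise",
                        noise_sd = 0, seed = 11)
  fit <- fit_forest(dat$x, dat$y, ctl)
  imp <- oob_importance(fit, dat$x, dat$y, ctl)
  expect_equal(imp$importance, rep(0, 3))
  # and a non-zero SD perturbs the signal feature measurably
  ctl2 <- forest_control(n_trees = 10, perturbation = "gaussian_noise",
                         noise_sd = 1, seed = 11)
  imp2 <- oob_importance(fit, dat$x, dat$y, ctl2)
  expect_gt(imp2$importance[1], 0)
})

test_that("selection applies the threshold with canonical tie-breaking", {
  imp <- structure(data.frame(
    feature = c("1-5", "1-4", "2-3"),
    i = c(1L, 1L, 2L), j = c(5L, 4L, 3L),
    importance = c(0.02, 0.004, 0.0051),
    err_oob_baseline = 0.1, selected = NA), class = c("importance_table", "data.frame"))
  sel <- select_features(imp, 0.005)
  expect_equal(sel$feature, c("1-5", "2-3"))

  expect_equal(nrow(select_features(imp, 0.05)), 0)

  tie <- imp
  tie$importance <- c(0.01, 0.01, 0.001)
  sel2 <- select_features(tie, 0.005)
  expect_equal(sel2$feature, c("1-4", "1-5")) # tie broken by (i, j)
})

test_that("importance tables keep edge identity from feature matrices", {
  hp <- small_planted_cohort(n_subjects = 20, seed = 13)
  fit <- fit_forest(hp$features, hp$y, forest_control(seed = 13))
  imp <- oob_importance(fit, hp$features, hp$y)
  expect_equal(imp$feature, paste(imp$i, imp$j, sep = "-"))
  expect_equal(attr(imp, "network"), "RH")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_importance(imp, path)
  expect_equal(read.delim(path)$network[1], "RH")
})
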