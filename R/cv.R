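# Outcome definition, evaluation statistics, and the nested
# leave-one-subject-out cross-validation around selection + ridge.

#' Motor improvement rate from UPDRS-III scores
#'
#' `(pre - post) / pre`: the fractional improvement in the motor score
#' after surgery (1 = full recovery, 0 = no change). Note that the mean of
#' per-subject rates is not the rate of the mean scores, so group-mean
#' scores do not reproduce a cohort's mean rate.
#'
#' @param pre,post Pre- and post-surgical UPDRS-III scores (vectorized);
#'   `pre` must be positive, `post` non-negative.
#' @return Numeric improvement rate(s).
#' @export
#' @examples
#' improvement_rate(40, 10)
improvement_rate <- function(pre, post) {
  if (any(pre <= 0)) abort("pre-surgical score must be positive")
  if (any(post < 0)) abort("post-surgical score must be non-negative")
  (pre - post) / pre
}

#' Two-sided Pearson p-value from r and sample size
#'
#' Uses the t-distribution transform `t = r * sqrt((n - 2) / (1 - r^2))`
#' with `n - 2` degrees of freedom.
#'
#' @param r Pearson correlation.
#' @param n Sample size (>= 3).
#' @return Two-sided p-value.
#' @export
#' @examples
#' pearson_p_from_r(0.37, 55)
pearson_p_from_r <- function(r, n) {
  if (n < 3) abort("need n >= 3")
  if (abs(r) >= 1) return(0)
  tval <- abs(r) * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-tval, df = n - 2)
}

#' Correlation-based evaluation of predicted against true outcomes
#'
#' @param predicted,true Numeric vectors (length >= 3, non-constant).
#' @return List with `pearson_r`, `pearson_p` (two-sided, t-transform) and
#'   `r_squared` (squared Pearson correlation).
#' @export
evaluate <- function(predicted, true) {
  if (length(predicted) != length(true)) abort("length mismatch")
  if (length(true) < 3L) abort("need at least 3 pairs")
  if (stats::sd(predicted) == 0 || stats::sd(true) == 0) {
    abort("correlation undefined for a constant vector")
  }
  r <- stats::cor(predicted, true)
  list(pearson_r = r, pearson_p = pearson_p_from_r(r, length(true)),
       r_squared = r^2)
}

#' Nested leave-one-out cross-validation of the selection + ridge pipeline
#'
#' The outer loop leaves one subject out at a time. With
#' `selection_scope = "per_fold"` (the default), random-forest OOB
#' importance selection runs on the N-1 training subjects only; the inner
#' five-fold grid search and the ridge fit use the same training subjects,
#' and a single prediction is made for the held-out subject, whose outcome
#' and connectivity are never touched during training. With
#' `selection_scope = "global"`, the feature set is selected once on the
#' full cohort (or supplied via `selected`), matching the inter-group
#' selection procedure of group analyses; only the ridge stage is then
#' cross-validated.
#'
#' @param x N x d feature matrix with subject ids as rownames (an
#'   `"fc_features"` or plain matrix).
#' @param y Outcome vector (improvement rates), length N.
#' @param forest A [forest_control()].
#' @param ridge A [ridge_control()].
#' @param selection_scope `"per_fold"` or `"global"`.
#' @param selected Optional pre-computed selection (data.frame with a
#'   `feature` column, as from [select_features()]); implies global scope.
#' @param seed Integer seed; per-fold sub-seeds are derived from it, so
#'   every fold is reproducible independently.
#' @return Object of class `"cpm_cv"`: per-subject prediction table
#'   (`subject_id`, `true_rate`, `predicted_rate`, `fold_alpha`,
#'   `fold_max_iter`, `n_selected_features`), evaluation stats, per-fold
#'   selected feature lists, and the number of intercept-only fallbacks.
#' @export
nested_loocv <- function(x, y, forest = forest_control(),
                         ridge = ridge_control(),
                         selection_scope = c("per_fold", "global"),
                         selected = NULL, seed = 1L) {
  selection_scope <- match.arg(selection_scope)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 10L) abort("nested LOOCV needs at least 10 subjects (got %d)", n)
  if (length(y) != n) abort("length(y) != nrow(x)")
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  if (anyDuplicated(ids)) {
    abort("duplicate subject_id: %s", ids[anyDuplicated(ids)])
  }
  edges <- attr(x, "edges")

  if (!is.null(selected)) selection_scope <- "global"
  if (selection_scope == "global" && is.null(selected)) {
    fc <- forest
    fc$seed <- derive_seed(seed, "global-selection")
    fit <- fit_forest(x, y, fc)
    imp <- oob_importance(fit, x, y, fc)
    selected <- select_features(imp, fc$importance_threshold)
  }

  pred <- numeric(n)
  fold_alpha <- numeric(n)
  fold_iter <- integer(n)
  n_sel <- integer(n)
  fold_features <- vector("list", n)
  fallbacks <- 0L

  for (s in seq_len(n)) {
    xtr <- x[-s, , drop = FALSE]
    ytr <- y[-s]
    fold_seed <- derive_seed(seed, "fold", s)
    if (selection_scope == "per_fold") {
      fc <- forest
      fc$seed <- fold_seed
      attr(xtr, "edges") <- edges # keep edge metadata on the subset
      fit <- fit_forest(xtr, ytr, fc)
      imp <- oob_importance(fit, xtr, ytr, fc)
      sel <- select_features(imp, fc$importance_threshold)
    } else {
      sel <- selected
    }
    fold_features[[s]] <- sel
    n_sel[s] <- nrow(sel)
    if (nrow(sel) == 0L) {
      fallbacks <- fallbacks + 1L
      model <- suppressWarnings(
        fit_ridge(xtr[, integer(0), drop = FALSE], ytr, alpha = 0))
      fold_alpha[s] <- NA_real_
      fold_iter[s] <- NA_integer_
      pred[s] <- predict(model, x[s, integer(0), drop = FALSE])
    } else {
      cols <- sel$feature
      rc <- ridge
      rc$seed <- fold_seed
      best <- inner_grid_search(xtr[, cols, drop = FALSE], ytr, rc)
      model <- fit_ridge(xtr[, cols, drop = FALSE], ytr,
                         alpha = best$alpha, max_iter = best$max_iter,
                         standardize = rc$standardize)
      fold_alpha[s] <- best$alpha
      fold_iter[s] <- best$max_iter
      pred[s] <- predict(model, x[s, cols, drop = FALSE])
    }
  }
  if (fallbacks > 0L) {
    message(sprintf("nested_loocv: %d fold(s) selected no features; intercept-only fallback used",
                    fallbacks))
  }
  ev <- evaluate(pred, y)
  structure(list(
    predictions = data.frame(subject_id = ids, true_rate = y,
                             predicted_rate = pred, fold_alpha = fold_alpha,
                             fold_max_iter = fold_iter,
                             n_selected_features = n_sel,
                             stringsAsFactors = FALSE),
    pearson_r = ev$pearson_r, pearson_p = ev$pearson_p,
    r_squared = ev$r_squared,
    fold_features = fold_features, n_fallbacks = fallbacks,
    selection_scope = selection_scope,
    network = attr(x, "network"), seed = seed),
    class = "cpm_cv")
}

#' @export
print.cpm_cv <- function(x, ...) {
  cat(sprintf("Nested LOOCV (%s selection%s): %d subjects\n",
              x$selection_scope,
              if (is.null(x$network)) "" else paste0(", ", x$network),
              nrow(x$predictions)))
  cat(sprintf("  Pearson r = %.3f, p = %.3g, R^2 = %.3f\n",
              x$pearson_r, x$pearson_p, x$r_squared))
  invisible(x)
}
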