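# Connectome-based predictive model: the user-facing fitting function and
# its S3 methods. Wraps nested LOOCV (honest out-of-sample performance) and
# a final full-cohort model (for coefficients and prediction of new
# subjects).

#' Fit a connectome-based predictive model
#'
#' Fits the full selection + ridge pipeline on one network's feature
#' matrix: (1) nested leave-one-out cross-validation (outer LOOCV, inner
#' five-fold grid search; feature selection per training fold by default)
#' giving unbiased per-subject predictions and Pearson r / p / R-squared;
#' (2) a final model on the whole cohort — random-forest OOB-importance
#' selection followed by grid-searched ridge — used by `coef()` and
#' `predict()`.
#'
#' @param x N x d feature matrix (see [feature_matrix()]); rownames are
#'   subject ids.
#' @param y Outcome vector: the improvement rates.
#' @param forest A [forest_control()].
#' @param ridge A [ridge_control()].
#' @param selection_scope Scope of feature selection in the
#'   cross-validation: `"per_fold"` (default) or `"global"`.
#' @param seed Integer seed.
#' @return Object of class `"cpm"` with components `cv` (the `"cpm_cv"`),
#'   `importance` (full-cohort importance table), `selected` (full-cohort
#'   selection), `final` (the final `"cpm_ridge"`), `final_alpha`,
#'   `network`, `call`.
#' @seealso [nested_loocv()], [report_top_connections()]
#' @export
#' @examples
#' atlas <- synthetic_atlas(6)
#' cfg <- synthetic_config(14, n_timepoints = 60,
#'                         planted_edges = data.frame(i = 2, j = 4, beta = 1),
#'                         seed = 3)
#' coh <- generate_cohort(cfg, atlas)
#' fcs <- lapply(coh$panels, compute_fc)
#' feats <- feature_matrix(fcs, partition_edges(atlas), "RH")
#' fit <- cpm(feats, coh$subjects$improvement_rate,
#'            forest = forest_control(n_trees = 10), seed = 1)
#' print(fit)
cpm <- function(x, y, forest = forest_control(), ridge = ridge_control(),
                selection_scope = c("per_fold", "global"), seed = 1L) {
  selection_scope <- match.arg(selection_scope)
  cv <- nested_loocv(x, y, forest = forest, ridge = ridge,
                     selection_scope = selection_scope, seed = seed)

  # final full-cohort model for coef()/predict()
  fc <- forest
  fc$seed <- derive_seed(seed, "final-forest")
  ffit <- fit_forest(x, y, fc)
  importance <- oob_importance(ffit, x, y, fc)
  selected <- select_features(importance, fc$importance_threshold)
  if (nrow(selected)) {
    rc <- ridge
    rc$seed <- derive_seed(seed, "final-ridge")
    xm <- as.matrix(x)
    best <- inner_grid_search(xm[, selected$feature, drop = FALSE], y, rc)
    final <- fit_ridge(xm[, selected$feature, drop = FALSE], y,
                       alpha = best$alpha, max_iter = best$max_iter,
                       standardize = rc$standardize)
  } else {
    final <- suppressWarnings(
      fit_ridge(as.matrix(x)[, integer(0), drop = FALSE], y, alpha = 0))
  }
  structure(list(cv = cv, importance = importance, selected = selected,
                 final = final, network = attr(x, "network"),
                 n = nrow(x), d = ncol(x), seed = seed,
                 call = match.call()),
            class = "cpm")
}

#' @export
print.cpm <- function(x, ...) {
  cat("Connectome-based predictive model",
      if (!is.null(x$network)) sprintf("(%s network)", x$network), "\n")
  cat(sprintf("  %d subjects, %d edges, %d selected in the final model\n",
              x$n, x$d, nrow(x$selected)))
  cat(sprintf("  LOOCV: Pearson r = %.3f, p = %.3g, R^2 = %.3f\n",
              x$cv$pearson_r, x$cv$pearson_p, x$cv$r_squared))
  invisible(x)
}

#' @export
summary.cpm <- function(object, ...) {
  structure(list(model = object), class = "summary.cpm")
}

#' @export
print.summary.cpm <- function(x, ...) {
  m <- x$model
  print(m)
  cat(sprintf("  selection scope: %s; intercept-only folds: %d\n",
              m$cv$selection_scope, m$cv$n_fallbacks))
  alphas <- m$cv$predictions$fold_alpha
  if (any(!is.na(alphas))) {
    cat("  per-fold alpha:\n")
    print(table(alpha = alphas[!is.na(alphas)]))
  }
  if (nrow(m$selected)) {
    cat("  top selected edges (final model):\n")
    print(utils::head(m$selected, 10), row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.cpm <- function(object, ...) {
  stats::setNames(c(object$final$intercept, object$final$coefficients),
                  c("(Intercept)", object$final$feature_names))
}

#' Predict improvement rates for new subjects
#'
#' Uses the final full-cohort model (global selection + ridge).
#'
#' @param object A fitted `"cpm"`.
#' @param newx Feature matrix over the same edge set as the training
#'   features (columns matched by name).
#' @param ... Unused.
#' @return Numeric vector of predicted improvement rates.
#' @export
predict.cpm <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  cols <- object$final$feature_names
  if (length(cols)) {
    missing_cols <- setdiff(cols, colnames(newx))
    if (length(missing_cols)) {
      abort("newx lacks feature column(s): %s",
            paste(utils::head(missing_cols, 3), collapse = ", "))
    }
    newx <- newx[, cols, drop = FALSE]
  }
  predict(object$final, newx)
}

#' @export
fitted.cpm <- function(object, ...) {
  stats::setNames(object$cv$predictions$predicted_rate,
                  object$cv$predictions$subject_id)
}

#' @export
residuals.cpm <- function(object, ...) {
  with(object$cv$predictions,
       stats::setNames(true_rate - predicted_rate, subject_id))
}

#' Scatter plot of cross-validated predictions against true rates
#'
#' @param x A fitted `"cpm"`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.cpm <- function(x, ...) {
  p <- x$cv$predictions
  graphics::plot(p$true_rate, p$predicted_rate,
                 xlab = "observed improvement rate",
                 ylab = "LOOCV predicted improvement rate",
                 main = sprintf("%s: r = %.2f, p = %.2g",
                                if (is.null(x$network)) "CPM" else x$network,
                                x$cv$pearson_r, x$cv$pearson_p), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
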