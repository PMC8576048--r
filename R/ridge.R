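# Ridge regression with an unpenalized intercept, solved in closed form.
# Objective: J(theta) = mean((y - theta0 - X theta)^2) + alpha/2 * sum(theta^2).
# The SVD solution is exact, so the `max_iter` grid dimension (retained for
# interface compatibility with iterative solvers) never changes estimates.

#' Ridge hyper-parameter configuration
#'
#' @param alpha_grid Penalty grid; default 13 log-spaced points over
#'   `10^-3 .. 10^3`.
#' @param max_iter_grid Iteration-cap grid. The closed-form solver is exact,
#'   so this dimension only affects tie-breaking; it is kept because the
#'   grid-search contract spans both parameters.
#' @param inner_folds Folds of the inner cross-validation (default 5).
#' @param standardize Centre and scale features on the training data before
#'   penalization (default `TRUE`; penalized coefficients are
#'   scale-sensitive).
#' @param seed Integer seed for the inner-fold shuffle.
#' @return An object of class `"ridge_control"`.
#' @export
ridge_control <- function(alpha_grid = 10^seq(-3, 3, by = 0.5),
                          max_iter_grid = c(1000L, 5000L, 10000L),
                          inner_folds = 5L, standardize = TRUE, seed = 1L) {
  if (!length(alpha_grid) || !length(max_iter_grid)) {
    abort("hyper-parameter grids must be non-empty")
  }
  if (any(alpha_grid <= 0)) abort("alpha values must be positive")
  if (inner_folds < 2L) abort("inner_folds must be >= 2")
  structure(list(alpha_grid = sort(alpha_grid),
                 max_iter_grid = sort(as.integer(max_iter_grid)),
                 inner_folds = as.integer(inner_folds),
                 standardize = standardize, seed = as.integer(seed)),
            class = "ridge_control")
}

#' Fit a ridge regression with unpenalized intercept
#'
#' Minimizes `mean((y - theta0 - X theta)^2) + alpha/2 * sum(theta^2)` in
#' closed form via the SVD of the centred design (minimum-norm limit at
#' `alpha = 0`). With `standardize = TRUE`, features are centred and scaled
#' using training-data statistics only; returned coefficients are on the
#' original scale.
#'
#' @param x N x d feature matrix (d may be 0: intercept-only fallback,
#'   predicting the training mean, with a warning).
#' @param y Outcome vector.
#' @param alpha Penalty weight (>= 0).
#' @param max_iter Recorded but unused (exact solver).
#' @param standardize Standardize features on the training data.
#' @return Object of class `"cpm_ridge"` with elements `coefficients`
#'   (original scale), `intercept`, `alpha`, `center`, `scale`.
#' @export
fit_ridge <- function(x, y, alpha, max_iter = 1000L, standardize = TRUE) {
  x <- as.matrix(x)
  n <- length(y)
  if (nrow(x) != n) abort("nrow(x) != length(y)")
  if (n < 2L) abort("need at least 2 observations")
  if (alpha < 0) abort("alpha must be >= 0")
  d <- ncol(x)
  if (d == 0L) {
    warning("empty feature set: falling back to an intercept-only model",
            call. = FALSE)
    return(structure(list(coefficients = numeric(0), intercept = mean(y),
                          alpha = alpha, max_iter = max_iter,
                          center = numeric(0), scale = numeric(0),
                          feature_names = character(0)),
                     class = "cpm_ridge"))
  }
  ctr <- colMeans(x)
  scl <- if (standardize) {
    s <- apply(x, 2, stats::sd)
    ifelse(s > 0, s, 1)
  } else rep(1, d)
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  yc <- y - mean(y)
  sv <- svd(xs)
  pos <- sv$d > max(sv$d[1], 1) * 1e-12
  dvec <- sv$d[pos]
  # theta = V diag(dvec / (dvec^2 + n*alpha/2)) U' yc
  shrink <- dvec / (dvec^2 + n * alpha / 2)
  theta_s <- sv$v[, pos, drop = FALSE] %*%
    (shrink * crossprod(sv$u[, pos, drop = FALSE], yc))
  theta <- as.numeric(theta_s) / scl
  structure(list(coefficients = theta,
                 intercept = mean(y) - sum(ctr * theta),
                 alpha = alpha, max_iter = max_iter,
                 center = ctr, scale = scl,
                 coefficients_standardized = as.numeric(theta_s),
                 feature_names = colnames(x)),
            class = "cpm_ridge")
}

#' @export
predict.cpm_ridge <- function(object, newx, ...) {
  if (length(object$coefficients) == 0L) {
    n <- if (is.matrix(newx)) nrow(newx) else length(newx)
    return(rep(object$intercept, n))
  }
  newx <- as.matrix(newx)
  as.numeric(object$intercept + newx %*% object$coefficients)
}

#' @export
print.cpm_ridge <- function(x, ...) {
  cat(sprintf("Ridge fit: %d feature(s), alpha = %g, intercept = %.4f\n",
              length(x$coefficients), x$alpha, x$intercept))
  invisible(x)
}

#' Inner k-fold grid search for ridge hyper-parameters
#'
#' Evaluates every `(alpha, max_iter)` grid point by k-fold
#' cross-validated mean squared error with a seeded fold shuffle and
#' returns the minimizer. Ties are broken toward larger `alpha` (stronger
#' regularization), then smaller `max_iter`.
#'
#' @param x,y Training data.
#' @param control A [ridge_control()].
#' @return List with `alpha`, `max_iter`, and the full `cv_table`
#'   (`alpha`, `max_iter`, `mse`).
#' @export
inner_grid_search <- function(x, y, control = ridge_control()) {
  x <- as.matrix(x)
  n <- length(y)
  k <- control$inner_folds
  if (n < k) {
    warning(sprintf("only %d observations: reducing inner folds from %d", n, k),
            call. = FALSE)
    k <- n
  }
  folds <- with_seed(derive_seed(control$seed, "innerfolds"),
                     sample(rep(seq_len(k), length.out = n)))
  grid <- expand.grid(alpha = control$alpha_grid,
                      max_iter = control$max_iter_grid)
  fold_sets <- lapply(seq_len(k), function(f) which(folds == f))
  grid$mse <- vapply(seq_len(nrow(grid)), function(g) {
    errs <- vapply(fold_sets, function(test) {
      fit <- fit_ridge(x[-test, , drop = FALSE], y[-test],
                       alpha = grid$alpha[g], max_iter = grid$max_iter[g],
                       standardize = control$standardize)
      mean((predict(fit, x[test, , drop = FALSE]) - y[test])^2)
    }, 0)
    mean(errs)
  }, 0)
  best <- min(grid$mse)
  cand <- grid[grid$mse <= best + 1e-12, , drop = FALSE]
  cand <- cand[order(-cand$alpha, cand$max_iter), , drop = FALSE]
  list(alpha = cand$alpha[1], max_iter = cand$max_iter[1], cv_table = grid)
}
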