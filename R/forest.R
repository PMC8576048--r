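# Feature selection: bagged regression forest with out-of-bag permutation
# importance. The importance statistic is
#   X_k = sum_t (errOOB2_{t,k} - errOOB1_t) / n_trees,
# where errOOB1_t is tree t's mean squared error on its out-of-bag subjects
# and errOOB2_{t,k} the same after perturbing feature k among those
# subjects; edges with X above a threshold (0.005 by default) are selected.
# Tree growing is delegated to ranger; bootstrap resampling, OOB
# bookkeeping, the importance statistic and the selection rule live here
# (ranger's own importance modes are not used).

#' Forest configuration for OOB-importance feature selection
#'
#' @param n_trees Number of trees (default 20).
#' @param max_depth Maximum tree depth; `NULL` = unlimited.
#' @param mtry Candidate features per split; `NULL` = `ceiling(d / 3)`, the
#'   conventional regression-forest default.
#' @param min_leaf_size Minimum number of subjects per terminal node
#'   (default 2; grows deep trees).
#' @param importance_threshold Selection threshold on the importance scale
#'   (mean squared error of an improvement-rate fraction); default 0.005.
#' @param perturbation How feature values are perturbed among a tree's OOB
#'   subjects: `"permute"` (random permutation of the observed values, the
#'   standard procedure) or `"gaussian_noise"` (add
#'   `Normal(0, noise_sd * sd(column))` noise).
#' @param noise_sd Relative noise SD for `perturbation = "gaussian_noise"`.
#' @param seed Integer seed; bootstraps, tree growing and perturbations are
#'   reproducible from it, with sub-streams per (tree, feature).
#' @return An object of class `"forest_control"`.
#' @export
forest_control <- function(n_trees = 20L, max_depth = NULL, mtry = NULL,
                           min_leaf_size = 2L,
                           importance_threshold = 0.005,
                           perturbation = c("permute", "gaussian_noise"),
                           noise_sd = 1, seed = 1L) {
  if (n_trees < 1L) abort("n_trees must be >= 1")
  if (importance_threshold < 0) abort("importance_threshold must be >= 0")
  structure(list(n_trees = as.integer(n_trees), max_depth = max_depth,
                 mtry = mtry, min_leaf_size = as.integer(min_leaf_size),
                 importance_threshold = importance_threshold,
                 perturbation = match.arg(perturbation),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "forest_control")
}

#' Fit a bagged regression forest with explicit OOB sets
#'
#' Each tree is trained on a bootstrap sample of `N` subjects drawn with
#' replacement; the complementary subjects form that tree's out-of-bag
#' (OOB) set. A bootstrap whose OOB set would be empty is redrawn (up to
#' 100 attempts).
#'
#' @param x N x d numeric feature matrix (e.g. an `"fc_features"`).
#' @param y Numeric outcome vector, length N.
#' @param control A [forest_control()].
#' @return Object of class `"cpm_forest"`: the fitted ranger forest plus
#'   `inbag` (N x n_trees bootstrap counts), `oob` (list of OOB index
#'   vectors) and the control.
#' @export
fit_forest <- function(x, y, control = forest_control()) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 5L) abort("need at least 5 subjects to fit the forest (got %d)", n)
  if (anyNA(x) || anyNA(y)) abort("missing values are not supported")
  if (length(y) != n) abort("length(y) != nrow(x)")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))

  inbag <- with_seed(derive_seed(control$seed, "bootstrap"), {
    lapply(seq_len(control$n_trees), function(t) {
      for (attempt in 1:100) {
        draw <- sample.int(n, n, replace = TRUE)
        counts <- tabulate(draw, nbins = n)
        if (any(counts == 0L)) return(counts)
      }
      abort("tree %d: no bootstrap with a non-empty OOB set in 100 attempts", t)
    })
  })
  fit <- ranger::ranger(
    x = x, y = y,
    num.trees = control$n_trees,
    mtry = if (is.null(control$mtry)) ceiling(ncol(x) / 3) else control$mtry,
    min.bucket = control$min_leaf_size,
    max.depth = if (is.null(control$max_depth)) 0 else control$max_depth,
    replace = TRUE, inbag = inbag, keep.inbag = TRUE,
    num.threads = 1L, seed = derive_seed(control$seed, "trees"),
    oob.error = FALSE
  )
  inbag_m <- do.call(cbind, inbag)
  structure(list(forest = fit, inbag = inbag_m,
                 oob = lapply(seq_len(ncol(inbag_m)),
                              function(t) which(inbag_m[, t] == 0L)),
                 n = n, d = ncol(x), feature_names = colnames(x),
                 control = control),
            class = "cpm_forest")
}

#' @export
print.cpm_forest <- function(x, ...) {
  cat(sprintf("Bagged regression forest: %d trees, %d subjects, %d features\n",
              x$control$n_trees, x$n, x$d))
  cat(sprintf("  mean OOB set size: %.1f subjects\n",
              mean(lengths(x$oob))))
  invisible(x)
}

# per-tree predictions for all rows of `newx`
.tree_predictions <- function(model, newx) {
  stats::predict(model$forest, data = newx, predict.all = TRUE,
                 num.threads = 1L)$predictions
}

#' Out-of-bag permutation importance
#'
#' For every tree `t`, computes `errOOB1_t` (mean squared prediction error
#' on the tree's OOB subjects) and, for every feature `k`, `errOOB2_{t,k}`
#' (the same after perturbing column `k` among the OOB subjects; by default
#' a random permutation of its OOB values). The importance of feature `k`
#' is the average error inflation `X_k = sum_t (errOOB2_{t,k} -
#' errOOB1_t) / n_trees`. Perturbation RNG sub-streams are derived from
#' `(seed, tree, feature)`, so importances do not depend on feature
#' evaluation order.
#'
#' @param model A `"cpm_forest"` from [fit_forest()].
#' @param x,y The training data the forest was fitted on.
#' @param control Forest control; defaults to the one stored in `model`.
#' @return An `"importance_table"` data.frame with one row per feature:
#'   columns `feature`, `i`, `j` (edge endpoints when `x` carries edge
#'   metadata, `NA` otherwise), `importance`, `err_oob_baseline` and
#'   `selected` (`importance > threshold`).
#' @references The statistic is the classical permutation importance of
#'   bagged regression forests, computed tree-wise on OOB data.
#' @export
oob_importance <- function(model, x, y, control = model$control) {
  x <- as.matrix(x)
  d <- ncol(x)
  n_trees <- control$n_trees
  oob <- model$oob
  seed <- control$seed

  pred_all <- .tree_predictions(model, x)
  err1 <- vapply(seq_len(n_trees), function(t) {
    mean((pred_all[oob[[t]], t] - y[oob[[t]]])^2)
  }, 0)

  # Stacked layout: one block of rows per tree (that tree's OOB subjects).
  rows <- unlist(oob, use.names = FALSE)
  block <- rep.int(seq_len(n_trees), lengths(oob))
  xs <- x[rows, , drop = FALSE]
  n_stack <- nrow(xs)
  col_sd <- apply(x, 2, stats::sd)

  perturbed_column <- function(k) {
    col <- xs[, k]
    for (t in seq_len(n_trees)) {
      idx <- which(block == t)
      sub <- derive_seed(seed, "perturb", t, k)
      if (control$perturbation == "permute") {
        col[idx] <- col[idx][with_seed(sub, sample.int(length(idx)))]
      } else {
        col[idx] <- col[idx] +
          with_seed(sub, stats::rnorm(length(idx), 0,
                                      control$noise_sd * col_sd[k]))
      }
    }
    col
  }

  importance <- numeric(d)
  # Batch features into chunks: each chunk stacks the per-feature perturbed
  # copies vertically so one ranger predict call covers many features.
  chunk_size <- max(1L, floor(5e6 / max(1L, n_stack * d)))
  chunks <- split(seq_len(d), ceiling(seq_len(d) / chunk_size))
  y_stack <- y[rows]
  for (ch in chunks) {
    keep <- ch[apply(xs[, ch, drop = FALSE], 2,
                     function(v) length(unique(v)) > 1L)]
    # globally constant columns: perturbation cannot change predictions
    for (k in ch) if (!k %in% keep && control$perturbation == "permute") {
      importance[k] <- 0
    }
    todo <- if (control$perturbation == "permute") keep else ch
    if (!length(todo)) next
    big <- xs[rep(seq_len(n_stack), times = length(todo)), , drop = FALSE]
    for (m in seq_along(todo)) {
      big[(m - 1L) * n_stack + seq_len(n_stack), todo[m]] <-
        perturbed_column(todo[m])
    }
    preds <- .tree_predictions(model, big)
    for (m in seq_along(todo)) {
      off <- (m - 1L) * n_stack
      err2 <- vapply(seq_len(n_trees), function(t) {
        idx <- which(block == t)
        mean((preds[off + idx, t] - y_stack[idx])^2)
      }, 0)
      importance[todo[m]] <- sum(err2 - err1) / n_trees
    }
  }

  edges <- attr(x, "edges")
  out <- data.frame(
    feature = model$feature_names,
    i = if (is.null(edges)) NA_integer_ else edges$i,
    j = if (is.null(edges)) NA_integer_ else edges$j,
    importance = importance,
    err_oob_baseline = mean(err1),
    selected = importance > control$importance_threshold,
    stringsAsFactors = FALSE
  )
  structure(out, network = attr(x, "network"),
            threshold = control$importance_threshold,
            class = c("importance_table", "data.frame"))
}

#' Select features above the importance threshold
#'
#' Returns the features with importance strictly above the threshold,
#' ordered by decreasing importance; ties are broken by canonical edge
#' order (i, then j). The selection may be empty — downstream ridge fits
#' then fall back to an intercept-only model.
#'
#' @param importances An `"importance_table"`.
#' @param threshold Importance threshold (default 0.005).
#' @return Data.frame with columns `feature`, `i`, `j`, `importance`.
#' @export
select_features <- function(importances, threshold = 0.005) {
  sel <- importances[importances$importance > threshold, , drop = FALSE]
  ord <- if (all(is.na(sel$i))) {
    order(-sel$importance, sel$feature)
  } else {
    order(-sel$importance, sel$i, sel$j)
  }
  sel <- sel[ord, c("feature", "i", "j", "importance"), drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Write an importance table to TSV
#'
#' @param importances An `"importance_table"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_importance <- function(importances, path) {
  df <- data.frame(network = attr(importances, "network"),
                   importances, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
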