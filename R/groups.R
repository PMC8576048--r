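# Group analysis: age / sex splits and per-group cross-validated prediction
# on a cohort-wide ("inter-group") feature selection.

#' Split a cohort into two groups by age or sex
#'
#' Age: subjects are sorted by age (ties by subject id) and the first
#' `ceiling(n / 2)` form the younger group, so group sizes differ by at
#' most one. Sex: split by label. Exclusions are removed first (exclusion
#' is always an explicit list, never automatic).
#'
#' @param subjects Data.frame with columns `subject_id`, `age`, `sex`.
#' @param covariate `"age"` or `"sex"`.
#' @param exclude Character vector of subject ids to drop before
#'   splitting.
#' @return Named list of two data.frames (`younger`/`older` or `M`/`F`).
#'   A group smaller than 10 triggers a warning (LOOCV still runs);
#'   smaller than 3, an error.
#' @export
split_groups <- function(subjects, covariate = c("age", "sex"),
                         exclude = character()) {
  covariate <- match.arg(covariate)
  subjects <- subjects[!subjects$subject_id %in% exclude, , drop = FALSE]
  n <- nrow(subjects)
  if (covariate == "age") {
    ord <- order(subjects$age, subjects$subject_id)
    k <- ceiling(n / 2)
    groups <- list(younger = subjects[ord[seq_len(k)], , drop = FALSE],
                   older = subjects[ord[-seq_len(k)], , drop = FALSE])
  } else {
    groups <- split(subjects, factor(subjects$sex, levels = c("M", "F")))
  }
  sizes <- vapply(groups, nrow, 0L)
  if (any(sizes < 3L)) {
    abort("group '%s' has only %d subject(s); need at least 3",
          names(groups)[which.min(sizes)], min(sizes))
  }
  if (any(sizes < 10L)) {
    warning(sprintf("group '%s' has fewer than 10 subjects; LOOCV estimates will be unstable",
                    names(groups)[sizes < 10L][1]), call. = FALSE)
  }
  lapply(groups, function(g) { rownames(g) <- NULL; g })
}

#' Group analysis with inter-group feature selection
#'
#' Feature selection (random-forest OOB importance) runs once on the full
#' non-excluded cohort; ridge nested LOOCV then runs within each group on
#' that shared feature set, and per-group Pearson r / p are reported.
#'
#' @param x Feature matrix for one network (rownames = subject ids).
#' @param subjects Cohort table with `subject_id`, `age`, `sex`,
#'   `improvement_rate`.
#' @param covariate `"age"` or `"sex"`.
#' @param forest,ridge Control objects.
#' @param exclude Subject ids excluded before selection and splitting.
#' @param seed Integer seed.
#' @return List with `selected` (the shared selection) and `groups`
#'   (named list of `"cpm_cv"` results).
#' @export
run_group_analysis <- function(x, subjects, covariate = c("age", "sex"),
                               forest = forest_control(),
                               ridge = ridge_control(),
                               exclude = character(), seed = 1L) {
  covariate <- match.arg(covariate)
  edges <- attr(x, "edges")
  network <- attr(x, "network")
  x <- as.matrix(x)
  keep <- !subjects$subject_id %in% exclude
  subjects <- subjects[keep, , drop = FALSE]
  x <- x[subjects$subject_id, , drop = FALSE]
  attr(x, "edges") <- edges
  attr(x, "network") <- network

  fc <- forest
  fc$seed <- derive_seed(seed, "intergroup-selection")
  fit <- fit_forest(x, subjects$improvement_rate, fc)
  imp <- oob_importance(fit, x, subjects$improvement_rate, fc)
  selected <- select_features(imp, fc$importance_threshold)

  groups <- split_groups(subjects, covariate)
  # the same derived seed for both groups: identical groups (by data) then
  # yield identical results, and group labels do not perturb the folds
  cv_seed <- derive_seed(seed, "group-cv")
  results <- lapply(names(groups), function(g) {
    gs <- groups[[g]]
    nested_loocv(x[gs$subject_id, , drop = FALSE], gs$improvement_rate,
                 forest = forest, ridge = ridge, selected = selected,
                 seed = cv_seed)
  })
  names(results) <- names(groups)
  list(selected = selected, importance = imp, groups = results)
}
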