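# Cross-validated parameter selection on the training set: stratified
# 10-fold partitions, summed confusion matrices (metrics are computed from
# the sum, never averaged over folds), and the two selection rules — max
# RBBB sensitivity then max RBBB predictivity for the discriminant
# weights, max mean sensitivity then smallest C for the SVM penalty.

#' Stratified k-fold assignment
#'
#' Assigns each sample to one of `k` folds so that within every stratum
#' the fold sizes differ by at most one. Reproducible under `seed`.
#'
#' @param n Number of samples.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @param strata Optional label vector (length `n`) to stratify on.
#' @return Integer vector in `1..k`, length `n`.
#' @export
kfold_partition <- function(n, k = 10, seed = 1, strata = NULL) {
  if (n < k) stopf("cannot make %d folds from %d samples", k, n)
  if (is.null(strata)) strata <- rep(1L, n)
  if (length(strata) != n) stopf("strata length must equal n")
  folds <- integer(n)
  with_private_seed(seed, function() {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      if (length(idx) < k) {
        warnf("stratum '%s' has %d < k = %d samples; some folds get none", s, length(idx), k)
      }
      # cycle fold ids over a shuffled stratum
      folds[idx] <<- (sample(seq_along(idx)) - 1L) %% k + 1L
    }
  })
  folds
}

#' Cross-validated summed confusion matrix
#'
#' For each fold, fits the classifier factory on the remaining folds and
#' predicts the held-out fold; the k per-fold confusion matrices are
#' summed and metrics are derived from the summed matrix. This avoids the
#' distortion of averaging per-fold rates when folds carry unequal class
#' counts.
#'
#' @param X Feature matrix.
#' @param y Two-level factor of labels.
#' @param fit_fun `function(X, y) -> model`.
#' @param predict_fun `function(model, X) -> labels`.
#' @param folds Integer fold assignment from [kfold_partition()].
#' @return A list: `confusion` (a `bbb_confusion` over `levels(y)`) and
#'   `metrics` (tibble from [metrics_from_confusion()]).
#' @export
cv_summed_confusion <- function(X, y, fit_fun, predict_fun, folds) {
  y <- check_two_class(y)
  if (length(folds) != nrow(X)) stopf("folds length must match nrow(X)")
  labels <- levels(y)
  total <- matrix(0L, 2, 2, dimnames = list(reference = labels, algorithm = labels))
  for (f in sort(unique(folds))) {
    test <- folds == f
    model <- tryCatch(
      fit_fun(X[!test, , drop = FALSE], droplevels(y[!test])),
      error = function(e) stopf("fold %d: %s", f, conditionMessage(e))
    )
    pred <- predict_fun(model, X[test, , drop = FALSE])
    total <- total + unclass(confusion(y[test], pred, labels = labels))
  }
  cm <- new_confusion(total)
  list(confusion = cm, metrics = metrics_from_confusion(cm))
}

#' Select the discriminant weighting coefficients by cross-validation
#'
#' Evaluates the 30-point grid — NORM weight `w1` in 0.01..0.10 by 0.01
#' crossed with RBBB weight `w2` in {0.4, 0.5, 0.6} — by 10-fold
#' cross-validation with summed confusion matrices on NORM/RBBB data, and
#' picks the pair maximising RBBB sensitivity, breaking ties by RBBB
#' positive predictive value (then by grid order, which is deterministic).
#'
#' @param X ICA + RR feature matrix of NORM and RBBB beats.
#' @param y Factor with levels `NORM`, `RBBB`.
#' @param seed Fold seed.
#' @param k Folds (default 10).
#' @param w1_grid,w2_grid Overridable parameter grids.
#' @return A list: selected `w1`, `w2`, and the full audit `table` (one
#'   row per pair with summed-confusion cells and derived metrics).
#' @export
select_wlda_params <- function(X, y, seed = 1, k = 10,
                               w1_grid = seq(0.01, 0.1, by = 0.01),
                               w2_grid = c(0.4, 0.5, 0.6)) {
  y <- check_two_class(y)
  folds <- kfold_partition(nrow(X), k = k, seed = seed, strata = as.character(y))
  grid <- expand.grid(w1 = w1_grid, w2 = w2_grid, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$w1, grid$w2), , drop = FALSE]
  tab <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    w <- c(grid$w1[[i]], grid$w2[[i]])
    res <- cv_summed_confusion(
      X, y,
      fit_fun = function(Xt, yt) fit_wlda(Xt, yt, w = w, priors = c(0.5, 0.5)),
      predict_fun = predict_wlda, folds = folds)
    m <- unclass(res$confusion)
    tibble::tibble(
      w1 = w[[1]], w2 = w[[2]],
      nn = m[1, 1], nr = m[1, 2], rn = m[2, 1], rr = m[2, 2],
      norm_sp = metric_value(res$metrics, "NORM", "Sp"),
      norm_np = metric_value(res$metrics, "NORM", "NP"),
      rbbb_se = metric_value(res$metrics, "RBBB", "Se"),
      rbbb_pp = metric_value(res$metrics, "RBBB", "PP")
    )
  })
  best <- tab[order(-tab$rbbb_se, -tab$rbbb_pp), ][1, ]
  list(w1 = best$w1, w2 = best$w2, table = tab)
}

#' Select the SVM penalty by cross-validation
#'
#' Evaluates C in {0.001, 0.01, 0.1, 1, 10, 100} by 10-fold
#' cross-validation with summed confusion matrices on LBBB/RBBB data and
#' picks the value maximising the mean of the two class sensitivities,
#' breaking ties by the smallest C.
#'
#' @param X ICA + RR feature matrix of LBBB and RBBB beats.
#' @param y Factor with levels `LBBB`, `RBBB`.
#' @param seed Fold seed.
#' @param k Folds (default 10).
#' @param C_grid Overridable penalty grid.
#' @return A list: selected `C` and the full audit `table`.
#' @export
select_svm_C <- function(X, y, seed = 1, k = 10,
                         C_grid = c(0.001, 0.01, 0.1, 1, 10, 100)) {
  y <- check_two_class(y)
  folds <- kfold_partition(nrow(X), k = k, seed = seed, strata = as.character(y))
  tab <- purrr::map_dfr(C_grid, function(C) {
    res <- cv_summed_confusion(
      X, y,
      fit_fun = function(Xt, yt) fit_linear_svm(Xt, yt, C = C),
      predict_fun = predict_svm, folds = folds)
    m <- unclass(res$confusion)
    se1 <- metric_value(res$metrics, levels(y)[[1]], "Se")
    se2 <- metric_value(res$metrics, levels(y)[[2]], "Se")
    tibble::tibble(
      C = C, ll = m[1, 1], lr = m[1, 2], rl = m[2, 1], rr = m[2, 2],
      se_1 = se1, se_2 = se2, mean_se = (se1 + se2) / 2
    )
  })
  best <- tab[order(-tab$mean_se, tab$C), ][1, ]
  list(C = best$C, table = tab)
}
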