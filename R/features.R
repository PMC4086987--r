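# Feature construction: raw morphology + RR vectors, and per-lead ICA
# projections + RR. The ICA basis is fitted once on a designated subset of
# training beats and new beats are projected with the cached Moore-Penrose
# pseudo-inverse of the component matrix, i.e. least-squares coordinates in
# the component row space.

#' Select the designated ICA-basis training beats
#'
#' From each training record containing a class, take the first `k` beats
#' of that class in temporal order (`k` = 10 for NORM, 100 for LBBB, 80 for
#' RBBB by default). On the canonical training set — 18 records with NORM,
#' 2 with LBBB, 3 with RBBB — this yields 180 + 200 + 240 = 620 beats.
#'
#' @param beats A beats tibble (training set).
#' @param per_record Named integer vector: beats per record per class.
#' @return A beats tibble of the selected beats.
#' @export
select_basis_beats <- function(beats, per_record = c(NORM = 10, LBBB = 100, RBBB = 80)) {
  picked <- lapply(names(per_record), function(cls) {
    k <- per_record[[cls]]
    cls_beats <- dplyr::filter(beats, .data$label == cls)
    if (nrow(cls_beats) == 0) stopf("no %s beats available for basis selection", cls)
    by_rec <- dplyr::group_by(dplyr::arrange(cls_beats, .data$record_id, .data$r_index),
                              .data$record_id)
    short <- dplyr::filter(dplyr::summarise(by_rec, n = dplyr::n()), .data$n < k)
    if (nrow(short) > 0) {
      stopf("record %s has only %d %s beat(s), %d requested per record",
            short$record_id[[1]], short$n[[1]], cls, k)
    }
    dplyr::ungroup(dplyr::slice_head(by_rec, n = k))
  })
  dplyr::bind_rows(picked)
}

# Balanced fallback when the per-record rule is infeasible (e.g. synthetic
# data with few beats per virtual patient): round-robin over records within
# each class up to the class quota.
select_basis_quota <- function(beats, n_per_class = c(NORM = 180, LBBB = 200, RBBB = 240)) {
  picked <- lapply(names(n_per_class), function(cls) {
    cls_beats <- dplyr::arrange(dplyr::filter(beats, .data$label == cls),
                                .data$record_id, .data$r_index)
    if (nrow(cls_beats) == 0) stopf("no %s beats available for basis selection", cls)
    cls_beats <- dplyr::mutate(dplyr::group_by(cls_beats, .data$record_id),
                               .rank = dplyr::row_number())
    cls_beats <- dplyr::arrange(dplyr::ungroup(cls_beats), .data$.rank, .data$record_id)
    dplyr::select(utils::head(cls_beats, n_per_class[[cls]]), -".rank")
  })
  dplyr::bind_rows(picked)
}

lead_column <- function(lead) {
  switch(toupper(lead), A = "lead_a", B = "lead_b",
         stopf("unknown lead '%s' (use \"A\" or \"B\")", lead))
}

# Evaluate fn with a private RNG state so basis fitting is reproducible
# without disturbing the caller's stream.
with_private_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Fit a per-lead ICA basis with FastICA
#'
#' Runs fixed-point FastICA (deflation: components extracted one by one,
#' tanh contrast, PCA whitening to `n_components` dimensions) on the
#' designated training beats of one lead and stores the component matrix
#' together with its cached Moore-Penrose pseudo-inverse.
#'
#' @param beats Beats tibble (the designated basis subset, 620 beats in the
#'   canonical protocol).
#' @param lead `"A"` or `"B"`.
#' @param n_components Number of independent components (default 100).
#' @param seed Integer seed for the random orthogonal initialisation.
#' @param max_iter,tol Fixed-point iteration limit and convergence
#'   tolerance on `|<w, w_old>| - 1`.
#' @param on_no_convergence `"warn"` keeps the last iterate (the behaviour
#'   of standard FastICA implementations); `"error"` aborts.
#' @return An object of class `bbb_ica_basis`: `lead`, `components`
#'   (`n_components` x 200), `pinv_components` (200 x `n_components`),
#'   `fit_seed`, `n_train_beats`, `n_iter` per component.
#' @export
fit_ica_basis <- function(beats, lead, n_components = 100, seed = 1,
                          max_iter = 1000, tol = 1e-6,
                          on_no_convergence = c("warn", "error")) {
  on_no_convergence <- match.arg(on_no_convergence)
  col <- lead_column(lead)
  X <- do.call(rbind, beats[[col]])
  n <- nrow(X); p <- ncol(X)
  if (n < n_components) stopf("%d beats cannot support %d components", n, n_components)

  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  eg <- eigen(crossprod(Xc) / n, symmetric = TRUE)
  if (eg$values[n_components] < 1e-12 * eg$values[1]) {
    stopf("beat matrix is rank-deficient after whitening: eigenvalue %d is %.3g",
          n_components, eg$values[n_components])
  }
  K <- eg$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(1 / sqrt(eg$values[seq_len(n_components)]), n_components)
  Z <- Xc %*% K                     # n x m, whitened
  Kplus <- diag(sqrt(eg$values[seq_len(n_components)]), n_components) %*%
    t(eg$vectors[, seq_len(n_components), drop = FALSE])  # m x p

  m <- n_components
  W <- matrix(0, m, m)
  n_iter <- integer(m)
  init <- with_private_seed(seed, function() matrix(stats::rnorm(m * m), m, m))
  for (i in seq_len(m)) {
    w <- init[i, ]
    if (i > 1) {
      w <- w - t(W[seq_len(i - 1), , drop = FALSE]) %*%
        (W[seq_len(i - 1), , drop = FALSE] %*% w)
    }
    w <- w / sqrt(sum(w^2))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      u <- as.vector(Z %*% w)
      g <- tanh(u)
      gp <- 1 - g^2
      w_new <- as.vector(crossprod(Z, g)) / n - mean(gp) * w
      if (i > 1) {
        w_new <- w_new - as.vector(t(W[seq_len(i - 1), , drop = FALSE]) %*%
          (W[seq_len(i - 1), , drop = FALSE] %*% w_new))
      }
      w_new <- w_new / sqrt(sum(w_new^2))
      delta <- abs(abs(sum(w_new * w)) - 1)
      w <- w_new
      if (delta < tol) { converged <- TRUE; n_iter[i] <- it; break }
    }
    if (!converged) {
      n_iter[i] <- max_iter
      msg <- sprintf("component %d did not converge within %d iterations (lead %s)",
                     i, max_iter, lead)
      if (on_no_convergence == "error") stopf("%s", msg) else warnf("%s", msg)
    }
    W[i, ] <- w
  }

  components <- W %*% Kplus                      # m x p rows are components
  structure(list(
    lead = toupper(lead),
    components = components,
    pinv_components = pracma_pinv(components),
    center = mu,
    fit_seed = seed,
    n_train_beats = n,
    n_components = n_components,
    n_iter = n_iter
  ), class = "bbb_ica_basis")
}

# Moore-Penrose pseudo-inverse via SVD (full-row-rank case in practice).
pracma_pinv <- function(A, rtol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > rtol * sv$d[1]
  sv$v[, keep, drop = FALSE] %*%
    diag(1 / sv$d[keep], sum(keep)) %*%
    t(sv$u[, keep, drop = FALSE])
}

#' @export
print.bbb_ica_basis <- function(x, ...) {
  cat(sprintf("<bbb_ica_basis> lead %s: %d components x %d samples, fitted on %d beats (seed %d)\n",
              x$lead, nrow(x$components), ncol(x$components), x$n_train_beats, x$fit_seed))
  invisible(x)
}

#' Project a beat segment onto an ICA basis
#'
#' `f = segment %*% pinv(components)`: the least-squares coefficient vector
#' of the segment in the component row space. Linear in the segment; a
#' segment equal to a component row maps to the corresponding standard
#' basis vector.
#'
#' @param segment Numeric vector of length matching the basis (200).
#' @param basis A `bbb_ica_basis`.
#' @return Numeric vector of length `n_components`.
#' @export
ica_project <- function(segment, basis) {
  if (length(segment) != ncol(basis$components)) {
    stopf("segment length %d does not match basis sample length %d",
          length(segment), ncol(basis$components))
  }
  as.vector(segment %*% basis$pinv_components)
}

rr_term <- function(beats) beats$rr_s

#' Morphology + RR feature matrix
#'
#' Concatenates the normalized lead waveforms and the RR interval:
#' 401-dimensional for two leads (200 + 200 + 1), 201-dimensional for a
#' single lead. The RR term is always the last column.
#'
#' @param beats A beats tibble.
#' @param leads Character vector over `"A"`, `"B"`; order is kept.
#' @return Numeric matrix, one row per beat.
#' @export
assemble_morph <- function(beats, leads = c("A", "B")) {
  parts <- lapply(leads, function(l) do.call(rbind, beats[[lead_column(l)]]))
  X <- cbind(do.call(cbind, parts), rr_term(beats))
  colnames(X) <- NULL
  X
}

#' ICA + RR feature matrix
#'
#' Projects each lead onto its fitted ICA basis and appends the RR
#' interval: 201-dimensional for two leads (100 + 100 + 1), 101 for one.
#'
#' @param beats A beats tibble.
#' @param bases Named list of `bbb_ica_basis`, e.g. `list(A = ..., B = ...)`.
#' @param leads Character vector over `"A"`, `"B"`.
#' @return Numeric matrix, one row per beat; RR is the last column.
#' @export
assemble_ica <- function(beats, bases, leads = c("A", "B")) {
  parts <- lapply(leads, function(l) {
    basis <- bases[[toupper(l)]]
    if (is.null(basis)) stopf("no ICA basis supplied for lead %s", l)
    if (!identical(basis$lead, toupper(l))) {
      stopf("basis fitted for lead %s used for lead %s", basis$lead, toupper(l))
    }
    seg <- do.call(rbind, beats[[lead_column(l)]])
    seg %*% basis$pinv_components
  })
  X <- cbind(do.call(cbind, parts), rr_term(beats))
  colnames(X) <- NULL
  X
}
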