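# The three one-vs-one component classifiers: minimum-distance centroid
# (NORM vs LBBB on morphology+RR), weighted linear discriminant with
# softmax posteriors (NORM vs RBBB on ICA+RR), and a linear SVM (LBBB vs
# RBBB on ICA+RR). All ties resolve toward NORM when NORM is one of the
# class labels, reflecting its overwhelming prevalence.

check_two_class <- function(y) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stopf("exactly two classes required, got: %s",
                             paste(levels(y), collapse = ", "))
  y
}

tie_label <- function(class_labels) {
  if ("NORM" %in% class_labels) "NORM" else class_labels[[1]]
}

# ---- minimum distance -------------------------------------------------------

#' Fit a minimum-distance (centroid) classifier
#'
#' Stores the arithmetic mean vector of each class; prediction assigns a
#' beat to the class with the nearer (Euclidean) centroid.
#'
#' @param X Numeric feature matrix, one row per beat.
#' @param y Two-level factor (or character) of class labels.
#' @return An object of class `bbb_centroid`.
#' @export
fit_centroid <- function(X, y) {
  y <- check_two_class(y)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  structure(list(class_labels = levels(y), centroids = class_means(X, y)),
            class = "bbb_centroid")
}

# 2 x d matrix of class means, robust to d = 1
class_means <- function(X, y) {
  m <- vapply(levels(y), function(cl) colMeans(X[y == cl, , drop = FALSE]),
              numeric(ncol(X)))
  if (is.matrix(m)) t(m) else matrix(m, ncol = 1, dimnames = list(levels(y), NULL))
}

#' Predict with a centroid classifier
#'
#' @param model A `bbb_centroid`.
#' @param X Feature matrix (or single vector).
#' @return Character vector of labels; exact distance ties go to NORM.
#' @export
predict_centroid <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != ncol(model$centroids)) {
    stopf("feature dimension %d does not match model dimension %d",
          ncol(X), ncol(model$centroids))
  }
  d1 <- rowSums(sweep(X, 2, model$centroids[1, ])^2)
  d2 <- rowSums(sweep(X, 2, model$centroids[2, ])^2)
  out <- ifelse(d1 < d2, model$class_labels[[1]],
                ifelse(d2 < d1, model$class_labels[[2]], tie_label(model$class_labels)))
  unname(out)
}

# ---- weighted linear discriminant ------------------------------------------

#' Fit the weighted linear discriminant classifier
#'
#' Computes class means and the class-weighted pooled scatter matrix
#' \deqn{\Sigma = \sum_i w_i \sum_k (x_{ik} - m_i)(x_{ik} - m_i)^T}
#' (a weighted sum of outer products, with no per-class normalisation —
#' the weights absorb scale). Posteriors follow from linear discriminants
#' \eqn{g_i(x) = m_i^T \Sigma^{-1} x - \tfrac12 m_i^T \Sigma^{-1} m_i +
#' \log P(\omega_i)} passed through a softmax. A singular scatter matrix
#' falls back to a logged ridge `ridge_eps * trace(Sigma)/d` on the
#' diagonal.
#'
#' @param X Feature matrix.
#' @param y Two-level labels; `w` and `priors` follow `levels(y)` order.
#' @param w Positive class weights `(w1, w2)`.
#' @param priors Prior probabilities summing to 1 (default equal).
#' @param ridge_eps Relative ridge used only if `Sigma` is singular; `0`
#'   disables the fallback (singularity is then an error).
#' @return An object of class `bbb_wlda`.
#' @export
fit_wlda <- function(X, y, w = c(1, 1), priors = c(0.5, 0.5), ridge_eps = 1e-6) {
  y <- check_two_class(y)
  if (any(w <= 0)) stopf("class weights must be positive")
  if (abs(sum(priors) - 1) > 1e-8) stopf("priors must sum to 1")
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  d <- ncol(X)
  means <- class_means(X, y)
  sigma <- matrix(0, d, d)
  for (i in 1:2) {
    Xi <- sweep(X[y == levels(y)[i], , drop = FALSE], 2, means[i, ])
    sigma <- sigma + w[i] * crossprod(Xi)
  }
  ridge_used <- 0
  sigma_inv <- tryCatch(solve(sigma), error = function(e) NULL)
  if (is.null(sigma_inv)) {
    if (ridge_eps <= 0) stopf("scatter matrix is singular and the ridge fallback is disabled")
    ridge_used <- ridge_eps * max(sum(diag(sigma)), 1) / d
    warnf("singular scatter matrix: adding ridge %.3g to the diagonal", ridge_used)
    sigma_inv <- solve(sigma + diag(ridge_used, d))
  }
  structure(list(
    class_labels = levels(y), means = means, sigma = sigma,
    sigma_inv = sigma_inv, weights = w, priors = priors,
    ridge_eps = ridge_eps, ridge_used = ridge_used
  ), class = "bbb_wlda")
}

#' Posterior probabilities from a weighted linear discriminant
#'
#' Softmax over the two linear discriminants, computed with a
#' max-subtraction guard so large discriminant values cannot overflow.
#' The two posteriors always sum to 1.
#'
#' @param model A `bbb_wlda`.
#' @param X Feature matrix (or single vector).
#' @return Numeric matrix, one row per beat, columns named by class.
#' @export
wlda_posterior <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != ncol(model$means)) {
    stopf("feature dimension %d does not match model dimension %d",
          ncol(X), ncol(model$means))
  }
  if (any(!is.finite(X))) stopf("non-finite feature values")
  G <- vapply(1:2, function(i) {
    a <- model$sigma_inv %*% model$means[i, ]
    as.vector(X %*% a) - 0.5 * sum(model$means[i, ] * a) + log(model$priors[i])
  }, numeric(nrow(X)))
  G <- matrix(G, ncol = 2)
  G <- G - apply(G, 1, max)
  E <- exp(G)
  P <- E / rowSums(E)
  colnames(P) <- model$class_labels
  P
}

#' Predict with the weighted linear discriminant
#'
#' Maximum posterior; an exact 0.5/0.5 tie goes to NORM.
#'
#' @inheritParams wlda_posterior
#' @return Character vector of labels.
#' @export
predict_wlda <- function(model, X) {
  P <- wlda_posterior(model, X)
  out <- ifelse(P[, 1] > P[, 2], model$class_labels[[1]],
                ifelse(P[, 2] > P[, 1], model$class_labels[[2]],
                       tie_label(model$class_labels)))
  unname(out)
}

# ---- linear SVM -------------------------------------------------------------

#' Fit a linear support vector machine
#'
#' L2-regularised hinge-loss linear classifier with penalty `C`, optionally
#' with per-class penalty weights for imbalanced problems (penalty
#' `C * class_weights[i]` for class `i`). Features are not rescaled. The
#' separating hyperplane (`weight_vector`, `bias`) is extracted so
#' prediction is an explicit sign test.
#'
#' @param X Feature matrix.
#' @param y Two-level labels.
#' @param C Penalty parameter (> 0).
#' @param class_weights Positive pair, `(1, 1)` for the plain SVM.
#' @return An object of class `bbb_svm`.
#' @export
fit_linear_svm <- function(X, y, C = 1, class_weights = c(1, 1)) {
  y <- check_two_class(y)
  if (C <= 0) stopf("penalty C must be positive")
  cw <- stats::setNames(class_weights, levels(y))
  fit <- e1071::svm(x = X, y = y, kernel = "linear", cost = C, scale = FALSE,
                    class.weights = cw)
  wv <- as.vector(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # orient the hyperplane so that a positive decision value means the first
  # factor level, regardless of the solver's internal class ordering
  pred <- as.character(predict(fit, X))
  dv <- as.vector(X %*% wv) + b
  if (mean((dv > 0) == (pred == levels(y)[[1]])) < 0.5) {
    wv <- -wv
    b <- -b
  }
  structure(list(
    class_labels = levels(y), weight_vector = wv, bias = b,
    penalty_C = C, class_weights = class_weights,
    n_support = nrow(fit$SV)
  ), class = "bbb_svm")
}

#' Predict with a linear SVM
#'
#' Label by the sign of `weight_vector . x + bias`; a decision value of
#' exactly zero goes to NORM when NORM is a class label, else to the first
#' class label.
#'
#' @param model A `bbb_svm`.
#' @param X Feature matrix (or single vector).
#' @return Character vector of labels.
#' @export
predict_svm <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != length(model$weight_vector)) {
    stopf("feature dimension %d does not match model dimension %d",
          ncol(X), length(model$weight_vector))
  }
  dv <- as.vector(X %*% model$weight_vector) + model$bias
  out <- ifelse(dv > 0, model$class_labels[[1]],
                ifelse(dv < 0, model$class_labels[[2]], tie_label(model$class_labels)))
  unname(out)
}

svm_decision_values <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  as.vector(X %*% model$weight_vector) + model$bias
}

# ---- serialization ----------------------------------------------------------

#' Serialize / restore fitted models and ICA bases
#'
#' Models are written as a single versioned JSON document (metadata plus
#' numeric arrays at full precision) and restored to identical objects.
#'
#' @param object A `bbb_centroid`, `bbb_wlda`, `bbb_svm` or
#'   `bbb_ica_basis`.
#' @param path Output / input file path.
#' @return `write_model()` the path invisibly; `read_model()` the restored
#'   object.
#' @export
write_model <- function(object, path) {
  kind <- class(object)[[1]]
  payload <- unclass(object)
  payload$.kind <- kind
  payload$.format_version <- 1L
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  kind <- payload$.kind
  payload$.kind <- NULL
  payload$.format_version <- NULL
  for (nm in c("centroids", "means", "sigma", "sigma_inv", "components",
               "pinv_components")) {
    if (!is.null(payload[[nm]]) && !is.matrix(payload[[nm]])) {
      payload[[nm]] <- as.matrix(payload[[nm]])
    }
  }
  structure(payload, class = kind)
}
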