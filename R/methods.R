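# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a centroid classifier
#'
#' @param x A `bbb_centroid`.
#' @param ... Unused.
#' @return Tibble: `class`, `dimension`, `centroid`.
#' @export
tidy.bbb_centroid <- function(x, ...) {
  purrr::map_dfr(seq_along(x$class_labels), function(i) {
    tibble::tibble(class = x$class_labels[[i]],
                   dimension = seq_len(ncol(x$centroids)),
                   centroid = x$centroids[i, ])
  })
}

#' @rdname tidy.bbb_centroid
#' @export
glance.bbb_centroid <- function(x, ...) {
  tibble::tibble(classes = paste(x$class_labels, collapse = "/"),
                 n_dimensions = ncol(x$centroids))
}

#' Tidy a weighted linear discriminant
#'
#' @param x A `bbb_wlda`.
#' @param ... Unused.
#' @return Tibble: `class`, `weight`, `prior`, `dimension`, `mean`.
#' @export
tidy.bbb_wlda <- function(x, ...) {
  purrr::map_dfr(seq_along(x$class_labels), function(i) {
    tibble::tibble(class = x$class_labels[[i]], weight = x$weights[[i]],
                   prior = x$priors[[i]], dimension = seq_len(ncol(x$means)),
                   mean = x$means[i, ])
  })
}

#' @rdname tidy.bbb_wlda
#' @export
glance.bbb_wlda <- function(x, ...) {
  tibble::tibble(classes = paste(x$class_labels, collapse = "/"),
                 n_dimensions = ncol(x$means),
                 w1 = x$weights[[1]], w2 = x$weights[[2]],
                 ridge_used = x$ridge_used)
}

#' Tidy a linear SVM
#'
#' @param x A `bbb_svm`.
#' @param ... Unused.
#' @return Tibble: `term` (`bias` or dimension index), `estimate`.
#' @export
tidy.bbb_svm <- function(x, ...) {
  tibble::tibble(
    term = c(paste0("x", seq_along(x$weight_vector)), "bias"),
    estimate = c(x$weight_vector, x$bias)
  )
}

#' @rdname tidy.bbb_svm
#' @export
glance.bbb_svm <- function(x, ...) {
  tibble::tibble(classes = paste(x$class_labels, collapse = "/"),
                 C = x$penalty_C, n_support = x$n_support,
                 n_dimensions = length(x$weight_vector))
}

#' Tidy an ensemble
#'
#' @param x A `bbb_ensemble`.
#' @param ... Unused.
#' @return `glance()`: one-row tibble of configuration and selected
#'   parameters; `tidy()`: one row per component classifier.
#' @export
glance.bbb_ensemble <- function(x, ...) {
  tibble::tibble(lead_config = x$lead_config, n_components = x$n_components,
                 w1 = x$wlda_w[[1]], w2 = x$wlda_w[[2]], C = x$svm_C,
                 ica_seed = x$ica_seed, cv_seed = x$cv_seed)
}

#' @rdname glance.bbb_ensemble
#' @export
tidy.bbb_ensemble <- function(x, ...) {
  tibble::tibble(
    classifier = c("centroid", "wlda", "svm"),
    pair = c("NORM/LBBB", "NORM/RBBB", "LBBB/RBBB"),
    features = c("morphology+RR", "ICA+RR", "ICA+RR"),
    n_dimensions = c(ncol(x$centroid$centroids), ncol(x$wlda$means),
                     length(x$svm$weight_vector))
  )
}

#' Tidy a confusion matrix
#'
#' @param x A `bbb_confusion`.
#' @param ... Unused.
#' @return Long tibble: `reference`, `algorithm`, `n`.
#' @export
tidy.bbb_confusion <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    reference = rep(rownames(m), times = ncol(m)),
    algorithm = rep(colnames(m), each = nrow(m)),
    n = as.integer(as.vector(m))
  )
}

#' Heatmap of a confusion matrix
#'
#' @param object A `bbb_confusion`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bbb_confusion <- function(object, ...) {
  d <- tidy(object)
  d$reference <- factor(d$reference, levels = rev(rownames(object)))
  d$algorithm <- factor(d$algorithm, levels = colnames(object))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$algorithm, y = .data$reference,
                                  fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_fill_viridis_c(trans = "log1p") +
    ggplot2::labs(x = "Algorithm label", y = "Reference label", fill = "beats") +
    ggplot2::theme_minimal()
}

#' Plot beat waveforms
#'
#' Overlays the two-lead waveforms of a (sub)set of beats, faceted by
#' class and lead.
#'
#' @param beats A beats tibble.
#' @param max_per_class Beats drawn per class (default 20).
#' @return A ggplot.
#' @export
plot_beats <- function(beats, max_per_class = 20) {
  sub <- dplyr::slice_head(dplyr::group_by(beats, .data$label), n = max_per_class)
  sub <- dplyr::ungroup(sub)
  long <- purrr::map_dfr(seq_len(nrow(sub)), function(i) {
    n <- length(sub$lead_a[[i]])
    tibble::tibble(
      beat = i, label = as.character(sub$label[[i]]),
      sample = rep(seq_len(n) - 1, 2),
      lead = rep(c("A", "B"), each = n),
      value = c(sub$lead_a[[i]], sub$lead_b[[i]])
    )
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$value,
                                     group = .data$beat)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::facet_grid(lead ~ label) +
    ggplot2::labs(x = "sample (R wave at 100)", y = "normalized amplitude") +
    ggplot2::theme_minimal()
}

#' Plot independent components of a fitted basis
#'
#' @param basis A `bbb_ica_basis`.
#' @param n_show Number of leading components to draw.
#' @return A ggplot.
#' @export
plot_ica_components <- function(basis, n_show = 6) {
  n_show <- min(n_show, nrow(basis$components))
  long <- purrr::map_dfr(seq_len(n_show), function(i) {
    tibble::tibble(component = i,
                   sample = seq_len(ncol(basis$components)) - 1,
                   value = basis$components[i, ])
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(title = sprintf("Lead %s independent components", basis$lead),
                  x = "sample", y = "amplitude") +
    ggplot2::theme_minimal()
}
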