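# Confusion matrices and the metric suite: per-class sensitivity (Se) and
# positive predictive value (PP) — reported as specificity (Sp) and
# negative predictive value (NP) for the NORM class — plus overall
# accuracy. Rows are the reference label, columns the algorithm label.

#' Build a reference-by-algorithm confusion matrix
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param labels Class order for rows and columns; defaults to
#'   `NORM, LBBB, RBBB` restricted to the labels present.
#' @return An object of class `bbb_confusion`: an integer matrix with rows
#'   = reference, columns = algorithm.
#' @export
confusion <- function(y_true, y_pred, labels = NULL) {
  if (length(y_true) != length(y_pred)) stopf("y_true and y_pred lengths differ")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (is.null(labels)) labels <- intersect(beat_labels(), unique(c(y_true, y_pred)))
  bad <- setdiff(unique(c(y_true, y_pred)), labels)
  if (length(bad) > 0) stopf("labels not covered by `labels`: %s", paste(bad, collapse = ", "))
  m <- table(factor(y_true, levels = labels), factor(y_pred, levels = labels))
  m <- matrix(as.integer(m), nrow = length(labels),
              dimnames = list(reference = labels, algorithm = labels))
  new_confusion(m)
}

#' Construct a confusion matrix object from counts
#'
#' @param counts Square non-negative integer matrix, rows = reference
#'   label, columns = algorithm label; `dimnames` give the class labels.
#' @return A `bbb_confusion`.
#' @export
new_confusion <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) != ncol(counts)) {
    stopf("counts must be a square matrix")
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    stopf("counts must be non-negative integers")
  }
  if (is.null(dimnames(counts))) stopf("counts must carry class labels as dimnames")
  structure(counts, class = c("bbb_confusion", "matrix", "array"))
}

#' @export
print.bbb_confusion <- function(x, ...) {
  cat("Confusion matrix (rows = reference label, columns = algorithm label)\n")
  print(unclass(x))
  invisible(x)
}

#' Metric suite from a confusion matrix
#'
#' For each class: sensitivity `Se = diag/row total` and positive
#' predictive value `PP = diag/column total`; for NORM these are reported
#' under their conventional names specificity (Sp) and negative predictive
#' value (NP). Overall accuracy is `trace/total`. A zero row or column
#' total makes the metric undefined (`NA`, never 0 or 1).
#'
#' @param cm A `bbb_confusion`.
#' @param percent Report values in percent (default) or as fractions.
#' @return A tibble with columns `class`, `metric` (`Se`/`PP`, or
#'   `Sp`/`NP` for NORM), `value`, plus one `Acc` row with `class = "all"`.
#' @export
metrics_from_confusion <- function(cm, percent = TRUE) {
  stopifnot(inherits(cm, "bbb_confusion"))
  m <- unclass(cm)
  labels <- rownames(m)
  scale <- if (percent) 100 else 1
  rows <- purrr::map_dfr(seq_along(labels), function(i) {
    rs <- sum(m[i, ]); cs <- sum(m[, i])
    se <- if (rs > 0) m[i, i] / rs else NA_real_
    pp <- if (cs > 0) m[i, i] / cs else NA_real_
    is_norm <- labels[[i]] == "NORM"
    tibble::tibble(
      class = labels[[i]],
      metric = if (is_norm) c("Sp", "NP") else c("Se", "PP"),
      value = c(se, pp) * scale
    )
  })
  total <- sum(m)
  acc <- if (total > 0) sum(diag(m)) / total else NA_real_
  dplyr::bind_rows(rows, tibble::tibble(class = "all", metric = "Acc",
                                        value = acc * scale))
}

metric_value <- function(metrics, class, metric) {
  v <- metrics$value[metrics$class == class & metrics$metric == metric]
  if (length(v) == 0) NA_real_ else v[[1]]
}

#' Per-record metric table
#'
#' One metric row set per record; classes absent from a record (zero
#' reference beats and zero predictions) yield undefined (`NA`) entries,
#' rendered as `"-"` by [format_metrics_table()].
#'
#' @param predictions Output of [classify_beats()] (needs `record_id`,
#'   `label`, `predicted`).
#' @param labels Class order, default `NORM, LBBB, RBBB`.
#' @return A tibble keyed by `record_id` with per-class beat counts and
#'   wide metric columns.
#' @export
per_record_metrics <- function(predictions, labels = beat_labels()) {
  purrr::map_dfr(split(predictions, predictions$record_id), function(p) {
    cm <- confusion(p$label, p$predicted, labels = labels)
    met <- metrics_from_confusion(cm)
    wide <- tidyr::pivot_wider(dplyr::filter(met, .data$class != "all"),
                               names_from = c("class", "metric"),
                               values_from = "value", names_sep = "_")
    cnt <- as.list(rowSums(unclass(cm)))
    names(cnt) <- paste0("n_", names(cnt))
    dplyr::bind_cols(tibble::tibble(record_id = p$record_id[[1]]),
                     tibble::as_tibble(cnt), wide,
                     tibble::tibble(Acc = metric_value(met, "all", "Acc")))
  })
}

#' Compare evaluated runs across lead configurations
#'
#' Binds the global metric tables of several evaluated runs side by side
#' (one row per configuration, wide metric columns). Missing
#' configurations are omitted with a warning.
#'
#' @param runs Named list of [classify_beats()] outputs, e.g.
#'   `list(A = ..., B = ..., AB = ...)`.
#' @return A tibble, one row per configuration.
#' @export
compare_lead_configs <- function(runs) {
  runs <- runs[!vapply(runs, is.null, logical(1))]
  if (length(runs) == 0) stopf("no evaluated runs supplied")
  expected <- c("A", "B", "AB")
  missing <- setdiff(expected, names(runs))
  if (length(missing) > 0) {
    warnf("missing lead configuration(s): %s", paste(missing, collapse = ", "))
  }
  purrr::map_dfr(names(runs), function(nm) {
    met <- metrics_from_confusion(confusion(runs[[nm]]$label, runs[[nm]]$predicted))
    wide <- tidyr::pivot_wider(dplyr::filter(met, .data$class != "all"),
                               names_from = c("class", "metric"),
                               values_from = "value", names_sep = "_")
    dplyr::bind_cols(tibble::tibble(lead_config = nm), wide,
                     tibble::tibble(Acc = metric_value(met, "all", "Acc")))
  })
}

#' Format a metric table for reporting
#'
#' Rounds percent metrics half-up to one decimal and renders undefined
#' entries as `"-"`. Raw fractions are always retained in the unformatted
#' tibbles; this is presentation only.
#'
#' @param metrics A tibble with numeric metric columns.
#' @param digits Decimal places (default 1).
#' @return A character data frame of the same shape.
#' @export
format_metrics_table <- function(metrics, digits = 1) {
  as.data.frame(lapply(metrics, function(col) {
    if (!is.numeric(col)) return(as.character(col))
    out <- ifelse(is.na(col), "-", formatC(round_half_up(col, digits),
                                           format = "f", digits = digits))
    out
  }), check.names = FALSE)
}

#' Write a confusion matrix as CSV
#'
#' @param cm A `bbb_confusion`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_confusion_csv <- function(cm, path) {
  utils::write.csv(as.data.frame(unclass(cm)), path, row.names = TRUE)
  invisible(path)
}
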