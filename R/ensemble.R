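# Fusion of the three one-vs-one decisions by majority vote, and the
# end-to-end train/classify wrappers.

#' Majority vote over the three one-vs-one labels
#'
#' Each test beat receives one label from each classifier (centroid:
#' NORM/LBBB; discriminant: NORM/RBBB; SVM: LBBB/RBBB). Any label with at
#' least two votes wins; when all three labels occur once — the only
#' ambiguous case — the beat is assigned to NORM, the overwhelmingly most
#' prevalent class. Total over all 8 vote combinations.
#'
#' @param v1 Centroid votes (`NORM`/`LBBB`).
#' @param v2 Discriminant votes (`NORM`/`RBBB`).
#' @param v3 SVM votes (`LBBB`/`RBBB`).
#' @return Character vector over `NORM`, `LBBB`, `RBBB`.
#' @export
#' @examples
#' vote_majority("NORM", "RBBB", "LBBB")  # three-way split -> NORM
vote_majority <- function(v1, v2, v3) {
  if (!all(v1 %in% c("NORM", "LBBB"))) stopf("v1 must be NORM or LBBB")
  if (!all(v2 %in% c("NORM", "RBBB"))) stopf("v2 must be NORM or RBBB")
  if (!all(v3 %in% c("LBBB", "RBBB"))) stopf("v3 must be LBBB or RBBB")
  out <- character(length(v1))
  out[v1 == "NORM" & v2 == "NORM"] <- "NORM"          # two NORM votes
  out[v1 == "LBBB" & v3 == "LBBB"] <- "LBBB"
  out[v2 == "RBBB" & v3 == "RBBB"] <- "RBBB"
  out[out == ""] <- "NORM"                            # three distinct labels
  out
}

#' Train the full three-classifier ensemble
#'
#' Fits, on a labelled training set of beats: per-lead ICA bases on the
#' designated basis subset; the NORM-vs-LBBB centroid classifier on
#' morphology + RR; the NORM-vs-RBBB weighted linear discriminant and the
#' LBBB-vs-RBBB linear SVM on ICA + RR. The discriminant weights
#' `(w1, w2)` and SVM penalty `C` are chosen by 10-fold cross-validation
#' unless supplied.
#'
#' @param train_beats Beats tibble with all three classes.
#' @param lead_config `"AB"` (two-lead), `"A"` or `"B"`.
#' @param n_components ICA components per lead (default 100).
#' @param ica_seed,cv_seed Seeds for basis fitting and fold assignment.
#' @param basis_selection `"per_record"` applies the canonical
#'   10/100/80-beats-per-record rule; `"quota"` (default) takes balanced
#'   per-class quotas round-robin over records, which also works for small
#'   synthetic cohorts.
#' @param wlda_w Optional `(w1, w2)` to skip cross-validation.
#' @param svm_C Optional penalty to skip cross-validation.
#' @param k Number of cross-validation folds.
#' @return An object of class `bbb_ensemble` holding the three models, the
#'   ICA bases, the lead configuration, the selected parameters and the
#'   cross-validation audit tables (`cv_wlda`, `cv_svm`).
#' @export
train_ensemble <- function(train_beats, lead_config = c("AB", "A", "B"),
                           n_components = 100, ica_seed = 1, cv_seed = 1,
                           basis_selection = c("quota", "per_record"),
                           wlda_w = NULL, svm_C = NULL, k = 10) {
  lead_config <- match.arg(lead_config)
  basis_selection <- match.arg(basis_selection)
  leads <- strsplit(lead_config, "")[[1]]
  if (!all(beat_labels() %in% as.character(train_beats$label))) {
    stopf("training set must contain NORM, LBBB and RBBB beats")
  }

  basis_beats <- switch(basis_selection,
    per_record = select_basis_beats(train_beats),
    quota = select_basis_quota(train_beats)
  )
  bases <- stats::setNames(lapply(leads, function(l) {
    fit_ica_basis(basis_beats, lead = l, n_components = n_components, seed = ica_seed)
  }), leads)

  morph <- assemble_morph(train_beats, leads = leads)
  icaf <- assemble_ica(train_beats, bases, leads = leads)
  y <- as.character(train_beats$label)

  nl <- y %in% c("NORM", "LBBB")
  nr <- y %in% c("NORM", "RBBB")
  lr <- y %in% c("LBBB", "RBBB")

  cv_wlda <- NULL
  if (is.null(wlda_w)) {
    sel <- select_wlda_params(icaf[nr, , drop = FALSE],
                              factor(y[nr], levels = c("NORM", "RBBB")),
                              seed = cv_seed, k = k)
    wlda_w <- c(sel$w1, sel$w2)
    cv_wlda <- sel$table
  }
  cv_svm <- NULL
  if (is.null(svm_C)) {
    sel <- select_svm_C(icaf[lr, , drop = FALSE],
                        factor(y[lr], levels = c("LBBB", "RBBB")),
                        seed = cv_seed, k = k)
    svm_C <- sel$C
    cv_svm <- sel$table
  }

  structure(list(
    lead_config = lead_config,
    n_components = n_components,
    bases = bases,
    centroid = fit_centroid(morph[nl, , drop = FALSE],
                            factor(y[nl], levels = c("NORM", "LBBB"))),
    wlda = fit_wlda(icaf[nr, , drop = FALSE],
                    factor(y[nr], levels = c("NORM", "RBBB")),
                    w = wlda_w, priors = c(0.5, 0.5)),
    svm = fit_linear_svm(icaf[lr, , drop = FALSE],
                         factor(y[lr], levels = c("LBBB", "RBBB")), C = svm_C),
    wlda_w = wlda_w,
    svm_C = svm_C,
    cv_wlda = cv_wlda,
    cv_svm = cv_svm,
    ica_seed = ica_seed,
    cv_seed = cv_seed
  ), class = "bbb_ensemble")
}

#' @export
print.bbb_ensemble <- function(x, ...) {
  cat(sprintf(
    "<bbb_ensemble> leads %s, %d ICA components/lead\n  WLDA (w1, w2) = (%g, %g); SVM C = %g\n",
    x$lead_config, x$n_components, x$wlda_w[[1]], x$wlda_w[[2]], x$svm_C))
  invisible(x)
}

#' Classify beats with a trained ensemble
#'
#' Assembles the morphology and ICA feature vectors under the ensemble's
#' lead configuration, queries the three classifiers and fuses their votes
#' by [vote_majority()]. The raw vote triple is retained per beat for
#' audit.
#'
#' @param ensemble A `bbb_ensemble`.
#' @param beats Beats tibble.
#' @return The input tibble (without waveform columns) with `v1`, `v2`,
#'   `v3` and `predicted` columns appended.
#' @export
classify_beats <- function(ensemble, beats) {
  leads <- strsplit(ensemble$lead_config, "")[[1]]
  morph <- assemble_morph(beats, leads = leads)
  icaf <- assemble_ica(beats, ensemble$bases, leads = leads)
  v1 <- predict_centroid(ensemble$centroid, morph)
  v2 <- predict_wlda(ensemble$wlda, icaf)
  v3 <- predict_svm(ensemble$svm, icaf)
  tibble::tibble(
    record_id = beats$record_id,
    r_index = beats$r_index,
    label = beats$label,
    v1 = v1, v2 = v2, v3 = v3,
    predicted = factor(vote_majority(v1, v2, v3), levels = beat_labels())
  )
}

#' Write the per-beat vote audit trail
#'
#' CSV of `(record_id, r_index, label, v1, v2, v3, predicted)`.
#'
#' @param predictions Output of [classify_beats()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_predictions_csv <- function(predictions, path) {
  out <- dplyr::mutate(predictions,
                       label = as.character(.data$label),
                       predicted = as.character(.data$predicted))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
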