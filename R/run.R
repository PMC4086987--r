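# Reproducible run entry points: simulate / train / evaluate / reproduce.
# These back the command-line interface (inst/cli/bbb.R) and always write
# a manifest (config echo + seeds + package version) next to their
# outputs.

write_manifest <- function(out_dir, entries) {
  entries$package_version <- as.character(utils::packageVersion("bbbensemble"))
  entries$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(entries, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(entries)
}

#' Simulate a synthetic dataset to disk
#'
#' Draws an inter-patient-style synthetic dataset and writes
#' `train_beats.csv`, `test_beats.csv` and a manifest. Byte-identical on
#' re-run with the same configuration.
#'
#' @param out_dir Output directory (created).
#' @param config A `bbb_generator_config`.
#' @return Invisibly, the manifest list.
#' @export
run_simulate <- function(out_dir, config = make_generator_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- generate_dataset(config)
  write_beats_csv(ds$train, file.path(out_dir, "train_beats.csv"))
  write_beats_csv(ds$test, file.path(out_dir, "test_beats.csv"))
  write_manifest(out_dir, list(
    command = "simulate",
    seed = config$seed,
    n_per_class = as.list(config$n_per_class),
    n_subjects = as.list(config$n_subjects),
    noise_sd = config$noise_sd,
    amplitude_jitter_sd = config$amplitude_jitter_sd,
    n_train = nrow(ds$train), n_test = nrow(ds$test)
  ))
}

#' Train the ensemble from a beats file
#'
#' Reads training beats (CSV layout of [write_beats_csv()]), trains the
#' three-classifier ensemble with cross-validated parameter selection, and
#' writes the serialized models, ICA bases, CV audit tables and a manifest
#' recording the selected parameters and seeds.
#'
#' @param train_csv Path to the training beats CSV.
#' @param out_dir Output directory.
#' @param lead_config `"AB"`, `"A"` or `"B"`.
#' @param n_components ICA components per lead.
#' @param ica_seed,cv_seed Seeds.
#' @param basis_selection Passed to [train_ensemble()].
#' @return Invisibly, the trained `bbb_ensemble`.
#' @export
run_train <- function(train_csv, out_dir, lead_config = "AB", n_components = 100,
                      ica_seed = 1, cv_seed = 1, basis_selection = "quota") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  train_beats <- read_beats_csv(train_csv)
  ens <- train_ensemble(train_beats, lead_config = lead_config,
                        n_components = n_components, ica_seed = ica_seed,
                        cv_seed = cv_seed, basis_selection = basis_selection)
  write_model(ens$centroid, file.path(out_dir, "model_centroid.json"))
  write_model(ens$wlda, file.path(out_dir, "model_wlda.json"))
  write_model(ens$svm, file.path(out_dir, "model_svm.json"))
  for (l in names(ens$bases)) {
    write_model(ens$bases[[l]], file.path(out_dir, sprintf("ica_basis_%s.json", l)))
  }
  utils::write.csv(ens$cv_wlda, file.path(out_dir, "cv_wlda.csv"), row.names = FALSE)
  utils::write.csv(ens$cv_svm, file.path(out_dir, "cv_svm.csv"), row.names = FALSE)
  write_manifest(out_dir, list(
    command = "train", train_csv = train_csv, lead_config = lead_config,
    n_components = n_components, ica_seed = ica_seed, cv_seed = cv_seed,
    selected = list(w1 = ens$wlda_w[[1]], w2 = ens$wlda_w[[2]], C = ens$svm_C)
  ))
  invisible(ens)
}

read_ensemble <- function(model_dir) {
  leads <- sub("^ica_basis_(.).json$", "\\1",
               basename(Sys.glob(file.path(model_dir, "ica_basis_?.json"))))
  bases <- stats::setNames(lapply(leads, function(l) {
    read_model(file.path(model_dir, sprintf("ica_basis_%s.json", l)))
  }), leads)
  wlda <- read_model(file.path(model_dir, "model_wlda.json"))
  svm <- read_model(file.path(model_dir, "model_svm.json"))
  structure(list(
    lead_config = paste(leads, collapse = ""),
    n_components = bases[[1]]$n_components,
    bases = bases,
    centroid = read_model(file.path(model_dir, "model_centroid.json")),
    wlda = wlda, svm = svm,
    wlda_w = wlda$weights, svm_C = svm$penalty_C,
    cv_wlda = NULL, cv_svm = NULL, ica_seed = NA, cv_seed = NA
  ), class = "bbb_ensemble")
}

#' Evaluate a trained ensemble on a beats file
#'
#' Classifies the test beats, and writes the per-beat vote audit CSV, the
#' confusion matrix CSV, global and per-record metric tables (raw and
#' report-formatted) and a manifest.
#'
#' @param model_dir Directory written by [run_train()].
#' @param test_csv Path to the test beats CSV.
#' @param out_dir Output directory.
#' @return Invisibly, a list with `predictions`, `confusion`, `metrics`,
#'   `per_record`.
#' @export
run_evaluate <- function(model_dir, test_csv, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ens <- read_ensemble(model_dir)
  test_beats <- read_beats_csv(test_csv)
  preds <- classify_beats(ens, test_beats)
  cm <- confusion(preds$label, preds$predicted)
  met <- metrics_from_confusion(cm)
  per_rec <- per_record_metrics(preds)
  write_predictions_csv(preds, file.path(out_dir, "votes.csv"))
  write_confusion_csv(cm, file.path(out_dir, "confusion.csv"))
  utils::write.csv(met, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(per_rec, file.path(out_dir, "per_record_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(format_metrics_table(per_rec),
                   file.path(out_dir, "per_record_metrics_report.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, list(
    command = "evaluate", model_dir = model_dir, test_csv = test_csv,
    n_beats = nrow(preds),
    accuracy = metric_value(met, "all", "Acc")
  ))
  invisible(list(predictions = preds, confusion = cm, metrics = met,
                 per_record = per_rec))
}

#' Run the full inter-patient protocol from a WFDB directory
#'
#' Loads the training and testing records of a record division, extracts
#' normalized beats, trains the ensemble (cross-validated parameter
#' selection included) on the training split and evaluates on the testing
#' split, writing all artefacts under `out_dir`.
#'
#' @param data_dir Directory of WFDB records.
#' @param out_dir Output directory.
#' @param split A record division as from [default_split()].
#' @param lead_config,n_components,ica_seed,cv_seed,basis_selection Passed
#'   to [train_ensemble()].
#' @param fs_expected Expected sampling frequency of the records.
#' @return Invisibly, a list with `ensemble`, `counts` (per-split beat
#'   counts) and the [run_evaluate()] result list.
#' @export
run_reproduce <- function(data_dir, out_dir, split = default_split(),
                          lead_config = "AB", n_components = 100,
                          ica_seed = 1, cv_seed = 1,
                          basis_selection = "per_record", fs_expected = 360) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  load_split <- function(ids) {
    dplyr::bind_rows(lapply(ids, function(id) {
      make_beats(load_record(file.path(data_dir, id), fs_expected = fs_expected,
                             symbol_map = split$symbol_map))
    }))
  }
  train_beats <- load_split(split$ds1_records)
  test_beats <- load_split(split$ds2_records)
  counts <- dplyr::bind_rows(
    dplyr::mutate(count_beats_by_type(data_dir, split$ds1_records,
                                      fs_expected = fs_expected,
                                      symbol_map = split$symbol_map),
                  dataset = "DS1", .before = 1),
    dplyr::mutate(count_beats_by_type(data_dir, split$ds2_records,
                                      fs_expected = fs_expected,
                                      symbol_map = split$symbol_map),
                  dataset = "DS2", .before = 1)
  )
  utils::write.csv(counts, file.path(out_dir, "beat_counts.csv"), row.names = FALSE)

  write_beats_csv(train_beats, file.path(out_dir, "train_beats.csv"))
  write_beats_csv(test_beats, file.path(out_dir, "test_beats.csv"))
  ens <- run_train(file.path(out_dir, "train_beats.csv"),
                   file.path(out_dir, "model"),
                   lead_config = lead_config, n_components = n_components,
                   ica_seed = ica_seed, cv_seed = cv_seed,
                   basis_selection = basis_selection)
  eval_res <- run_evaluate(file.path(out_dir, "model"),
                           file.path(out_dir, "test_beats.csv"),
                           file.path(out_dir, "evaluation"))
  invisible(list(ensemble = ens, counts = counts, evaluation = eval_res))
}
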