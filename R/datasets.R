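# Record-level data access: the inter-patient record division, annotation
# label mapping, and per-record beat streams.

#' The inter-patient record division
#'
#' Returns the canonical division of the 48 study records into a 22-record
#' training set (DS1), a 22-record testing set (DS2) and 4 excluded paced
#' records. The lists are data, shipped as an editable YAML config, not
#' hard-coded logic.
#'
#' @param config_path Path to a YAML file with `ds1`, `ds2`, `excluded` and
#'   `symbol_map` entries; defaults to the packaged division.
#' @return A list with character vectors `ds1_records`, `ds2_records`,
#'   `excluded_records` and the named character vector `symbol_map`.
#' @export
#' @examples
#' split <- default_split()
#' length(split$ds1_records)  # 22
default_split <- function(config_path = NULL) {
  if (is.null(config_path)) {
    config_path <- system.file("extdata", "mitdb_split.yaml", package = "bbbensemble")
  }
  cfg <- yaml::read_yaml(config_path)
  ds1 <- as.character(cfg$ds1)
  ds2 <- as.character(cfg$ds2)
  excl <- as.character(cfg$excluded)
  if (length(intersect(ds1, ds2)) > 0) stopf("ds1 and ds2 overlap in %s", config_path)
  if (anyDuplicated(c(ds1, ds2, excl))) stopf("duplicated record id in %s", config_path)
  sym <- unlist(cfg$symbol_map)
  list(
    ds1_records = ds1,
    ds2_records = ds2,
    excluded_records = excl,
    symbol_map = sym
  )
}

#' Map an annotation symbol to a studied beat class
#'
#' Total and deterministic: the normal-beat symbol maps to `NORM`, the left
#' and right bundle branch block symbols to `LBBB` / `RBBB`, and every
#' other symbol (including unknown ones) to `OTHER`, which downstream
#' preprocessing drops.
#'
#' @param symbol Character vector of single-character annotation symbols.
#' @param symbol_map Named character vector (names = symbols); defaults to
#'   the packaged mapping `N/L/R`.
#' @return Character vector over `NORM`, `LBBB`, `RBBB`, `OTHER`.
#' @export
#' @examples
#' map_beat_label(c("N", "L", "R", "V", "!"))
map_beat_label <- function(symbol, symbol_map = NULL) {
  if (is.null(symbol_map)) symbol_map <- c(N = "NORM", L = "LBBB", R = "RBBB")
  out <- unname(symbol_map[symbol])
  out[is.na(out)] <- "OTHER"
  out
}

#' Load a two-lead record with labelled beat annotations
#'
#' Reads a WFDB record, checks the two-lead contract, maps annotation
#' symbols to classes and returns the raw material for beat extraction.
#'
#' @param path Record path without extension.
#' @param fs_expected Expected sampling frequency; mismatch is an error
#'   (no resampling is performed). `NULL` accepts any.
#' @param symbol_map Passed to [map_beat_label()].
#' @param annotator Annotation extension, default `"atr"`.
#' @return A list with `record_id`, `fs`, `lead_a`, `lead_b` (numeric
#'   vectors) and `annotations` (tibble: `r_index`, `symbol`, `label`,
#'   sorted by `r_index`).
#' @export
load_record <- function(path, fs_expected = 360, symbol_map = NULL, annotator = "atr") {
  rec <- read_wfdb_record(path, annotator = annotator)
  if (ncol(rec$signals) < 2) {
    stopf("record %s has %d channel(s); two leads are required", rec$record_id, ncol(rec$signals))
  }
  if (!is.null(fs_expected) && !isTRUE(all.equal(rec$fs, fs_expected))) {
    stopf("record %s sampled at %g Hz, expected %g Hz (no resampling supported)",
          rec$record_id, rec$fs, fs_expected)
  }
  ann <- rec$annotations
  if (is.null(ann)) stopf("record %s has no annotation file", rec$record_id)
  n <- nrow(rec$signals)
  if (any(ann$r_index >= n | ann$r_index < 0)) {
    stopf("record %s: annotation index beyond signal end (length %d)", rec$record_id, n)
  }
  ann$label <- map_beat_label(ann$symbol, symbol_map)
  list(
    record_id = rec$record_id,
    fs = rec$fs,
    lead_a = rec$signals[, 1],
    lead_b = rec$signals[, 2],
    annotations = ann
  )
}

#' Count annotated beats per studied class
#'
#' Tallies `NORM` / `LBBB` / `RBBB` annotations across a set of records;
#' `OTHER` annotations are excluded from the counts. Counting is additive
#' across disjoint record sets.
#'
#' @param data_dir Directory holding the WFDB files.
#' @param record_ids Character vector of record ids (file stems).
#' @param ... Passed to [load_record()].
#' @return A one-row tibble with columns `NORM`, `LBBB`, `RBBB`, `total`.
#' @export
count_beats_by_type <- function(data_dir, record_ids, ...) {
  counts <- c(NORM = 0L, LBBB = 0L, RBBB = 0L)
  for (id in record_ids) {
    rec <- load_record(file.path(data_dir, id), ...)
    tab <- table(factor(rec$annotations$label, levels = names(counts)))
    counts <- counts + as.integer(tab)
  }
  tibble::tibble(
    NORM = counts[["NORM"]], LBBB = counts[["LBBB"]], RBBB = counts[["RBBB"]],
    total = sum(counts)
  )
}
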