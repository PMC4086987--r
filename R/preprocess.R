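# Beat extraction: fixed-length windows around annotated R peaks,
# per-lead z-normalization, and RR intervals. No filtering or denoising is
# ever applied to the signal.

#' Extract a fixed-length window around an R peak
#'
#' Returns the `pre + post` samples `[r_index - pre, r_index + post)`
#' (0-based indexing). At 360 Hz the default 100 + 100 window spans 0.278 s
#' on either side of the R wave. Windows that cross a record boundary are
#' either edge-padded (first/last sample replicated) or rejected.
#'
#' @param signal Numeric vector.
#' @param r_index 0-based sample index of the R peak.
#' @param pre,post Samples before / after the R peak; `pre + post` is the
#'   beat length (200 by default).
#' @param edge `"pad"` (replicate the boundary sample) or `"skip"` (error,
#'   for the caller to catch and log).
#' @return Numeric vector of length `pre + post`.
#' @export
segment_beat <- function(signal, r_index, pre = 100, post = 100, edge = c("pad", "skip")) {
  edge <- match.arg(edge)
  n <- length(signal)
  idx <- seq.int(r_index - pre, r_index + post - 1L) + 1L  # to 1-based
  if (idx[1] < 1L || idx[length(idx)] > n) {
    if (edge == "skip") {
      stopf("beat window [%d, %d) crosses record boundary [0, %d)",
            r_index - pre, r_index + post, n)
    }
    idx <- pmin(pmax(idx, 1L), n)
  }
  signal[idx]
}

#' Z-normalize a beat segment
#'
#' Subtracts the mean and divides by the population (divide-by-N) standard
#' deviation, so every beat has mean 0 and standard deviation 1 regardless
#' of amplitude calibration. Idempotent, and invariant to positive affine
#' rescaling of the input.
#'
#' @param segment Numeric vector.
#' @return Numeric vector of the same length, mean 0, population sd 1.
#' @export
znormalize <- function(segment) {
  if (length(segment) == 0) stopf("cannot normalize an empty segment")
  s <- pop_sd(segment)
  if (s == 0) stopf("zero-variance (flatline) segment cannot be normalized")
  (segment - mean(segment)) / s
}

#' RR intervals from R-peak sample indices
#'
#' `rr[k]` is the interval preceding beat `k` in seconds. The first beat,
#' which has no preceding peak, copies the following interval so the output
#' is index-aligned with the input.
#'
#' @param r_indices Strictly ascending integer sample indices.
#' @param fs Sampling frequency in Hz.
#' @param first_beat `"copy_next"` (default) or `"na"`.
#' @return Numeric vector of seconds, same length as `r_indices`.
#' @export
#' @examples
#' compute_rr(c(100, 460, 820), fs = 360)
compute_rr <- function(r_indices, fs, first_beat = c("copy_next", "na")) {
  first_beat <- match.arg(first_beat)
  if (length(r_indices) < 2) stopf("RR intervals need at least two annotated beats")
  if (any(diff(r_indices) <= 0)) stopf("r_indices must be strictly ascending")
  if (fs <= 0) stopf("fs must be positive")
  d <- diff(r_indices) / fs
  c(if (first_beat == "copy_next") d[[1]] else NA_real_, d)
}

# Construct/validate the canonical beats tibble.
new_beats <- function(record_id, r_index, label, rr_s, lead_a, lead_b) {
  tibble::tibble(
    record_id = as.character(record_id),
    r_index = as.integer(r_index),
    label = as_beat_factor(label),
    rr_s = as.numeric(rr_s),
    lead_a = lead_a,
    lead_b = lead_b
  )
}

#' Build normalized beats from a loaded record
#'
#' Composes segmentation, per-lead z-normalization and RR computation over
#' every studied annotation of a record. `OTHER`-labelled annotations are
#' dropped; RR intervals are computed from the studied-beat R peaks only
#' (the beat stream actually classified). Beats whose window cannot be
#' extracted (flatline, or boundary crossing under `edge = "skip"`) are
#' skipped and reported.
#'
#' @param record A list as returned by [load_record()].
#' @param pre,post,edge Passed to [segment_beat()].
#' @param rr_unit `"seconds"` (default) or `"samples"`.
#' @return A beats tibble: `record_id`, `r_index`, `label` (factor
#'   NORM/LBBB/RBBB), `rr_s`, and list-columns `lead_a`, `lead_b` of
#'   200-sample normalized waveforms. Skipped beats are attached as the
#'   `"skipped"` attribute (tibble: `r_index`, `reason`).
#' @export
make_beats <- function(record, pre = 100, post = 100, edge = "pad",
                       rr_unit = c("seconds", "samples")) {
  rr_unit <- match.arg(rr_unit)
  ann <- dplyr::filter(record$annotations, .data$label != "OTHER")
  if (nrow(ann) < 2) stopf("record %s: fewer than two studied beats", record$record_id)
  rr <- compute_rr(ann$r_index, fs = if (rr_unit == "seconds") record$fs else 1)

  rows <- vector("list", nrow(ann))
  skipped <- list()
  for (k in seq_len(nrow(ann))) {
    res <- tryCatch({
      a <- znormalize(segment_beat(record$lead_a, ann$r_index[[k]], pre, post, edge))
      b <- znormalize(segment_beat(record$lead_b, ann$r_index[[k]], pre, post, edge))
      list(a = a, b = b)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1]] <- tibble::tibble(
        r_index = ann$r_index[[k]], reason = conditionMessage(res))
      next
    }
    rows[[k]] <- new_beats(record$record_id, ann$r_index[[k]], ann$label[[k]],
                           rr[[k]], list(res$a), list(res$b))
  }
  beats <- dplyr::bind_rows(rows)
  skipped <- if (length(skipped)) dplyr::bind_rows(skipped) else
    tibble::tibble(r_index = integer(0), reason = character(0))
  if (nrow(skipped) > 0) {
    warnf("record %s: skipped %d beat(s): %s", record$record_id, nrow(skipped),
          paste(utils::head(unique(skipped$reason), 3), collapse = "; "))
  }
  attr(beats, "skipped") <- skipped
  beats
}

#' Write / read beats in the documented CSV layout
#'
#' Wide plain-text layout, one row per beat:
#' `record_id, r_index, label, rr_s, a001..a<n>, b001..b<n>`.
#'
#' @param beats A beats tibble.
#' @param path Output CSV path.
#' @return `write_beats_csv()` the path invisibly; `read_beats_csv()` a
#'   beats tibble.
#' @export
write_beats_csv <- function(beats, path) {
  n <- length(beats$lead_a[[1]])
  a <- do.call(rbind, beats$lead_a)
  b <- do.call(rbind, beats$lead_b)
  colnames(a) <- sprintf("a%03d", seq_len(n))
  colnames(b) <- sprintf("b%03d", seq_len(n))
  flat <- cbind(
    data.frame(record_id = beats$record_id, r_index = beats$r_index,
               label = as.character(beats$label), rr_s = beats$rr_s),
    as.data.frame(a), as.data.frame(b)
  )
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beats_csv
#' @export
read_beats_csv <- function(path) {
  flat <- utils::read.csv(path, check.names = FALSE)
  a_cols <- grep("^a[0-9]+$", names(flat))
  b_cols <- grep("^b[0-9]+$", names(flat))
  new_beats(
    flat$record_id, flat$r_index, flat$label, flat$rr_s,
    lapply(seq_len(nrow(flat)), function(i) as.numeric(flat[i, a_cols])),
    lapply(seq_len(nrow(flat)), function(i) as.numeric(flat[i, b_cols]))
  )
}
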