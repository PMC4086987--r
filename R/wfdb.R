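# Minimal WFDB (MIT dialect) reader/writer: .hea text headers, .dat signal
# files in formats 212 and 16, and .atr annotation files in the MIT
# annotation byte format. Covers what two-lead Holter records need; it is
# not a general WFDB implementation (no multi-segment records, no EDF).

# Standard annotation code -> symbol table (beat and non-beat codes).
.wfdb_ann_codes <- c(
  "1" = "N", "2" = "L", "3" = "R", "4" = "a", "5" = "V", "6" = "F",
  "7" = "J", "8" = "A", "9" = "S", "10" = "E", "11" = "j", "12" = "/",
  "13" = "Q", "14" = "~", "16" = "|", "18" = "s", "19" = "T", "20" = "*",
  "21" = "D", "22" = "\"", "23" = "=", "24" = "p", "25" = "B", "26" = "^",
  "27" = "t", "28" = "+", "29" = "u", "30" = "?", "31" = "!", "32" = "[",
  "33" = "]", "34" = "e", "35" = "n", "36" = "@", "37" = "x", "38" = "f",
  "39" = "(", "40" = ")", "41" = "r"
)

wfdb_symbol_to_code <- function(symbol) {
  code <- names(.wfdb_ann_codes)[match(symbol, .wfdb_ann_codes)]
  if (anyNA(code)) {
    stopf("unknown annotation symbol(s): %s",
          paste(unique(symbol[is.na(code)]), collapse = ", "))
  }
  as.integer(code)
}

#' Read a WFDB header file
#'
#' Parses the `.hea` text header of a MIT-dialect record: record line
#' (name, number of signals, sampling frequency, number of samples) and one
#' specification line per signal (file, format, gain, baseline, units,
#' description).
#'
#' @param path Path to the `.hea` file.
#' @return A list with `record_id`, `n_sig`, `fs`, `n_samp` and a tibble
#'   `signals` (file, format, gain, baseline, description).
#' @export
read_wfdb_header <- function(path) {
  if (!file.exists(path)) stopf("header not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  n_sig <- as.integer(rec[[2]])
  fs <- if (length(rec) >= 3) as.numeric(sub("/.*$", "", rec[[3]])) else 250
  n_samp <- if (length(rec) >= 4) as.integer(rec[[4]]) else NA_integer_
  if (length(lines) < 1 + n_sig) stopf("header %s declares %d signals but lists fewer", path, n_sig)

  sig <- purrr::map_dfr(lines[1 + seq_len(n_sig)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    gain_spec <- if (length(f) >= 3) f[[3]] else "200"
    gain <- suppressWarnings(as.numeric(sub("[(/].*$", "", gain_spec)))
    if (is.na(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gain_spec)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_spec))
    } else if (length(f) >= 5) {
      suppressWarnings(as.numeric(f[[5]]))  # adc zero
    } else 0
    if (is.na(baseline)) baseline <- 0
    tibble::tibble(
      file = f[[1]],
      format = sub("x.*$", "", f[[2]]),
      gain = gain,
      baseline = baseline,
      description = if (length(f) >= 9) paste(f[-(1:8)], collapse = " ") else NA_character_
    )
  })
  list(record_id = rec[[1]], n_sig = n_sig, fs = fs, n_samp = n_samp, signals = sig)
}

# Unpack format 212: 3 bytes hold two 12-bit two's-complement samples.
.decode_212 <- function(raw, n_samples) {
  n3 <- (length(raw) %/% 3L) * 3L
  b <- as.integer(raw[seq_len(n3)])
  b1 <- b[seq(1, n3, by = 3)]
  b2 <- b[seq(2, n3, by = 3)]
  b3 <- b[seq(3, n3, by = 3)]
  s1 <- b1 + bitwShiftL(bitwAnd(b2, 0x0FL), 8)
  s2 <- b3 + bitwShiftL(bitwShiftR(b2, 4), 8)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  out <- as.vector(rbind(s1, s2))
  out[seq_len(min(n_samples, length(out)))]
}

#' Read a two-lead WFDB record
#'
#' Reads the header, signal file (formats 212 or 16) and, when present, the
#' annotation file of a MIT-dialect WFDB record. Signals are converted to
#' physical units via `(adc - baseline) / gain`. Annotation sample indices
#' are 0-based.
#'
#' @param path Record path without extension (e.g. `"data/mitdb/100"`).
#' @param annotator Annotation file extension (default `"atr"`); `NULL`
#'   skips annotations.
#' @return A list with `record_id`, `fs`, `signals` (numeric matrix, one
#'   column per lead) and `annotations`
#'   (tibble: `r_index`, `symbol`).
#' @export
read_wfdb_record <- function(path, annotator = "atr") {
  hdr <- read_wfdb_header(paste0(path, ".hea"))
  dat_path <- file.path(dirname(path), hdr$signals$file[[1]])
  if (!file.exists(dat_path)) stopf("signal file not found: %s", dat_path)
  raw <- readBin(dat_path, "raw", n = file.size(dat_path))
  fmt <- hdr$signals$format[[1]]
  n_sig <- hdr$n_sig
  total <- if (!is.na(hdr$n_samp)) hdr$n_samp * n_sig else NA_integer_

  adc <- switch(fmt,
    "212" = .decode_212(raw, if (is.na(total)) length(raw) * 2L else total),
    "16" = {
      v <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                   signed = TRUE, endian = "little")
      if (!is.na(total)) v[seq_len(min(total, length(v)))] else v
    },
    stopf("unsupported WFDB signal format: %s", fmt)
  )
  n_samp <- length(adc) %/% n_sig
  m <- matrix(adc[seq_len(n_samp * n_sig)], ncol = n_sig, byrow = TRUE)
  phys <- sweep(sweep(m, 2, hdr$signals$baseline), 2, hdr$signals$gain, "/")
  colnames(phys) <- hdr$signals$description

  ann <- NULL
  if (!is.null(annotator)) {
    atr_path <- paste0(path, ".", annotator)
    if (file.exists(atr_path)) ann <- read_wfdb_annotations(atr_path)
  }
  list(record_id = hdr$record_id, fs = hdr$fs, signals = phys, annotations = ann)
}

#' Read a MIT-format annotation file
#'
#' Decodes the MIT annotation byte format: 16-bit little-endian words whose
#' high 6 bits are the annotation code and low 10 bits the sample interval
#' since the previous annotation. Handles the SKIP (long-interval), NUM,
#' SUB, CHN and AUX pseudo-annotations.
#'
#' @param path Path to the annotation file.
#' @return Tibble with 0-based `r_index` and annotation `symbol`, sorted by
#'   `r_index`.
#' @export
read_wfdb_annotations <- function(path) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  raw <- readBin(path, "raw", n = file.size(path))
  nw <- length(raw) %/% 2L
  lo <- as.integer(raw[seq(1, 2L * nw, by = 2)])
  hi <- as.integer(raw[seq(2, 2L * nw, by = 2)])
  words <- lo + bitwShiftL(hi, 8)

  t_now <- 0
  i <- 1L
  idx <- integer(0)
  sym <- character(0)
  while (i <= nw) {
    w <- words[[i]]
    code <- bitwShiftR(w, 10)
    delta <- bitwAnd(w, 1023L)
    if (w == 0L) break
    if (code == 59L) {            # SKIP: next two words hold a long interval
      if (i + 2L > nw) break
      t_now <- t_now + bitwShiftL(words[[i + 1L]], 16) + words[[i + 2L]]
      i <- i + 3L
      next
    } else if (code == 63L) {     # AUX: delta = byte count, padded to even
      i <- i + 1L + ceiling(delta / 2)
      next
    } else if (code %in% c(60L, 61L, 62L)) {  # NUM / SUB / CHN
      i <- i + 1L
      next
    }
    t_now <- t_now + delta
    s <- .wfdb_ann_codes[as.character(code)]
    idx <- c(idx, t_now)
    sym <- c(sym, if (is.na(s)) "?" else unname(s))
    i <- i + 1L
  }
  out <- tibble::tibble(r_index = as.integer(idx), symbol = sym)
  dplyr::arrange(out, .data$r_index)
}

#' Write a two-lead WFDB record
#'
#' Writes a MIT-dialect record (header, format-16 signal file and MIT-format
#' annotation file). Used to build fixtures and to export synthetic
#' datasets so the file-level pipeline can be exercised without any
#' database download.
#'
#' @param dir Output directory (created if needed).
#' @param record_id Record name (file stem).
#' @param signals Numeric matrix, one column per lead, physical units.
#' @param fs Sampling frequency in Hz.
#' @param annotations Tibble with 0-based `r_index` and `symbol`, or `NULL`.
#' @param gain ADC gain (units per physical unit) used for quantisation.
#' @param lead_names Character vector of signal descriptions.
#' @return The record path (without extension), invisibly.
#' @export
write_wfdb_record <- function(dir, record_id, signals, fs, annotations = NULL,
                              gain = 200, lead_names = NULL) {
  stopifnot(is.matrix(signals), fs > 0)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_sig <- ncol(signals)
  n_samp <- nrow(signals)
  if (is.null(lead_names)) lead_names <- paste0("lead", seq_len(n_sig))

  adc <- round(signals * gain)
  adc[adc > 32767] <- 32767
  adc[adc < -32768] <- -32768

  hea <- c(
    sprintf("%s %d %g %d", record_id, n_sig, fs, n_samp),
    sprintf("%s.dat 16 %g(0)/mV 16 0 %d 0 0 %s",
            record_id, gain, as.integer(adc[1, ]), lead_names)
  )
  writeLines(hea, file.path(dir, paste0(record_id, ".hea")))

  interleaved <- as.integer(t(adc))
  writeBin(interleaved, file.path(dir, paste0(record_id, ".dat")),
           size = 2L, endian = "little")

  if (!is.null(annotations) && nrow(annotations) > 0) {
    ann <- dplyr::arrange(annotations, .data$r_index)
    codes <- wfdb_symbol_to_code(ann$symbol)
    words <- integer(0)
    t_prev <- 0L
    for (k in seq_len(nrow(ann))) {
      delta <- as.integer(ann$r_index[[k]]) - t_prev
      if (delta > 1023L) {
        words <- c(words, bitwShiftL(59L, 10),
                   bitwShiftR(delta, 16), bitwAnd(delta, 65535L))
        delta <- 0L
      }
      words <- c(words, bitwShiftL(codes[[k]], 10) + delta)
      t_prev <- as.integer(ann$r_index[[k]])
    }
    words <- c(words, 0L)  # terminator
    bytes <- as.raw(as.vector(rbind(bitwAnd(words, 255L), bitwShiftR(words, 8))))
    writeBin(bytes, file.path(dir, paste0(record_id, ".atr")))
  }
  invisible(file.path(dir, record_id))
}
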