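# Synthetic two-lead beat generator: Gaussian-bump class templates with
# per-"virtual patient" perturbations, per-beat amplitude jitter and
# additive Gaussian noise, class-dependent RR distributions and strong
# NORM-dominant imbalance. Templates are controllable class geometry, not
# physiological ECG models.

#' Default class/lead beat templates
#'
#' Parameterised Gaussian bumps (center sample, width, amplitude) over a
#' 200-sample window with the R wave at sample 100. NORM carries a narrow
#' central QRS with upright T; LBBB a widened, notched complex with
#' discordant T; RBBB a late secondary deflection (rSR'-like). The two
#' leads use distinct bump sets, and all normalized template pairs are
#' separated by an L2 distance greater than 1.
#'
#' @return Nested list `templates[[class]][[lead]]`, each a data frame
#'   with columns `center`, `width`, `amp`.
#' @export
default_templates <- function() {
  tpl <- function(...) {
    m <- rbind(...)
    data.frame(center = m[, 1], width = m[, 2], amp = m[, 3])
  }
  list(
    NORM = list(
      A = tpl(c(55, 6, 0.15), c(94, 2, -0.20), c(100, 3, 1.00),
              c(106, 2, -0.25), c(150, 12, 0.30)),
      B = tpl(c(55, 6, 0.10), c(100, 4, -0.90), c(108, 3, 0.20),
              c(152, 12, 0.25))
    ),
    LBBB = list(
      A = tpl(c(55, 6, 0.12), c(95, 8, 0.85), c(109, 8, 0.80),
              c(158, 14, -0.35)),
      B = tpl(c(55, 6, 0.10), c(96, 9, -0.80), c(110, 8, -0.65),
              c(158, 14, 0.35))
    ),
    RBBB = list(
      A = tpl(c(55, 6, 0.15), c(96, 3, 0.55), c(103, 3, -0.45),
              c(112, 6, 0.95), c(155, 12, -0.25)),
      B = tpl(c(55, 6, 0.10), c(97, 4, 0.75), c(110, 6, -0.85),
              c(155, 12, 0.20))
    )
  )
}

render_template <- function(bumps, n_samples = 200) {
  t <- seq_len(n_samples) - 1
  out <- numeric(n_samples)
  for (k in seq_len(nrow(bumps))) {
    out <- out + bumps$amp[[k]] *
      exp(-(t - bumps$center[[k]])^2 / (2 * bumps$width[[k]]^2))
  }
  out
}

#' Generator configuration
#'
#' Bundles and validates the knobs of the synthetic beat generator. The
#' defaults define the study conditions used throughout the test suite:
#' 10:1:1 NORM-dominant imbalance, class-dependent RR distributions,
#' moderate additive noise, and per-subject template perturbations that
#' emulate inter-individual variation.
#'
#' @param n_per_class Named beats per class per split
#'   (default `NORM = 1000, LBBB = 100, RBBB = 100`).
#' @param n_subjects Named virtual patients per class per split
#'   (default `10, 2, 3`, echoing the record structure of the study data).
#' @param rr_mean_s,rr_sd_s Named per-class RR mean / sd in seconds.
#' @param noise_sd Additive Gaussian noise sd (template units).
#' @param amplitude_jitter_sd Per-beat multiplicative amplitude jitter sd.
#' @param subject_amp_sd,subject_shift_sd Per-subject bump amplitude jitter
#'   sd and bump center shift sd (samples).
#' @param templates Bump parameter sets, see [default_templates()].
#' @param fs Sampling frequency (Hz).
#' @param seed Integer seed governing the whole dataset draw.
#' @return A validated list of class `bbb_generator_config`.
#' @export
make_generator_config <- function(
    n_per_class = c(NORM = 1000, LBBB = 100, RBBB = 100),
    n_subjects = c(NORM = 10, LBBB = 2, RBBB = 3),
    rr_mean_s = c(NORM = 0.80, LBBB = 0.92, RBBB = 0.70),
    rr_sd_s = c(NORM = 0.05, LBBB = 0.06, RBBB = 0.05),
    noise_sd = 0.10,
    amplitude_jitter_sd = 0.10,
    subject_amp_sd = 0.12,
    subject_shift_sd = 1.5,
    templates = default_templates(),
    fs = 360,
    seed = 1) {
  cls <- beat_labels()
  for (nm in list(n_per_class, n_subjects, rr_mean_s, rr_sd_s)) {
    if (!all(cls %in% names(nm))) stopf("per-class settings must name NORM, LBBB, RBBB")
  }
  if (any(rr_mean_s[cls] <= 3 * rr_sd_s[cls])) {
    stopf("rr_mean_s must exceed 3 * rr_sd_s to keep RR positive")
  }
  if (noise_sd < 0 || amplitude_jitter_sd < 0) stopf("noise parameters must be non-negative")
  for (c1 in cls) for (l in c("A", "B")) {
    if (any(templates[[c1]][[l]]$width <= 0)) stopf("template widths must be positive")
  }
  structure(list(
    n_per_class = n_per_class[cls], n_subjects = n_subjects[cls],
    rr_mean_s = rr_mean_s[cls], rr_sd_s = rr_sd_s[cls],
    noise_sd = noise_sd, amplitude_jitter_sd = amplitude_jitter_sd,
    subject_amp_sd = subject_amp_sd, subject_shift_sd = subject_shift_sd,
    templates = templates, fs = fs, seed = seed
  ), class = "bbb_generator_config")
}

# Perturb a bump set for one virtual patient (uses the current RNG stream).
perturb_templates <- function(config, class) {
  lapply(config$templates[[class]], function(bumps) {
    bumps$amp <- bumps$amp * (1 + stats::rnorm(nrow(bumps), 0, config$subject_amp_sd))
    bumps$center <- bumps$center + stats::rnorm(nrow(bumps), 0, config$subject_shift_sd)
    bumps
  })
}

draw_rr <- function(config, class, n) {
  rr <- stats::rnorm(n, config$rr_mean_s[[class]], config$rr_sd_s[[class]])
  pmax(rr, 0.2)
}

#' Draw one synthetic beat
#'
#' Renders the (possibly subject-perturbed) class template on both leads,
#' applies per-beat amplitude jitter and additive Gaussian noise, then
#' z-normalizes each lead. With `noise_sd = 0` and
#' `amplitude_jitter_sd = 0` the beat equals the normalized template
#' exactly. Uses the current RNG stream; seed externally for determinism.
#'
#' @param class `"NORM"`, `"LBBB"` or `"RBBB"`.
#' @param config A `bbb_generator_config`.
#' @param subject_templates Optional per-subject perturbed bump sets from
#'   [perturb_templates]; defaults to the unperturbed class templates.
#' @param record_id,r_index Provenance fields for the beat row.
#' @return A one-row beats tibble.
#' @export
sample_beat <- function(class, config, subject_templates = NULL,
                        record_id = "synthetic", r_index = 0L) {
  tpls <- if (is.null(subject_templates)) config$templates[[class]] else subject_templates
  jit <- 1 + stats::rnorm(1, 0, config$amplitude_jitter_sd)
  leads <- lapply(tpls[c("A", "B")], function(bumps) {
    wave <- jit * render_template(bumps) + stats::rnorm(200, 0, config$noise_sd)
    znormalize(wave)
  })
  rr <- draw_rr(config, class, 1)
  new_beats(record_id, r_index, class, rr, list(leads$A), list(leads$B))
}

#' Generate an inter-patient-style synthetic dataset
#'
#' Draws labelled two-lead beats for a training and a testing split. Each
#' split gets its own disjoint set of virtual patients — a patient is a
#' fixed random perturbation of the class template shared by all of that
#' patient's beats — so the split is inter-patient-like: test morphology
#' differs systematically, not just by noise, from training morphology.
#' The whole draw is reproducible from `config$seed`.
#'
#' @param config A `bbb_generator_config`.
#' @return A list with beats tibbles `train` and `test`. Record ids encode
#'   split, class and subject (e.g. `"tr_LBBB_01"`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "bbb_generator_config"))
  with_private_seed(config$seed, function() {
    gen_split <- function(prefix) {
      rows <- list()
      for (class in beat_labels()) {
        n_sub <- config$n_subjects[[class]]
        n_tot <- config$n_per_class[[class]]
        base <- n_tot %/% n_sub
        n_each <- rep(base, n_sub) + c(rep(1, n_tot - base * n_sub),
                                       rep(0, n_sub - (n_tot - base * n_sub)))
        for (s in seq_len(n_sub)) {
          rec <- sprintf("%s_%s_%02d", prefix, class, s)
          tpls <- perturb_templates(config, class)
          rr <- draw_rr(config, class, n_each[[s]])
          r_idx <- cumsum(round(rr * config$fs)) + 100L
          for (b in seq_len(n_each[[s]])) {
            rows[[length(rows) + 1]] <-
              sample_beat(class, config, tpls, record_id = rec,
                          r_index = as.integer(r_idx[[b]]))
            # overwrite the independently drawn RR with the stream used
            # for R-peak placement so rr and r_index agree
            rows[[length(rows)]]$rr_s <- rr[[b]]
          }
        }
      }
      dplyr::bind_rows(rows)
    }
    list(train = gen_split("tr"), test = gen_split("te"))
  })
}

#' Write a synthetic dataset as WFDB records
#'
#' Renders each virtual patient as a continuous two-lead WFDB record
#' (format 16) with MIT-format beat annotations, so the file-level
#' pipeline — record loading, label mapping, segmentation — can be
#' exercised end to end without any database download. Beat waveforms are
#' placed at RR-spaced R positions on a flat baseline; a fraction of
#' non-studied (`V`-symbol) annotations can be injected to exercise the
#' OTHER-label path.
#'
#' @param config A `bbb_generator_config`.
#' @param dir Output directory.
#' @param beats_per_record Beats per virtual patient record.
#' @param records_per_class Named records per class.
#' @param other_every Inject one `V`-annotated extra beat after every this
#'   many studied beats (`0` disables).
#' @param prefix Record id prefix.
#' @return Tibble manifest: `record_id`, `class`, `n_beats`, `path`.
#' @export
write_synthetic_wfdb <- function(config, dir, beats_per_record = 30,
                                 records_per_class = c(NORM = 2, LBBB = 1, RBBB = 1),
                                 other_every = 0, prefix = "syn") {
  stopifnot(inherits(config, "bbb_generator_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  symbols <- c(NORM = "N", LBBB = "L", RBBB = "R")
  manifest <- list()
  with_private_seed(config$seed + 7, function() {
    for (class in beat_labels()) {
      for (rno in seq_len(records_per_class[[class]])) {
        rec_id <- sprintf("%s%s%02d", prefix, substr(class, 1, 1), rno)
        tpls <- perturb_templates(config, class)
        n <- beats_per_record
        rr <- draw_rr(config, class, n + 1)
        r_idx <- cumsum(round(rr * config$fs)) + 150L
        total_len <- r_idx[[n]] + 400L
        sig <- matrix(stats::rnorm(total_len * 2, 0, config$noise_sd), ncol = 2)
        ann_idx <- integer(0); ann_sym <- character(0)
        for (b in seq_len(n)) {
          jit <- 1 + stats::rnorm(1, 0, config$amplitude_jitter_sd)
          span <- (r_idx[[b]] - 100L):(r_idx[[b]] + 99L) + 1L
          sig[span, 1] <- sig[span, 1] + jit * render_template(tpls$A)
          sig[span, 2] <- sig[span, 2] + jit * render_template(tpls$B)
          ann_idx <- c(ann_idx, r_idx[[b]])
          ann_sym <- c(ann_sym, symbols[[class]])
          if (other_every > 0 && b %% other_every == 0) {
            mid <- r_idx[[b]] + as.integer(round(rr[[b + 1]] * config$fs / 2))
            spikespan <- (mid - 5L):(mid + 5L) + 1L
            sig[spikespan, ] <- sig[spikespan, ] + 1.5
            ann_idx <- c(ann_idx, mid)
            ann_sym <- c(ann_sym, "V")
          }
        }
        write_wfdb_record(dir, rec_id, sig, fs = config$fs,
                          annotations = tibble::tibble(r_index = ann_idx,
                                                       symbol = ann_sym),
                          lead_names = c("leadA", "leadB"))
        manifest[[length(manifest) + 1]] <<- tibble::tibble(
          record_id = rec_id, class = class, n_beats = n,
          path = file.path(dir, rec_id))
      }
    }
  })
  dplyr::bind_rows(manifest)
}
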