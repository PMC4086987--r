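# Fixtures are built in code at test time; nothing is stored on disk.

# A beats tibble assembled by hand (bypasses the generator).
mk_beats <- function(labels, waves_a, waves_b, rr = NULL, record_id = NULL,
                     r_index = NULL) {
  n <- length(labels)
  tibble::tibble(
    record_id = if (is.null(record_id)) rep("rec1", n) else record_id,
    r_index = if (is.null(r_index)) seq_len(n) * 300L else as.integer(r_index),
    label = factor(labels, levels = c("NORM", "LBBB", "RBBB")),
    rr_s = if (is.null(rr)) rep(0.8, n) else rr,
    lead_a = waves_a,
    lead_b = waves_b
  )
}

# Small separable synthetic split for pipeline tests.
small_dataset <- function(seed = 1, n = c(NORM = 150, LBBB = 40, RBBB = 40),
                          noise_sd = 0.1) {
  cfg <- make_generator_config(n_per_class = n, noise_sd = noise_sd, seed = seed)
  generate_dataset(cfg)
}

# A fake loaded record (as from load_record) with a ramp on lead A.
fake_record <- function(n_samples = 4000, fs = 360,
                        ann = tibble::tibble(
                          r_index = c(400L, 760L, 1120L, 1480L, 1840L, 2200L, 2560L),
                          symbol = c("N", "N", "V", "L", "R", "+", "N"))) {
  ann$label <- map_beat_label(ann$symbol)
  set.seed(42)
  list(record_id = "fake01", fs = fs,
       lead_a = sin(seq_len(n_samples) / 7) + rnorm(n_samples, 0, 0.05),
       lead_b = cos(seq_len(n_samples) / 9) + rnorm(n_samples, 0, 0.05),
       annotations = ann)
}

# Overlapping 2-D NORM/RBBB cloud whose discriminant boundary moves with
# the scatter weights; used for the weight-selection tie-break check.
overlap_norm_rbbb <- function(seed = 7, n_n = 120, n_r = 30) {
  set.seed(seed)
  Xn <- cbind(rnorm(n_n, 0, 2.0), rnorm(n_n, 0, 0.5))
  Xr <- cbind(rnorm(n_r, 2.5, 0.8), rnorm(n_r, 1.2, 0.8))
  list(X = rbind(Xn, Xr),
       y = factor(rep(c("NORM", "RBBB"), c(n_n, n_r)), levels = c("NORM", "RBBB")))
}

expect_no_na <- function(x) testthat::expect_false(anyNA(x))
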