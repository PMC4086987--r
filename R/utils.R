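# Internal helpers shared across modules.

# The three studied beat classes, in canonical reporting order.
beat_labels <- function() c("NORM", "LBBB", "RBBB")

as_beat_factor <- function(x) {
  factor(as.character(x), levels = beat_labels())
}

#' Round half away from zero
#'
#' Report-style rounding: halves round up (`81.25 -> 81.3`), unlike base
#' [round()]'s round-half-even. Used for all percent tables so printed
#' metrics match clinical-report conventions.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Population (divide-by-N) standard deviation.
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
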