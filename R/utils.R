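# Small shared helpers: spectral windows, dB conversion, validation.

#' Spectral analysis windows
#'
#' Generates the taper windows used by the periodogram estimators. The Tukey
#' (cosine-tapered) and Bartlett-Hann windows are computed from their standard
#' closed-form definitions; `hann` is the usual raised cosine.
#'
#' @param n Window length in samples.
#' @param type One of `"tukey"`, `"barthann"`, `"hann"`, `"rect"`.
#' @param alpha Taper fraction for the Tukey window (default 0.25: 1/8 of the
#'   window tapered at each end).
#' @return Numeric vector of length `n`.
#' @export
spectral_window <- function(n, type = c("tukey", "barthann", "hann", "rect"),
                            alpha = 0.25) {
  type <- match.arg(type)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  n <- as.integer(n)
  if (n == 1L) return(1)
  k <- seq_len(n) - 1L
  x <- k / (n - 1L)
  switch(type,
    rect = rep(1, n),
    hann = 0.5 - 0.5 * cos(2 * pi * x),
    barthann = 0.62 - 0.48 * abs(x - 0.5) + 0.38 * cos(2 * pi * (x - 0.5)),
    tukey = {
      if (alpha <= 0) return(rep(1, n))
      if (alpha >= 1) return(0.5 - 0.5 * cos(2 * pi * x))
      w <- rep(1, n)
      taper <- x < alpha / 2
      w[taper] <- 0.5 * (1 + cos(pi * (2 * x[taper] / alpha - 1)))
      taper <- x > 1 - alpha / 2
      w[taper] <- 0.5 * (1 + cos(pi * (2 * x[taper] / alpha - 2 / alpha + 1)))
      w
    })
}

#' Convert linear power to decibels
#'
#' @param p Linear power value(s); non-positive values map to `-Inf`.
#' @return `10 * log10(p)`.
#' @export
power_db <- function(p) {
  out <- rep(-Inf, length(p))
  ok <- is.finite(p) & p > 0
  out[ok] <- 10 * log10(p[ok])
  out[!is.finite(p)] <- NA_real_
  out
}

#' Convert decibels to linear power
#' @param db Value(s) in dB.
#' @return `10^(db/10)`.
#' @export
db_power <- function(db) 10^(db / 10)

# internal: stop with a classed condition so callers/tests can distinguish
# malformed input files from invalid parameter values
stop_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("eggwave_format_error", "error")))
}

stop_invalid <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("eggwave_validation_error", "error")))
}

# internal: first value or default
`%||%` <- function(a, b) if (is.null(a)) b else a
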