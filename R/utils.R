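#' Round half away from zero
#'
#' Rounds to `ndigits` decimals with halves carried away from zero
#' (so 36.5 -> 37 and -56.5 -> -57), unlike [base::round()] which rounds
#' halves to even. Percent changes in treatment tables are reported with
#' this convention.
#'
#' @param x Numeric vector.
#' @param ndigits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, ndigits = 0) {
  m <- 10^ndigits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("soyco2_domain_error", "error")))
}

stop_fit <- function(msg, diagnostics = NULL) {
  stop(errorCondition(msg, diagnostics = diagnostics,
                      class = c("soyco2_fit_error", "error")))
}

# Derive a reproducible 32-bit substream seed from a base seed and a stage tag.
# Stage tags keep the Monte Carlo envelope, the study generator and noise
# streams independent while everything still flows from one user seed.
substream_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}
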