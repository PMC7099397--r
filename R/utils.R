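#' Round half away from zero
#'
#' Base R's \code{round()} rounds half to even; published clinical tables are
#' conventionally formatted half-up. Used everywhere a percentage is printed
#' to 2 decimals.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # epsilon guards against values like 99.905 stored as 99.90499999999...
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible child seed from a base seed and a stream index.
# Kept below 2^31 so it is always a valid R integer seed.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483587)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
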