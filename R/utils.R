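#' Round half away from zero
#'
#' Base [round()] rounds half to even; printed summaries in field reports
#' conventionally round half up. Used only at the reporting layer; all
#' internal arithmetic keeps full precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `x` rounded half away from zero to `digits` places.
#' @examples
#' round_half_up(0.9375, 2) # 0.94
#' round_half_up(26.5, 0)   # 27
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# internal: stop with a message assembled from sprintf parts
ct_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

ct_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# internal: check a scalar probability / proportion argument
check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    ct_stop("`%s` must be a single number in [0, 1]", name)
  }
  invisible(x)
}

# internal: log(1 - exp(x)) for x <= 0, stable near both ends
log1mexp <- function(x) {
  ifelse(x > -log(2), log(-expm1(x)), log1p(-exp(x)))
}
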