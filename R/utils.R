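# Internal numeric and logging helpers shared across modules.

#' Round half away from zero
#'
#' Index values and printed percentages use the half-up convention of the
#' EPA AQI calculator rather than R's round-half-even.
#' @param x numeric vector (non-negative in all internal uses)
#' @param digits decimal places to keep
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

#' Truncate a PM2.5 concentration to 0.1 µg/m³ precision
#'
#' Breakpoint band edges are defined on a 0.1 µg/m³ grid, so concentrations
#' are truncated (not rounded) before band lookup, following the EPA AQI
#' convention.
#'
#' @param pm25 numeric vector of concentrations in µg/m³; must be >= 0.
#' @return numeric vector truncated toward zero at 0.1 precision.
#' @examples
#' truncate_concentration(20.55) # 20.5
#' @export
truncate_concentration <- function(pm25) {
  if (any(is.na(pm25))) stop("pm25 must not contain missing values")
  if (any(pm25 < 0)) stop("pm25 must be non-negative")
  # add a small epsilon so values stored as e.g. 55.5 - 1e-15 do not drop a grid step
  floor(pm25 * 10 + 1e-9) / 10
}

# One-line structured log event to stderr; results never go to stderr.
log_event <- function(event, ...) {
  details <- c(...)
  msg <- if (length(details)) {
    paste0(event, ": ", paste(names(details), details, sep = "=", collapse = " "))
  } else {
    event
  }
  message("[smokepolicy] ", msg)
}

# state (2-digit) + county (3-digit) FIPS -> county key string
make_county_key <- function(state_fips, county_fips) {
  paste0(
    formatC(as.character(state_fips), width = 2, flag = "0"),
    formatC(as.character(county_fips), width = 3, flag = "0")
  )
}
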