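# Internal helpers shared across the package.

#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish validation failures from
# configuration mistakes programmatically.
pdbia_stop <- function(msg, class = "pdbia_validation_error", call. = FALSE) {
  stop(structure(
    class = c(class, "pdbia_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && abs(x - round(x)) < 1e-9
}

is_proportion <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

is_nonneg_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0
}

#' Round half away from zero
#'
#' Display rounding used for all printed patient counts and euro totals.
#' `round()` in R rounds half to even (banker's rounding), which does not
#' match printed tables where e.g. 47913.75 appears as 47914; half-away
#' rounding does.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places (default 0).
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_away(47913.75)  # 47914
#' round_half_away(-0.5)      # -1
#' @export
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Stage and scenario vocabularies used throughout.
STAGES <- c("mild", "moderate", "advanced")
SCENARIOS <- c("moderate_detected", "advanced_detected")
HY_STAGES <- c("I", "II", "III", "IV", "V")

match_scenario <- function(scenario) {
  if (!is.character(scenario) || length(scenario) != 1L || !scenario %in% SCENARIOS) {
    pdbia_stop(
      sprintf("scenario must be one of: %s", paste(SCENARIOS, collapse = ", ")),
      "pdbia_config_error"
    )
  }
  scenario
}

`%||%` <- function(a, b) if (is.null(a)) b else a
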