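# Detection cascade: per country and scenario, how many misclassified
# patients the device can actually reach.
#
#   stage pool --(underdiagnosis rate)--> underdiagnosed
#              --(detection sensitivity)--> detectable
#              --(market penetration)--> adopted
#
# Each step is a plain multiplication, so the cascade equals the closed
# form total * share * rate * sensitivity * penetration; unrounded counts
# are carried downstream and rounding is presentation-only.

#' Underdiagnosed patients in a stage pool
#'
#' @param stage_pool patients in the source stage pool (real-valued; >= 0).
#' @param rate underdiagnosis rate in \[0,1\].
#' @return `stage_pool * rate`, unrounded.
#' @export
underdiagnosed_count <- function(stage_pool, rate) {
  if (!is.numeric(stage_pool) || any(stage_pool < 0)) pdbia_stop("stage_pool must be >= 0")
  if (!all(vapply(rate, is_proportion, logical(1)))) pdbia_stop("rate must lie in [0,1]")
  stage_pool * rate
}

#' Patients detectable by the device
#'
#' @param n underdiagnosed patients (real-valued; >= 0).
#' @param sensitivity detection sensitivity in \[0,1\].
#' @return `n * sensitivity`, unrounded.
#' @export
detectable_count <- function(n, sensitivity) {
  if (!is.numeric(n) || any(n < 0)) pdbia_stop("n must be >= 0")
  if (!all(vapply(sensitivity, is_proportion, logical(1)))) {
    pdbia_stop("sensitivity must lie in [0,1]")
  }
  n * sensitivity
}

#' Patients reached at a given market penetration
#'
#' @param n detectable patients (real-valued; >= 0).
#' @param penetration market penetration in \[0,1\].
#' @return `n * penetration`, unrounded (e.g. 453.6 stays 453.6; display
#'   rounding happens only at presentation).
#' @export
adopted_count <- function(n, penetration) {
  if (!is.numeric(n) || any(n < 0)) pdbia_stop("n must be >= 0")
  if (!all(vapply(penetration, is_proportion, logical(1)))) {
    pdbia_stop("penetration must lie in [0,1]")
  }
  n * penetration
}

# Which stage pool and which underdiagnosis rate a scenario draws on.
scenario_stage <- function(scenario) {
  switch(match_scenario(scenario), moderate_detected = "mild", advanced_detected = "moderate")
}

scenario_rate <- function(cascade, scenario) {
  switch(match_scenario(scenario),
         moderate_detected = cascade$underdiagnosis_rate_mild,
         advanced_detected = cascade$underdiagnosis_rate_moderate)
}

#' Run the detection cascade over a portfolio
#'
#' For each country the stage pool is the selected national total times the
#' source-stage share (mild for `moderate_detected`, moderate for
#' `advanced_detected`), then the three multiplicative steps are applied.
#'
#' @param p a `portfolio`.
#' @param scenario `"moderate_detected"` or `"advanced_detected"`.
#' @return data.frame with one row per country: unrounded `stage_pool`,
#'   `underdiagnosed`, `detectable`, `adopted` plus `*_display`
#'   nearest-integer copies.
#' @examples
#' run_cascade(bundled_portfolio(), "moderate_detected")
#' @export
run_cascade <- function(p, scenario) {
  validate_portfolio(p)
  scenario <- match_scenario(scenario)
  stage <- scenario_stage(scenario)
  rate <- scenario_rate(p$cascade, scenario)
  rows <- lapply(p$countries, function(ct) {
    total <- country_total(ct, p$config)
    pool <- total * p$stage_distribution[[stage]]
    und <- underdiagnosed_count(pool, rate)
    det <- detectable_count(und, p$cascade$detection_sensitivity)
    ado <- adopted_count(det, p$cascade$market_penetration)
    data.frame(
      country = ct$costs$code, country_name = ct$costs$name, scenario = scenario,
      stage_pool = pool, underdiagnosed = und, detectable = det, adopted = ado,
      stage_pool_display = round_half_away(pool),
      underdiagnosed_display = round_half_away(und),
      detectable_display = round_half_away(det),
      adopted_display = round_half_away(ado),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cascade grid over all configured scenarios
#'
#' Stacks [run_cascade()] over the scenarios in the portfolio's config:
#' the device-reach table (unrounded and display columns side by side).
#'
#' @param p a `portfolio`.
#' @return data.frame with one row per country x scenario.
#' @export
cascade_table <- function(p) {
  validate_portfolio(p)
  out <- do.call(rbind, lapply(p$config$scenarios, function(s) run_cascade(p, s)))
  rownames(out) <- NULL
  out
}
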