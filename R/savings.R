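# Savings model: device-cost amortization and the two stage-reclassification
# savings equations.
#
# Per patient and year, moving a patient's effective care stage one level
# down saves the direct-cost gap (scaled by the effectiveness factor f),
# costs the medication gap (optimised therapy is dearer), and costs the
# amortised device:
#
#   saving_pp = f * (DC_high - DC_low) - (MC_high - MC_low) - device_cost
#
# with (low, high) = (mild, moderate) for the moderate_detected scenario and
# (moderate, advanced) for advanced_detected.  National totals multiply by
# the unrounded adopted count from the cascade.

#' Annual per-patient device cost
#'
#' A unit is shared: `unit_price / uses_per_device_year` is the cost of one
#' recording week, and each patient is prescribed
#' `prescriptions_per_patient_year` of them.  Under the default
#' `floor_integer` mode the result is floored to whole euros
#' (2500/30*2 = 166.67 -> 166).
#'
#' @param device a [device_params()].
#' @return euros per patient-year.
#' @examples
#' annual_device_cost(device_params())                          # 166
#' annual_device_cost(device_params(cost_rounding = "exact"))   # 166.666...
#' @export
annual_device_cost <- function(device = device_params()) {
  if (!inherits(device, "device_params")) device <- do.call(device_params, as.list(device))
  raw <- device$unit_price / device$uses_per_device_year *
    device$prescriptions_per_patient_year
  switch(device$cost_rounding, floor_integer = floor(raw), exact = raw)
}

stage_pair <- function(scenario) {
  switch(match_scenario(scenario),
         moderate_detected = c(low = "mild", high = "moderate"),
         advanced_detected = c(low = "moderate", high = "advanced"))
}

#' Per-patient saving components
#'
#' @param costs a [country_cost_table()].
#' @param scenario detection scenario.
#' @param effectiveness_factor fraction of reclassified patients whose
#'   direct costs actually drop, in (0,1\].
#' @param device_cost euros per patient-year.
#' @return named list: `direct_cost_gap`, `medication_cost_gap`,
#'   `device_cost`, `effectiveness_factor`.
#' @export
saving_components <- function(costs, scenario, effectiveness_factor, device_cost) {
  if (!inherits(costs, "country_cost_table")) {
    pdbia_stop("costs must be a country_cost_table", "pdbia_schema_error")
  }
  if (!is.numeric(effectiveness_factor) || effectiveness_factor <= 0 ||
      effectiveness_factor > 1) {
    pdbia_stop("effectiveness_factor must lie in (0, 1]")
  }
  pair <- stage_pair(scenario)
  lo <- costs$costs[[pair[["low"]]]]
  hi <- costs$costs[[pair[["high"]]]]
  list(
    direct_cost_gap = hi$direct_cost - lo$direct_cost,
    medication_cost_gap = hi$medication_cost - lo$medication_cost,
    device_cost = device_cost,
    effectiveness_factor = effectiveness_factor
  )
}

#' Per-patient annual saving
#'
#' May be negative (the device then costs more than it saves); the sign is
#' preserved for break-even analysis.
#'
#' @inheritParams saving_components
#' @return euros per patient-year.
#' @examples
#' p <- bundled_portfolio()
#' per_patient_saving(p$countries$SE$costs, "moderate_detected", 1.0, 166)  # 3278
#' @export
per_patient_saving <- function(costs, scenario, effectiveness_factor, device_cost) {
  cmp <- saving_components(costs, scenario, effectiveness_factor, device_cost)
  cmp$effectiveness_factor * cmp$direct_cost_gap - cmp$medication_cost_gap -
    cmp$device_cost
}

#' National annual saving
#'
#' @param per_patient euros per patient-year.
#' @param n_patients_unrounded adopted patient count from the cascade,
#'   unrounded.
#' @return euros per year, unrounded (use [round_half_away()] for display).
#' @export
total_savings <- function(per_patient, n_patients_unrounded) {
  if (any(n_patients_unrounded < 0)) pdbia_stop("n_patients must be >= 0")
  per_patient * n_patients_unrounded
}

#' Run the full savings model
#'
#' Chains the detection cascade and the savings equation for every country
#' and configured scenario, in portfolio country order then scenario order.
#'
#' @param p a `portfolio`.
#' @return data.frame with columns `country`, `country_name`, `scenario`,
#'   `n_patients_unrounded`, `n_patients_display`, `per_patient_saving`,
#'   `total_saving_unrounded`, `total_saving` (display-rounded to whole
#'   euros), and the component columns `direct_cost_gap`,
#'   `medication_cost_gap`, `device_cost`, `effectiveness_factor`.
#' @examples
#' savings_table(bundled_portfolio())
#' @export
savings_table <- function(p) {
  validate_portfolio(p)
  dev_cost <- annual_device_cost(p$device)
  f <- p$config$effectiveness_factor
  rows <- list()
  for (code in names(p$countries)) {
    ct <- p$countries[[code]]
    for (sc in p$config$scenarios) {
      casc <- run_cascade_country(p, ct, sc)
      cmp <- saving_components(ct$costs, sc, f, dev_cost)
      pp <- per_patient_saving(ct$costs, sc, f, dev_cost)
      tot <- total_savings(pp, casc$adopted)
      rows[[length(rows) + 1L]] <- data.frame(
        country = code, country_name = ct$costs$name, scenario = sc,
        n_patients_unrounded = casc$adopted,
        n_patients_display = round_half_away(casc$adopted),
        per_patient_saving = pp,
        total_saving_unrounded = tot,
        total_saving = round_half_away(tot),
        direct_cost_gap = cmp$direct_cost_gap,
        medication_cost_gap = cmp$medication_cost_gap,
        device_cost = cmp$device_cost,
        effectiveness_factor = cmp$effectiveness_factor,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Cascade for a single country entry; avoids recomputing the full grid.
run_cascade_country <- function(p, ct, scenario) {
  stage <- scenario_stage(scenario)
  rate <- scenario_rate(p$cascade, scenario)
  pool <- country_total(ct, p$config) * p$stage_distribution[[stage]]
  und <- underdiagnosed_count(pool, rate)
  det <- detectable_count(und, p$cascade$detection_sensitivity)
  list(stage_pool = pool, underdiagnosed = und, detectable = det,
       adopted = adopted_count(det, p$cascade$market_penetration))
}

# Single-number evaluation used by sweeps, tornado and Monte Carlo.
evaluate_total_saving <- function(p, country, scenario) {
  ct <- p$countries[[country]]
  if (is.null(ct)) {
    pdbia_stop(sprintf("unknown country: %s", country), "pdbia_config_error")
  }
  casc <- run_cascade_country(p, ct, scenario)
  pp <- per_patient_saving(ct$costs, scenario, p$config$effectiveness_factor,
                           annual_device_cost(p$device))
  total_savings(pp, casc$adopted)
}
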