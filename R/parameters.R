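# Domain types: constructors and validators.
#
# All types are plain base-R lists carrying an S3 class; every constructor
# validates its invariants eagerly so that a Portfolio that exists is a
# Portfolio that is safe to evaluate.

#' Per-stage cost pair
#'
#' Direct costs (hospitalisations, consultations, care — excluding drugs)
#' and medication costs, both in euros per patient-year.
#'
#' @param direct_cost euros per patient-year, excluding medication.
#' @param medication_cost euros per patient-year for pharmacological treatment.
#' @return an object of class `stage_costs`.
#' @export
stage_costs <- function(direct_cost, medication_cost) {
  if (!is_nonneg_number(direct_cost)) {
    pdbia_stop("direct_cost must be a single finite number >= 0")
  }
  if (!is_nonneg_number(medication_cost)) {
    pdbia_stop("medication_cost must be a single finite number >= 0")
  }
  structure(
    list(direct_cost = as.numeric(direct_cost),
         medication_cost = as.numeric(medication_cost)),
    class = "stage_costs"
  )
}

#' Country cost table
#'
#' Per-stage direct and medication costs plus diagnosed patient counts per
#' stage for one country.
#'
#' @param code short country identifier (e.g. `"DE"`).
#' @param name display name (e.g. `"Germany"`).
#' @param costs named list with elements `mild`, `moderate`, `advanced`,
#'   each a [stage_costs()] object.
#' @param stage_counts named numeric vector of diagnosed patients per stage
#'   (`mild`, `moderate`, `advanced`); non-negative integers.
#' @return an object of class `country_cost_table`.
#' @export
country_cost_table <- function(code, name, costs, stage_counts) {
  if (!is.character(code) || length(code) != 1L || !nzchar(code)) {
    pdbia_stop("country code must be a non-empty string")
  }
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    pdbia_stop("country name must be a non-empty string")
  }
  if (!is.list(costs) || !identical(sort(names(costs)), sort(STAGES))) {
    pdbia_stop(sprintf(
      "costs for %s must contain exactly the stages: %s",
      code, paste(STAGES, collapse = ", ")
    ), "pdbia_schema_error")
  }
  costs <- costs[STAGES]
  for (s in STAGES) {
    if (!inherits(costs[[s]], "stage_costs")) {
      costs[[s]] <- do.call(stage_costs, as.list(costs[[s]]))
    }
  }
  if (!is.numeric(stage_counts) || !identical(sort(names(stage_counts)), sort(STAGES))) {
    pdbia_stop(sprintf("stage_counts for %s must be named for all three stages", code),
               "pdbia_schema_error")
  }
  stage_counts <- stage_counts[STAGES]
  for (s in STAGES) {
    if (!is_count(stage_counts[[s]])) {
      pdbia_stop(sprintf("stage count %s/%s must be a non-negative integer", code, s))
    }
  }
  structure(
    list(code = code, name = name, costs = costs,
         stage_counts = as.numeric(stage_counts)),
    class = "country_cost_table"
  )
}

#' Country epidemiology
#'
#' Diagnosed-population totals for one country.  Two totals coexist because
#' published sources differ: the sum of a staged Hoehn & Yahr prevalence
#' table, and a narrative national total.  A portfolio-level flag selects
#' which one feeds the detection cascade.
#'
#' @param code country identifier matching the cost table.
#' @param hy_counts optional named numeric vector of H&Y stage I..V counts.
#' @param total_text narrative national total of diagnosed patients.
#' @return an object of class `country_epidemiology`.
#' @export
country_epidemiology <- function(code, hy_counts = NULL, total_text) {
  if (!is.character(code) || length(code) != 1L || !nzchar(code)) {
    pdbia_stop("country code must be a non-empty string")
  }
  if (!is_nonneg_number(total_text)) {
    pdbia_stop(sprintf("total_text for %s must be a non-negative number", code))
  }
  total_hy <- NA_real_
  if (!is.null(hy_counts)) {
    if (!is.numeric(hy_counts) || !identical(sort(names(hy_counts)), sort(HY_STAGES))) {
      pdbia_stop(sprintf("hy_counts for %s must be named I..V", code),
                 "pdbia_schema_error")
    }
    hy_counts <- hy_counts[HY_STAGES]
    if (any(!vapply(hy_counts, is_count, logical(1)))) {
      pdbia_stop(sprintf("hy_counts for %s must be non-negative integers", code))
    }
    hy_counts <- stats::setNames(as.numeric(hy_counts), HY_STAGES)
    total_hy <- sum(hy_counts)
  }
  structure(
    list(code = code, hy_counts = hy_counts,
         total_hy = total_hy, total_text = as.numeric(total_text)),
    class = "country_epidemiology"
  )
}

#' Three-stage population distribution
#'
#' Shares of diagnosed patients in the mild, moderate and advanced groups.
#' The published preset is (0.45, 0.35, 0.20).
#'
#' @param mild,moderate,advanced proportions in \[0,1\] summing to 1.
#' @return an object of class `stage_distribution` (a named numeric vector).
#' @export
stage_distribution <- function(mild = 0.45, moderate = 0.35, advanced = 0.20) {
  vals <- c(mild = mild, moderate = moderate, advanced = advanced)
  if (!all(vapply(vals, is_proportion, logical(1)))) {
    pdbia_stop("stage shares must each lie in [0,1]")
  }
  if (abs(sum(vals) - 1) > 1e-9) {
    pdbia_stop(sprintf("stage shares must sum to 1 (got %.12f)", sum(vals)))
  }
  structure(vals, class = "stage_distribution")
}

#' Detection-cascade parameters
#'
#' Underdiagnosis rates per stage pool, device detection sensitivity, and
#' national market penetration.  Defaults are the published constants:
#' 18% of mild patients have unrecognised motor fluctuations, 36% of
#' moderate patients are unrecognised advanced disease, sensitivity 0.9,
#' penetration 0.2.
#'
#' @param underdiagnosis_rate_mild,underdiagnosis_rate_moderate proportions.
#' @param detection_sensitivity proportion.
#' @param market_penetration proportion.
#' @return an object of class `cascade_params`.
#' @export
cascade_params <- function(underdiagnosis_rate_mild = 0.18,
                           underdiagnosis_rate_moderate = 0.36,
                           detection_sensitivity = 0.9,
                           market_penetration = 0.2) {
  vals <- list(
    underdiagnosis_rate_mild = underdiagnosis_rate_mild,
    underdiagnosis_rate_moderate = underdiagnosis_rate_moderate,
    detection_sensitivity = detection_sensitivity,
    market_penetration = market_penetration
  )
  for (nm in names(vals)) {
    if (!is_proportion(vals[[nm]])) {
      pdbia_stop(sprintf("%s must lie in [0,1]", nm))
    }
  }
  structure(vals, class = "cascade_params")
}

#' Device economics
#'
#' A device unit is reused across patients: with a unit price of 2500 EUR,
#' 30 one-week recordings per device-year and two prescriptions per
#' patient-year, the amortised cost is 2500/30*2 = 166.67 EUR, floored to
#' 166 EUR/patient-year under the default rounding mode.
#'
#' @param unit_price euros per device.
#' @param uses_per_device_year recordings per device per year (> 0).
#' @param prescriptions_per_patient_year recordings prescribed per patient
#'   per year (> 0).
#' @param cost_rounding `"floor_integer"` (default) or `"exact"`.
#' @return an object of class `device_params`.
#' @export
device_params <- function(unit_price = 2500,
                          uses_per_device_year = 30,
                          prescriptions_per_patient_year = 2,
                          cost_rounding = c("floor_integer", "exact")) {
  if (!is_nonneg_number(unit_price)) pdbia_stop("unit_price must be >= 0")
  if (!is.numeric(uses_per_device_year) || length(uses_per_device_year) != 1L ||
      !is.finite(uses_per_device_year) || uses_per_device_year <= 0) {
    pdbia_stop("uses_per_device_year must be > 0")
  }
  if (!is.numeric(prescriptions_per_patient_year) ||
      length(prescriptions_per_patient_year) != 1L ||
      !is.finite(prescriptions_per_patient_year) ||
      prescriptions_per_patient_year <= 0) {
    pdbia_stop("prescriptions_per_patient_year must be > 0")
  }
  if (!is.character(cost_rounding)) {
    pdbia_stop("unknown cost_rounding mode", "pdbia_config_error")
  }
  cost_rounding <- tryCatch(match.arg(cost_rounding),
                            error = function(e) pdbia_stop(
                              "unknown cost_rounding mode", "pdbia_config_error"))
  structure(
    list(unit_price = as.numeric(unit_price),
         uses_per_device_year = as.numeric(uses_per_device_year),
         prescriptions_per_patient_year = as.numeric(prescriptions_per_patient_year),
         cost_rounding = cost_rounding),
    class = "device_params"
  )
}

#' Model configuration
#'
#' The effectiveness factor multiplies the direct-cost gap in the savings
#' equations: the fraction of correctly-identified patients whose care costs
#' actually shift to the lower stage.  Two presets exist because the
#' published equations state 0.8 while the published totals are only
#' consistent with 1.0; `"published"` (1.0) is the default so the flagship
#' savings table reproduces.  See the methods vignette.
#'
#' @param preset `"published"` (factor 1.0) or `"equation"` (factor 0.8);
#'   ignored if `effectiveness_factor` is given explicitly.
#' @param effectiveness_factor optional explicit factor in (0,1\].
#' @param scenarios subset of `"moderate_detected"`, `"advanced_detected"`.
#' @param total_source `"narrative"` (default) or `"hy"`: which national
#'   total feeds the cascade.
#' @return an object of class `model_config`.
#' @export
model_config <- function(preset = c("published", "equation"),
                         effectiveness_factor = NULL,
                         scenarios = SCENARIOS,
                         total_source = c("narrative", "hy")) {
  preset <- match.arg(preset)
  total_source <- match.arg(total_source)
  f <- effectiveness_factor %||% switch(preset, published = 1.0, equation = 0.8)
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f <= 0 || f > 1) {
    pdbia_stop("effectiveness_factor must lie in (0, 1]")
  }
  if (length(scenarios) < 1L || !all(scenarios %in% SCENARIOS) ||
      anyDuplicated(scenarios)) {
    pdbia_stop("scenarios must be a non-empty subset of the two detection scenarios",
               "pdbia_config_error")
  }
  structure(
    list(preset = preset, effectiveness_factor = as.numeric(f),
         scenarios = scenarios, total_source = total_source),
    class = "model_config"
  )
}

#' Portfolio of countries plus shared model parameters
#'
#' @param countries list of entries, each a list with elements `costs`
#'   (a [country_cost_table()]) and `epi` (a [country_epidemiology()]).
#' @param stage_distribution a [stage_distribution()].
#' @param cascade a [cascade_params()].
#' @param device a [device_params()].
#' @param config a [model_config()].
#' @return a validated object of class `portfolio`.
#' @export
portfolio <- function(countries,
                      stage_distribution = pdbia::stage_distribution(),
                      cascade = cascade_params(),
                      device = device_params(),
                      config = model_config()) {
  p <- structure(
    list(countries = countries, stage_distribution = stage_distribution,
         cascade = cascade, device = device, config = config),
    class = "portfolio"
  )
  validate_portfolio(p)
}

#' Validate a portfolio
#'
#' Checks every type invariant: unique country identifiers, matching cost
#' and epidemiology records, and well-formed shared parameters.  Called by
#' [portfolio()] and [load_portfolio()].
#'
#' @param p a `portfolio`.
#' @return `p`, invisibly usable, after validation.
#' @export
validate_portfolio <- function(p) {
  if (!inherits(p, "portfolio")) pdbia_stop("not a portfolio object")
  if (!is.list(p$countries) || length(p$countries) < 1L) {
    pdbia_stop("portfolio must contain at least one country")
  }
  codes <- vapply(p$countries, function(ct) ct$costs$code, character(1))
  if (anyDuplicated(codes)) {
    pdbia_stop(sprintf("duplicate country identifiers: %s",
                       paste(unique(codes[duplicated(codes)]), collapse = ", ")))
  }
  for (ct in p$countries) {
    if (!inherits(ct$costs, "country_cost_table")) {
      pdbia_stop("each country entry needs a country_cost_table under $costs",
                 "pdbia_schema_error")
    }
    if (!inherits(ct$epi, "country_epidemiology")) {
      pdbia_stop("each country entry needs a country_epidemiology under $epi",
                 "pdbia_schema_error")
    }
    if (!identical(ct$costs$code, ct$epi$code)) {
      pdbia_stop(sprintf("cost table (%s) and epidemiology (%s) codes disagree",
                         ct$costs$code, ct$epi$code))
    }
    # re-run field validators so hand-edited objects are caught
    for (s in STAGES) {
      sc <- ct$costs$costs[[s]]
      if (!is_nonneg_number(sc$direct_cost) || !is_nonneg_number(sc$medication_cost)) {
        pdbia_stop(sprintf("negative or non-finite cost for %s/%s", ct$costs$code, s))
      }
    }
    if (!is.null(ct$epi$hy_counts) &&
        abs(sum(ct$epi$hy_counts) - ct$epi$total_hy) > 1e-9) {
      pdbia_stop(sprintf("hy_counts of %s do not sum to total_hy", ct$epi$code))
    }
  }
  names(p$countries) <- codes
  # revalidate shared parameter blocks through their constructors
  stage_distribution(p$stage_distribution[["mild"]],
                     p$stage_distribution[["moderate"]],
                     p$stage_distribution[["advanced"]])
  do.call(cascade_params, unclass(p$cascade))
  do.call(device_params, unclass(p$device))
  model_config(p$config$preset, p$config$effectiveness_factor,
               p$config$scenarios, p$config$total_source)
  p
}

#' National total feeding the cascade for one country
#'
#' Respects the portfolio's `total_source` flag; errors if the selected
#' source is unavailable for the country.
#'
#' @param country one entry of `portfolio$countries`.
#' @param config the portfolio's `model_config`.
#' @return a single number of diagnosed patients.
#' @export
country_total <- function(country, config) {
  tot <- switch(config$total_source,
                narrative = country$epi$total_text,
                hy = country$epi$total_hy)
  if (is.null(tot) || is.na(tot)) {
    pdbia_stop(sprintf("country %s lacks a usable '%s' total",
                       country$epi$code, config$total_source),
               "pdbia_config_error")
  }
  tot
}
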