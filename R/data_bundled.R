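# Bundled published parameter set: staged prevalence counts for seven
# regions, per-stage cost tables for five European countries, and the
# narrative national totals used by the detection cascade.
#
# All monetary values are whole euros per patient-year; counts are
# diagnosed-patient headcounts.

# Diagnosed PD patients by Hoehn & Yahr stage (2016 market-analysis data).
BUNDLED_HY <- list(
  US      = c(I = 108832, II = 251150, III = 293008, IV = 139013, V = 32709),
  Japan   = c(I = 15828,  II = 68580,  III = 183175, IV = 121674, V = 53094),
  UK      = c(I = 13649,  II = 31499,  III = 36749,  IV = 17849,  V = 4200),
  Spain   = c(I = 11819,  II = 52599,  III = 15758,  IV = 21082,  V = 5217),
  France  = c(I = 38729,  II = 89375,  III = 104271, IV = 50646,  V = 11917),
  Germany = c(I = 50293,  II = 116061, III = 135404, IV = 65768,  V = 15475),
  Italy   = c(I = 16338,  II = 37702,  III = 43986,  IV = 21365,  V = 5027)
)

# Per-stage direct costs (no drugs) and medication costs, EUR/patient-year,
# and diagnosed patients per stage, for the five modelled countries.
# Columns: stage, direct, medication, n_patients.
BUNDLED_COSTS <- list(
  ES = list(
    name = "Spain",
    mild     = c(direct = 5600,  medication = 1904, n = 47914),
    moderate = c(direct = 8680,  medication = 2951, n = 37266),
    advanced = c(direct = 10800, medication = 3672, n = 21295)
  ),
  SE = list(
    name = "Sweden",
    mild     = c(direct = 2180,  medication = 1308, n = 9000),
    moderate = c(direct = 7133,  medication = 2817, n = 7000),
    advanced = c(direct = 52300, medication = 5830, n = 4000)
  ),
  DE = list(
    name = "Germany",
    mild     = c(direct = 2000,  medication = 1500,  n = 172350),
    moderate = c(direct = 9105,  medication = 5000,  n = 134050),
    advanced = c(direct = 54006, medication = 15976, n = 76600)
  ),
  IT = list(
    name = "Italy",
    mild     = c(direct = 6460, medication = 2040, n = 54000),
    moderate = c(direct = 8677, medication = 2740, n = 42000),
    advanced = c(direct = 9943, medication = 3140, n = 24000)
  ),
  UK = list(
    name = "United Kingdom",
    mild     = c(direct = 6039,  medication = 1907, n = 46776),
    moderate = c(direct = 12376, medication = 3908, n = 36381),
    advanced = c(direct = 28522, medication = 9007, n = 20789)
  )
)

# Narrative national totals of diagnosed PD patients used by the cascade.
BUNDLED_TOTALS <- c(ES = 150000, SE = 20000, DE = 180000, IT = 120000, UK = 127000)

# Which bundled H&Y table (if any) belongs to each modelled country.
BUNDLED_HY_KEY <- c(ES = "Spain", SE = NA, DE = "Germany", IT = "Italy", UK = "UK")

#' Bundled Hoehn & Yahr prevalence tables
#'
#' Diagnosed Parkinson's patients by H&Y stage for seven regions (US,
#' Japan, UK, Spain, France, Germany, Italy).
#'
#' @param regions optional character vector to subset by region name.
#' @return a list of [hy_table()] objects.
#' @export
bundled_hy_tables <- function(regions = NULL) {
  keep <- regions %||% names(BUNDLED_HY)
  missing <- setdiff(keep, names(BUNDLED_HY))
  if (length(missing)) {
    pdbia_stop(sprintf("no bundled H&Y table for: %s", paste(missing, collapse = ", ")),
               "pdbia_config_error")
  }
  lapply(keep, function(r) hy_table(r, BUNDLED_HY[[r]]))
}

#' Bundled five-country portfolio
#'
#' The published European parameter set: per-stage cost tables and patient
#' counts for Spain, Sweden, Germany, Italy and the UK, the (0.45, 0.35,
#' 0.20) stage distribution, cascade constants (underdiagnosis 18%/36%,
#' sensitivity 0.9, penetration 0.2) and device economics (2500 EUR unit,
#' 30 uses/device-year, 2 prescriptions/patient-year).
#'
#' @param preset effectiveness preset, `"published"` (default) or
#'   `"equation"`; see [model_config()].
#' @param ... further arguments passed to [model_config()].
#' @return a validated `portfolio`.
#' @examples
#' p <- bundled_portfolio()
#' p$countries$DE$costs$costs$moderate$direct_cost  # 9105
#' @export
bundled_portfolio <- function(preset = c("published", "equation"), ...) {
  preset <- match.arg(preset)
  countries <- lapply(names(BUNDLED_COSTS), function(code) {
    b <- BUNDLED_COSTS[[code]]
    costs <- country_cost_table(
      code = code, name = b$name,
      costs = list(
        mild     = stage_costs(b$mild[["direct"]], b$mild[["medication"]]),
        moderate = stage_costs(b$moderate[["direct"]], b$moderate[["medication"]]),
        advanced = stage_costs(b$advanced[["direct"]], b$advanced[["medication"]])
      ),
      stage_counts = c(mild = b$mild[["n"]], moderate = b$moderate[["n"]],
                       advanced = b$advanced[["n"]])
    )
    hy_key <- BUNDLED_HY_KEY[[code]]
    epi <- country_epidemiology(
      code = code,
      hy_counts = if (!is.na(hy_key)) BUNDLED_HY[[hy_key]] else NULL,
      total_text = BUNDLED_TOTALS[[code]]
    )
    list(costs = costs, epi = epi)
  })
  names(countries) <- names(BUNDLED_COSTS)
  portfolio(
    countries = countries,
    stage_distribution = stage_distribution(0.45, 0.35, 0.20),
    cascade = cascade_params(),
    device = device_params(),
    config = model_config(preset = preset, ...)
  )
}
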