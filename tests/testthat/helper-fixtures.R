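# Shared fixtures built in code.

# A tiny hand-built two-country portfolio with easy arithmetic.
toy_portfolio <- function(...) {
  mk <- function(code, name, dc, mc, total) {
    pools <- stratify_total(total, stage_distribution())
    list(
      costs = country_cost_table(
        code, name,
        costs = list(mild = stage_costs(dc[1], mc[1]),
                     moderate = stage_costs(dc[2], mc[2]),
                     advanced = stage_costs(dc[3], mc[3])),
        stage_counts = pools$display
      ),
      epi = country_epidemiology(code, total_text = total)
    )
  }
  portfolio(
    countries = list(
      AA = mk("AA", "Alpha", c(1000, 3000, 10000), c(500, 1000, 2000), 10000),
      BB = mk("BB", "Beta", c(2000, 2000, 2000), c(800, 800, 800), 50000)
    ),
    config = model_config(...)
  )
}

# Closed-form oracle for the national total saving: one expression, no reuse
# of the pipeline code path.
oracle_total_saving <- function(p, code, scenario) {
  ct <- p$countries[[code]]
  total <- switch(p$config$total_source,
                  narrative = ct$epi$total_text, hy = ct$epi$total_hy)
  share <- switch(scenario, moderate_detected = p$stage_distribution[["mild"]],
                  advanced_detected = p$stage_distribution[["moderate"]])
  rate <- switch(scenario,
                 moderate_detected = p$cascade$underdiagnosis_rate_mild,
                 advanced_detected = p$cascade$underdiagnosis_rate_moderate)
  lo <- switch(scenario, moderate_detected = "mild", advanced_detected = "moderate")
  hi <- switch(scenario, moderate_detected = "moderate", advanced_detected = "advanced")
  dev <- p$device$unit_price / p$device$uses_per_device_year *
    p$device$prescriptions_per_patient_year
  if (p$device$cost_rounding == "floor_integer") dev <- floor(dev)
  n <- total * share * rate * p$cascade$detection_sensitivity *
    p$cascade$market_penetration
  pp <- p$config$effectiveness_factor *
    (ct$costs$costs[[hi]]$direct_cost - ct$costs$costs[[lo]]$direct_cost) -
    (ct$costs$costs[[hi]]$medication_cost - ct$costs$costs[[lo]]$medication_cost) - dev
  n * pp
}

# Printed five-country reference tables used across tests (stage order
# mild, moderate, advanced; countries ES, SE, DE, IT, UK).
printed_direct_costs <- rbind(
  ES = c(5600, 8680, 10800), SE = c(2180, 7133, 52300),
  DE = c(2000, 9105, 54006), IT = c(6460, 8677, 9943),
  UK = c(6039, 12376, 28522)
)
printed_medication_costs <- rbind(
  ES = c(1904, 2951, 3672), SE = c(1308, 2817, 5830),
  DE = c(1500, 5000, 15976), IT = c(2040, 2740, 3140),
  UK = c(1907, 3908, 9007)
)
printed_stage_counts <- rbind(
  ES = c(47914, 37266, 21295), SE = c(9000, 7000, 4000),
  DE = c(172350, 134050, 76600), IT = c(54000, 42000, 24000),
  UK = c(46776, 36381, 20789)
)
colnames(printed_direct_costs) <- colnames(printed_medication_costs) <-
  colnames(printed_stage_counts) <- c("mild", "moderate", "advanced")

# Published cascade grid (underdiagnosed, detectable, adopted display counts).
printed_cascade <- list(
  moderate_detected = rbind(
    ES = c(12150, 10935, 2187), SE = c(1620, 1458, 292),
    DE = c(14580, 13122, 2624), IT = c(9720, 8748, 1750),
    UK = c(10287, 9258, 1852)
  ),
  advanced_detected = rbind(
    ES = c(18900, 17010, 3402), SE = c(2520, 2268, 454),
    DE = c(22680, 20412, 4082), IT = c(15120, 13608, 2722),
    UK = c(16002, 14402, 2880)
  )
)

# Published national totals (EUR/year) per scenario.
printed_totals <- list(
  moderate_detected = c(ES = 4082692, SE = 955865, DE = 9025312,
                        IT = 2363126, UK = 7720983),
  advanced_detected = c(ES = 4195346, SE = 19045757, DE = 137817742,
                        IT = 1906934, UK = 31342029)
)
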