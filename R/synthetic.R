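# Synthetic country-portfolio generator.
#
# Emulates the statistical structure of national cost tables: per-stage
# direct costs that rise with disease stage (drawn as a mild-stage base
# times stage multipliers >= 1), medication costs as a fraction of direct
# costs (hence also stage-monotone), a positive diagnosed-population total,
# and cascade rates in [0,1].  Per-country random streams are derived from
# (seed, index) so a country does not depend on how many others are drawn.

#' Synthetic-portfolio configuration
#'
#' @param n_countries number of countries to generate (>= 1).
#' @param total_range (low, high) diagnosed-patient national totals.
#' @param base_direct_cost_range (low, high) euros for the mild-stage
#'   direct cost.
#' @param moderate_multiplier_range,advanced_multiplier_range (low, high)
#'   multiplicative factors >= 1 applied successively
#'   (moderate = mild x m1, advanced = moderate x m2).
#' @param medication_fraction_range (low, high) in (0,1): medication cost
#'   as a fraction of the same stage's direct cost.
#' @param cascade_jitter relative spread around the default cascade rates
#'   (0 = exact defaults).
#' @param seed integer master seed.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_countries = 5L,
                         total_range = c(20000, 200000),
                         base_direct_cost_range = c(2000, 7000),
                         moderate_multiplier_range = c(1.2, 4),
                         advanced_multiplier_range = c(1.2, 6),
                         medication_fraction_range = c(0.2, 0.6),
                         cascade_jitter = 0,
                         seed = 1L) {
  if (!is_count(n_countries) || n_countries < 1) {
    pdbia_stop("n_countries must be a positive integer", "pdbia_precondition_error")
  }
  ranges <- list(total_range = total_range,
                 base_direct_cost_range = base_direct_cost_range,
                 moderate_multiplier_range = moderate_multiplier_range,
                 advanced_multiplier_range = advanced_multiplier_range,
                 medication_fraction_range = medication_fraction_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (!is.numeric(r) || length(r) != 2L || r[1] > r[2]) {
      pdbia_stop(sprintf("%s must be (low, high) with low <= high", nm))
    }
  }
  if (any(c(moderate_multiplier_range, advanced_multiplier_range) < 1)) {
    pdbia_stop("stage multipliers must be >= 1")
  }
  if (any(medication_fraction_range <= 0) || any(medication_fraction_range >= 1)) {
    pdbia_stop("medication fractions must lie in (0, 1)")
  }
  if (!is.numeric(cascade_jitter) || cascade_jitter < 0 || cascade_jitter >= 1) {
    pdbia_stop("cascade_jitter must lie in [0, 1)")
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    pdbia_stop("seed must be a single integer")
  }
  structure(c(list(n_countries = as.integer(n_countries)), ranges,
              list(cascade_jitter = cascade_jitter, seed = as.integer(seed))),
            class = "synth_config")
}

# Deterministic per-country seed: independent of n_countries, < 2^31.
country_seed <- function(seed, index) {
  (abs(as.numeric(seed)) * 48271 + as.numeric(index) * 101159) %% 2147483629
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

#' Generate one synthetic country
#'
#' Deterministic given `(config$seed, index)`.
#'
#' @param config a [synth_config()].
#' @param index positive integer country index.
#' @return list with `costs` (a [country_cost_table()]) and `epi`
#'   (a [country_epidemiology()]).
#' @export
generate_country <- function(config, index) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, as.list(config))
  if (!is_count(index) || index < 1) pdbia_stop("index must be a positive integer")
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(country_seed(config$seed, index))

  total <- round(runif1(config$total_range))
  base_dc <- round(runif1(config$base_direct_cost_range))
  dc_mod <- round(base_dc * runif1(config$moderate_multiplier_range))
  dc_adv <- round(dc_mod * runif1(config$advanced_multiplier_range))
  frac <- runif1(config$medication_fraction_range)
  mc <- round(frac * c(base_dc, dc_mod, dc_adv))

  code <- sprintf("SYN%02d", index)
  pools <- stratify_total(total, stage_distribution())
  costs <- country_cost_table(
    code = code, name = sprintf("Synthetic country %d", index),
    costs = list(mild = stage_costs(base_dc, mc[1]),
                 moderate = stage_costs(dc_mod, mc[2]),
                 advanced = stage_costs(dc_adv, mc[3])),
    stage_counts = pools$display
  )
  epi <- country_epidemiology(code, hy_counts = NULL, total_text = total)
  list(costs = costs, epi = epi)
}

#' Generate a synthetic portfolio
#'
#' `n_countries` unique synthetic countries with the default stage
#' distribution and cascade parameters (jittered if configured), packaged
#' as a fully validated portfolio.
#'
#' @param config a [synth_config()].
#' @param ... passed to [model_config()] (preset, scenarios, ...).
#' @return a validated `portfolio`.
#' @examples
#' p <- generate_portfolio(synth_config(n_countries = 3, seed = 7))
#' savings_table(p)
#' @export
generate_portfolio <- function(config = synth_config(), ...) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, as.list(config))
  countries <- lapply(seq_len(config$n_countries),
                      function(i) generate_country(config, i))
  names(countries) <- vapply(countries, function(ct) ct$costs$code, character(1))

  casc <- cascade_params()
  if (config$cascade_jitter > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(country_seed(config$seed, 0L))
    j <- config$cascade_jitter
    jit <- function(x) min(1, max(0, x * stats::runif(1, 1 - j, 1 + j)))
    casc <- cascade_params(
      underdiagnosis_rate_mild = jit(casc$underdiagnosis_rate_mild),
      underdiagnosis_rate_moderate = jit(casc$underdiagnosis_rate_moderate),
      detection_sensitivity = jit(casc$detection_sensitivity),
      market_penetration = jit(casc$market_penetration)
    )
  }
  portfolio(countries = countries,
            stage_distribution = stage_distribution(),
            cascade = casc,
            device = device_params(),
            config = model_config(...))
}
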