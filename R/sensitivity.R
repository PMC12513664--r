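# Sensitivity and break-even analysis: parameter paths, one-way sweeps,
# tornado ranking, Monte-Carlo propagation, and the algebraic break-even
# device cost.

# Dotted parameter paths into a portfolio.  Scalar model knobs only; the
# per-country cost cells are inputs, not tunable scenario parameters.
PARAM_PATHS <- c(
  "cascade.underdiagnosis_rate_mild",
  "cascade.underdiagnosis_rate_moderate",
  "cascade.detection_sensitivity",
  "cascade.market_penetration",
  "device.unit_price",
  "device.uses_per_device_year",
  "device.prescriptions_per_patient_year",
  "stage_distribution.mild",
  "stage_distribution.moderate",
  "stage_distribution.advanced",
  "config.effectiveness_factor"
)

#' Read a scalar parameter from a portfolio by dotted path
#'
#' @param p a `portfolio`.
#' @param path e.g. `"cascade.market_penetration"`; see
#'   `pdbia:::PARAM_PATHS` for the full set.
#' @return the parameter value.
#' @export
get_param <- function(p, path) {
  check_param_path(path)
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  p[[parts[1]]][[parts[2]]]
}

#' Set a scalar parameter, returning a new validated portfolio
#'
#' Stage shares cannot be set individually (they must sum to 1), so setting
#' one rescales the other two proportionally.
#'
#' @inheritParams get_param
#' @param value new value; must respect the parameter's own domain.
#' @return a new `portfolio`; the input is unmodified.
#' @export
set_param <- function(p, path, value) {
  check_param_path(path)
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  block <- parts[1]
  field <- parts[2]
  if (block == "stage_distribution") {
    shares <- as.numeric(p$stage_distribution)
    names(shares) <- STAGES
    others <- setdiff(STAGES, field)
    rest <- sum(shares[others])
    if (rest <= 0) pdbia_stop("cannot rebalance a degenerate stage distribution")
    shares[others] <- shares[others] * (1 - value) / rest
    shares[field] <- value
    p$stage_distribution <- stage_distribution(shares[["mild"]], shares[["moderate"]],
                                               shares[["advanced"]])
  } else if (block == "config") {
    p$config <- model_config(p$config$preset, effectiveness_factor = value,
                             scenarios = p$config$scenarios,
                             total_source = p$config$total_source)
  } else {
    args <- unclass(p[[block]])
    args[[field]] <- value
    p[[block]] <- switch(block,
                         cascade = do.call(cascade_params, args),
                         device = do.call(device_params, args))
  }
  validate_portfolio(p)
}

check_param_path <- function(path) {
  if (!is.character(path) || length(path) != 1L || !path %in% PARAM_PATHS) {
    pdbia_stop(sprintf("unknown parameter path: %s (known: %s)",
                       paste(path, collapse = ","), paste(PARAM_PATHS, collapse = ", ")),
               "pdbia_config_error")
  }
}

#' One-way parameter sweep
#'
#' Evaluates the national total saving for one country and scenario at each
#' grid value of a single parameter, all others held at their portfolio
#' values.  The base portfolio is never modified.
#'
#' @param p a `portfolio`.
#' @param path dotted parameter path, see [set_param()].
#' @param grid numeric vector of parameter values.
#' @param country country code present in the portfolio.
#' @param scenario detection scenario.
#' @return data.frame with columns `value` and `total_saving` (unrounded).
#' @examples
#' one_way_sweep(bundled_portfolio(), "cascade.market_penetration",
#'               c(0.1, 0.2, 0.4), "SE", "advanced_detected")
#' @export
one_way_sweep <- function(p, path, grid, country, scenario) {
  validate_portfolio(p)
  if (!is.numeric(grid) || length(grid) < 1L) {
    pdbia_stop("grid must be a non-empty numeric vector", "pdbia_precondition_error")
  }
  totals <- vapply(grid, function(v) {
    evaluate_total_saving(set_param(p, path, v), country, scenario)
  }, numeric(1))
  data.frame(value = grid, total_saving = totals)
}

#' Parameter range for tornado analysis
#'
#' @param parameter dotted parameter path.
#' @param low,high,base values with `low <= base <= high`, each inside the
#'   parameter's own domain.
#' @return an object of class `param_range`.
#' @export
param_range <- function(parameter, low, high, base) {
  check_param_path(parameter)
  if (!(low <= base && base <= high)) {
    pdbia_stop(sprintf("%s: need low <= base <= high", parameter))
  }
  structure(list(parameter = parameter, low = low, high = high, base = base),
            class = "param_range")
}

#' Default illustrative tornado ranges
#'
#' Penetration 0.1-0.3, sensitivity 0.8-1.0, unit price 2000-3000 (the
#' published +/- 500 EUR band), and +/- 25% relative on both underdiagnosis
#' rates, each centred on the portfolio's current values where applicable.
#'
#' @param p a `portfolio` (bases are read from it).
#' @return list of [param_range()] objects.
#' @export
default_tornado_ranges <- function(p = bundled_portfolio()) {
  rm_ <- get_param(p, "cascade.underdiagnosis_rate_mild")
  rM <- get_param(p, "cascade.underdiagnosis_rate_moderate")
  list(
    param_range("cascade.market_penetration", 0.1, 0.3,
                get_param(p, "cascade.market_penetration")),
    param_range("cascade.detection_sensitivity", 0.8, 1.0,
                get_param(p, "cascade.detection_sensitivity")),
    param_range("device.unit_price", 2000, 3000, get_param(p, "device.unit_price")),
    param_range("cascade.underdiagnosis_rate_mild", 0.75 * rm_, min(1, 1.25 * rm_), rm_),
    param_range("cascade.underdiagnosis_rate_moderate", 0.75 * rM, min(1, 1.25 * rM), rM)
  )
}

#' Tornado ranking
#'
#' Evaluates the total saving at each range's low and high ends (one
#' parameter at a time) and ranks parameters by the absolute span, largest
#' first; ties break lexicographically by parameter path.
#'
#' @param p a `portfolio`.
#' @param ranges list of [param_range()] objects (at least one).
#' @param country country code.
#' @param scenario detection scenario.
#' @return data.frame with columns `parameter`, `saving_at_low`,
#'   `saving_at_high`, `span`, sorted by decreasing span.
#' @export
tornado <- function(p, ranges = default_tornado_ranges(p), country, scenario) {
  validate_portfolio(p)
  if (inherits(ranges, "param_range")) ranges <- list(ranges)
  if (!is.list(ranges) || length(ranges) < 1L) {
    pdbia_stop("need at least one parameter range", "pdbia_precondition_error")
  }
  rows <- lapply(ranges, function(r) {
    if (!inherits(r, "param_range")) r <- do.call(param_range, as.list(r))
    lo <- evaluate_total_saving(set_param(p, r$parameter, r$low), country, scenario)
    hi <- evaluate_total_saving(set_param(p, r$parameter, r$high), country, scenario)
    data.frame(parameter = r$parameter, saving_at_low = lo, saving_at_high = hi,
               span = abs(hi - lo), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span, out$parameter), ]
  rownames(out) <- NULL
  out
}

#' Monte-Carlo sampling specification
#'
#' @param distributions named list, one entry per parameter path; each a
#'   distribution descriptor from [dist_point()], [dist_uniform()] or
#'   [dist_triangular()].
#' @param n_draws number of draws (>= 1).
#' @param seed integer seed.
#' @return an object of class `mc_spec`.
#' @export
mc_spec <- function(distributions, n_draws = 1000L, seed = 1L) {
  if (!is.list(distributions) || is.null(names(distributions)) ||
      any(!nzchar(names(distributions)))) {
    pdbia_stop("distributions must be a named list keyed by parameter path")
  }
  for (nm in names(distributions)) {
    check_param_path(nm)
    if (!inherits(distributions[[nm]], "pdbia_dist")) {
      pdbia_stop(sprintf("distribution for %s is not a distribution descriptor", nm))
    }
  }
  if (!is_count(n_draws) || n_draws < 1) pdbia_stop("n_draws must be >= 1")
  if (!is.numeric(seed) || length(seed) != 1L) pdbia_stop("seed must be an integer")
  structure(list(distributions = distributions, n_draws = as.integer(n_draws),
                 seed = as.integer(seed)),
            class = "mc_spec")
}

#' Distribution descriptors for Monte-Carlo sampling
#'
#' `dist_point(value)` is a degenerate point mass, `dist_uniform(low, high)`
#' is uniform, `dist_triangular(low, mode, high)` is triangular (sampled by
#' inverse CDF).
#'
#' @param value,low,mode,high distribution parameters.
#' @return an object of class `pdbia_dist`.
#' @export
dist_point <- function(value) {
  structure(list(kind = "point", value = value), class = "pdbia_dist")
}

#' @rdname dist_point
#' @export
dist_uniform <- function(low, high) {
  if (low > high) pdbia_stop("uniform: low must be <= high")
  structure(list(kind = "uniform", low = low, high = high), class = "pdbia_dist")
}

#' @rdname dist_point
#' @export
dist_triangular <- function(low, mode, high) {
  if (!(low <= mode && mode <= high)) pdbia_stop("triangular: need low <= mode <= high")
  structure(list(kind = "triangular", low = low, mode = mode, high = high),
            class = "pdbia_dist")
}

sample_dist <- function(d, n) {
  switch(d$kind,
         point = rep(d$value, n),
         uniform = stats::runif(n, d$low, d$high),
         triangular = {
           u <- stats::runif(n)
           if (d$high == d$low) rep(d$low, n) else {
             fc <- (d$mode - d$low) / (d$high - d$low)
             ifelse(u < fc,
                    d$low + sqrt(u * (d$high - d$low) * (d$mode - d$low)),
                    d$high - sqrt((1 - u) * (d$high - d$low) * (d$high - d$mode)))
           }
         },
         pdbia_stop(sprintf("unknown distribution kind: %s", d$kind)))
}

#' Monte-Carlo uncertainty propagation
#'
#' Draws every listed parameter independently from its distribution,
#' re-evaluates the deterministic model per draw, and summarises the
#' resulting total-saving distribution.  Reproducible given the spec's seed.
#'
#' @param p a `portfolio`.
#' @param spec an [mc_spec()].
#' @param country country code.
#' @param scenario detection scenario.
#' @param keep_draws logical; attach the per-draw totals?
#' @return list with `mean`, `sd`, `quantiles` (2.5/50/97.5%), `n_draws`,
#'   and optionally `draws`.
#' @export
monte_carlo <- function(p, spec, country, scenario, keep_draws = FALSE) {
  validate_portfolio(p)
  if (!inherits(spec, "mc_spec")) pdbia_stop("spec must be an mc_spec")
  # draws must stay inside each parameter's domain: probe low/high ends
  for (nm in names(spec$distributions)) {
    d <- spec$distributions[[nm]]
    ends <- switch(d$kind, point = d$value, c(d$low, d$high))
    for (v in ends) set_param(p, nm, v)  # errors if out of domain
  }
  paths <- names(spec$distributions)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)
  draws_mat <- vapply(paths, function(nm) sample_dist(spec$distributions[[nm]],
                                                      spec$n_draws),
                      numeric(spec$n_draws))
  draws_mat <- matrix(draws_mat, nrow = spec$n_draws,
                      dimnames = list(NULL, paths))
  totals <- vapply(seq_len(spec$n_draws), function(i) {
    pi <- p
    for (nm in paths) pi <- set_param(pi, nm, draws_mat[i, nm])
    evaluate_total_saving(pi, country, scenario)
  }, numeric(1))
  out <- list(
    mean = mean(totals),
    sd = stats::sd(totals),
    quantiles = stats::quantile(totals, c(0.025, 0.5, 0.975), names = TRUE),
    n_draws = spec$n_draws
  )
  if (keep_draws) out$draws <- totals
  out
}

#' Break-even annual device cost
#'
#' The per-patient device cost at which the annual saving is exactly zero:
#' `f * (DC_high - DC_low) - (MC_high - MC_low)`.  Display rounding is
#' deliberately ignored here (a root of a rounded step function is
#' ill-defined).
#'
#' @param costs a [country_cost_table()].
#' @param scenario detection scenario.
#' @param effectiveness_factor factor in (0,1\].
#' @return euros per patient-year.
#' @examples
#' p <- bundled_portfolio()
#' break_even_device_cost(p$countries$SE$costs, "moderate_detected", 1.0)  # 3444
#' @export
break_even_device_cost <- function(costs, scenario, effectiveness_factor = 1.0) {
  cmp <- saving_components(costs, scenario, effectiveness_factor, device_cost = 0)
  cmp$effectiveness_factor * cmp$direct_cost_gap - cmp$medication_cost_gap
}
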