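# The bia_model S3 object: a fully evaluated budget-impact model with the
# classic modelling-object surface (print, summary, coef, predict, plot,
# simulate).

#' Fit the budget-impact model
#'
#' Evaluates the full deterministic model — stage stratification, detection
#' cascade, device amortization and savings equations — over a portfolio and
#' returns a classed object carrying both the inputs and every intermediate
#' table.  "Fitting" here is closed-form evaluation: the model has no free
#' parameters to estimate, only scenario parameters to propagate.
#'
#' @param portfolio a `portfolio`; defaults to the bundled five-country set.
#' @param preset optional effectiveness preset overriding the portfolio's
#'   config (`"published"` or `"equation"`).
#' @return an object of class `bia_model` with elements `portfolio`,
#'   `cascade` (per country x scenario reach table), `savings` (per country
#'   x scenario savings table), `device_cost` (EUR/patient-year) and
#'   `monitorable` (pooled monitorable fraction across bundled H&Y regions,
#'   or across the portfolio's own staged tables when present).
#' @examples
#' m <- bia_model()
#' summary(m)
#' coef(m)
#' @export
bia_model <- function(portfolio = bundled_portfolio(), preset = NULL) {
  validate_portfolio(portfolio)
  if (!is.null(preset)) {
    portfolio$config <- model_config(preset, scenarios = portfolio$config$scenarios,
                                     total_source = portfolio$config$total_source)
  }
  hy <- lapply(portfolio$countries, function(ct) {
    if (is.null(ct$epi$hy_counts)) NULL else hy_table(ct$epi$code, ct$epi$hy_counts)
  })
  hy <- Filter(Negate(is.null), hy)
  structure(
    list(
      portfolio = portfolio,
      cascade = cascade_table(portfolio),
      savings = savings_table(portfolio),
      device_cost = annual_device_cost(portfolio$device),
      monitorable = if (length(hy)) monitorable_fraction(hy) else NA_real_
    ),
    class = "bia_model"
  )
}

#' @export
print.bia_model <- function(x, ...) {
  p <- x$portfolio
  cat("Budget-impact model: wearable PD monitoring\n")
  cat(sprintf("  countries: %s\n",
              paste(vapply(p$countries, function(ct) ct$costs$code, character(1)),
                    collapse = ", ")))
  cat(sprintf("  effectiveness preset: %s (factor %.2f)\n",
              p$config$preset, p$config$effectiveness_factor))
  cat(sprintf("  device cost: %s EUR/patient-year\n", format(x$device_cost)))
  cat(sprintf("  total annual saving, all countries and scenarios: %s EUR\n",
              format(round_half_away(sum(x$savings$total_saving_unrounded)),
                     big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' @export
summary.bia_model <- function(object, ...) {
  structure(list(model = object), class = "summary.bia_model")
}

#' @export
print.summary.bia_model <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nDetection cascade (display-rounded):\n")
  print(m$cascade[, c("country", "scenario", "underdiagnosed_display",
                      "detectable_display", "adopted_display")], row.names = FALSE)
  cat("\nAnnual savings (EUR, display-rounded):\n")
  print(m$savings[, c("country", "scenario", "n_patients_display",
                      "per_patient_saving", "total_saving")], row.names = FALSE)
  if (!is.na(m$monitorable)) {
    cat(sprintf("\nMonitorable fraction (pooled staged tables): %.1f%%\n",
                100 * m$monitorable))
  }
  invisible(x)
}

#' @export
coef.bia_model <- function(object, ...) {
  p <- object$portfolio
  c(stats::setNames(as.numeric(p$stage_distribution),
                    paste0("stage_distribution.", STAGES)),
    stats::setNames(unlist(unclass(p$cascade)),
                    paste0("cascade.", names(p$cascade))),
    device.annual_cost = object$device_cost,
    config.effectiveness_factor = p$config$effectiveness_factor)
}

#' Predict national savings under modified scenario parameters
#'
#' Re-evaluates the deterministic model with scalar parameters overridden;
#' the model object itself is unchanged.
#'
#' @param object a `bia_model`.
#' @param newdata optional named list of parameter overrides keyed by dotted
#'   path (see [set_param()]), e.g.
#'   `list("cascade.market_penetration" = 0.3)`.
#' @param country optional country code filter.
#' @param scenario optional scenario filter.
#' @param ... unused.
#' @return a savings data.frame as from [savings_table()].
#' @export
predict.bia_model <- function(object, newdata = NULL, country = NULL,
                              scenario = NULL, ...) {
  p <- object$portfolio
  for (nm in names(newdata)) p <- set_param(p, nm, newdata[[nm]])
  out <- savings_table(p)
  if (!is.null(country)) out <- out[out$country %in% country, ]
  if (!is.null(scenario)) out <- out[out$scenario %in% scenario, ]
  rownames(out) <- NULL
  out
}

#' Simulate total savings under parameter uncertainty
#'
#' Monte-Carlo draws of the national total saving for one country and
#' scenario; a thin wrapper over [monte_carlo()] keeping draws.
#'
#' @param object a `bia_model`.
#' @param nsim number of draws.
#' @param seed integer seed.
#' @param country country code.
#' @param scenario detection scenario.
#' @param distributions named list of distribution descriptors; defaults to
#'   uniform penetration 0.1-0.3 and unit price 2000-3000.
#' @param ... unused.
#' @return numeric vector of `nsim` simulated totals.
#' @export
simulate.bia_model <- function(object, nsim = 1000L, seed = 1L,
                               country = names(object$portfolio$countries)[1],
                               scenario = object$portfolio$config$scenarios[1],
                               distributions = NULL, ...) {
  distributions <- distributions %||% list(
    "cascade.market_penetration" = dist_uniform(0.1, 0.3),
    "device.unit_price" = dist_uniform(2000, 3000)
  )
  spec <- mc_spec(distributions, n_draws = nsim, seed = seed)
  monte_carlo(object$portfolio, spec, country, scenario, keep_draws = TRUE)$draws
}

#' Tornado plot of parameter sensitivity
#'
#' Horizontal bars spanning the total saving at each parameter's low and
#' high end, most influential on top.
#'
#' @param x a `bia_model`.
#' @param country country code.
#' @param scenario detection scenario.
#' @param ranges list of [param_range()] objects; defaults to
#'   [default_tornado_ranges()].
#' @param ... passed to [graphics::barplot()].
#' @return the tornado data.frame, invisibly.
#' @export
plot.bia_model <- function(x, country = names(x$portfolio$countries)[1],
                           scenario = x$portfolio$config$scenarios[1],
                           ranges = default_tornado_ranges(x$portfolio), ...) {
  tor <- tornado(x$portfolio, ranges, country, scenario)
  base <- evaluate_total_saving(x$portfolio, country, scenario)
  ord <- rev(seq_len(nrow(tor)))  # largest span on top
  old <- graphics::par(mar = c(5, 14, 3, 1))
  on.exit(graphics::par(old))
  lo <- pmin(tor$saving_at_low, tor$saving_at_high)[ord]
  hi <- pmax(tor$saving_at_low, tor$saving_at_high)[ord]
  graphics::plot(NULL, xlim = range(c(lo, hi, base)), ylim = c(0.5, nrow(tor) + 0.5),
                 yaxt = "n", xlab = "Total annual saving (EUR)", ylab = "",
                 main = sprintf("Tornado: %s, %s", country, scenario), ...)
  graphics::rect(lo, seq_along(ord) - 0.35, hi, seq_along(ord) + 0.35,
                 col = "steelblue")
  graphics::abline(v = base, lty = 2)
  graphics::axis(2, at = seq_along(ord), labels = tor$parameter[ord], las = 1,
                 cex.axis = 0.8)
  invisible(tor)
}
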