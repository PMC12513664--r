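# Portfolio file I/O.
#
# A portfolio on disk is a directory with two files:
#   config.json  — shared parameters and per-country epidemiology
#   costs.csv    — flat per-country cost table (country, stage,
#                  direct_cost, medication_cost, n_patients)
# Numbers are written at full double precision so load(write(p)) == p.

BUNDLED_TOKENS <- c("bundled", "bundled:default")

#' Load a portfolio
#'
#' @param path directory written by [write_portfolio()], or the token
#'   `"bundled"` for the built-in five-country parameter set.
#' @return a validated `portfolio`.
#' @export
load_portfolio <- function(path) {
  if (is.character(path) && length(path) == 1L && path %in% BUNDLED_TOKENS) {
    return(bundled_portfolio())
  }
  cfg_file <- file.path(path, "config.json")
  costs_file <- file.path(path, "costs.csv")
  if (!dir.exists(path) || !file.exists(cfg_file) || !file.exists(costs_file)) {
    pdbia_stop(sprintf("portfolio directory %s is missing config.json or costs.csv",
                       path), "pdbia_io_error")
  }
  cfg <- jsonlite::read_json(cfg_file, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  costs_df <- utils::read.csv(costs_file, stringsAsFactors = FALSE)
  need <- c("country", "stage", "direct_cost", "medication_cost", "n_patients")
  if (!all(need %in% names(costs_df))) {
    pdbia_stop(sprintf("costs.csv must have columns: %s", paste(need, collapse = ", ")),
               "pdbia_schema_error")
  }
  countries <- lapply(cfg$countries, function(meta) {
    code <- meta$code
    rows <- costs_df[costs_df$country == code, ]
    missing <- setdiff(STAGES, rows$stage)
    if (length(missing)) {
      pdbia_stop(sprintf("country %s is missing stage row(s): %s",
                         code, paste(missing, collapse = ", ")),
                 "pdbia_schema_error")
    }
    by_stage <- lapply(STAGES, function(s) {
      r <- rows[rows$stage == s, ][1, ]
      stage_costs(r$direct_cost, r$medication_cost)
    })
    names(by_stage) <- STAGES
    counts <- vapply(STAGES, function(s) rows[rows$stage == s, ][1, "n_patients"],
                     numeric(1))
    hy <- NULL
    if (!is.null(meta$hy_counts) && length(meta$hy_counts)) {
      hy <- stats::setNames(as.numeric(unlist(meta$hy_counts)[HY_STAGES]), HY_STAGES)
    }
    list(
      costs = country_cost_table(code, meta$name, by_stage,
                                 stats::setNames(counts, STAGES)),
      epi = country_epidemiology(code, hy_counts = hy, total_text = meta$total_text)
    )
  })
  names(countries) <- vapply(countries, function(ct) ct$costs$code, character(1))
  portfolio(
    countries = countries,
    stage_distribution = stage_distribution(cfg$stage_distribution$mild,
                                            cfg$stage_distribution$moderate,
                                            cfg$stage_distribution$advanced),
    cascade = do.call(cascade_params, as.list(cfg$cascade)),
    device = device_params(cfg$device$unit_price, cfg$device$uses_per_device_year,
                           cfg$device$prescriptions_per_patient_year,
                           cfg$device$cost_rounding),
    config = model_config(cfg$config$preset, cfg$config$effectiveness_factor,
                          unlist(cfg$config$scenarios), cfg$config$total_source)
  )
}

#' Write a portfolio to a directory
#'
#' Emits `config.json` (shared parameters, per-country epidemiology) and
#' `costs.csv` (one row per country x stage).  The directory reloads to a
#' portfolio equal to the source.
#'
#' @param p a `portfolio`.
#' @param path destination directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_portfolio <- function(p, path) {
  validate_portfolio(p)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) pdbia_stop(sprintf("cannot create %s", path), "pdbia_io_error")

  cfg <- list(
    stage_distribution = as.list(stats::setNames(as.numeric(p$stage_distribution),
                                                 STAGES)),
    cascade = unclass(p$cascade),
    device = unclass(p$device),
    config = unclass(p$config),
    countries = lapply(unname(p$countries), function(ct) {
      list(code = ct$epi$code, name = ct$costs$name,
           total_text = ct$epi$total_text,
           hy_counts = if (is.null(ct$epi$hy_counts)) NULL else
             as.list(ct$epi$hy_counts))
    })
  )
  # I(17) significant digits: doubles survive the text round trip exactly
  jsonlite::write_json(cfg, file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE,
                       null = "null")

  rows <- do.call(rbind, lapply(unname(p$countries), function(ct) {
    data.frame(
      country = ct$costs$code, stage = STAGES,
      direct_cost = vapply(STAGES, function(s) ct$costs$costs[[s]]$direct_cost,
                           numeric(1)),
      medication_cost = vapply(STAGES, function(s) ct$costs$costs[[s]]$medication_cost,
                               numeric(1)),
      n_patients = ct$costs$stage_counts,
      stringsAsFactors = FALSE
    )
  }))
  # full-precision text so numeric round-trip is exact
  out <- rows
  for (col in c("direct_cost", "medication_cost", "n_patients")) {
    out[[col]] <- sprintf("%.17g", rows[[col]])
  }
  utils::write.csv(out, file.path(path, "costs.csv"), row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write model results to CSV or JSON
#'
#' @param results non-empty data.frame, typically from [savings_table()].
#' @param path destination file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("csv", "json")) {
  if (!is.character(format) || !all(format %in% c("csv", "json"))) {
    pdbia_stop("unknown results format", "pdbia_config_error")
  }
  format <- match.arg(format)
  if (!is.data.frame(results) || nrow(results) == 0L) {
    pdbia_stop("results must be a non-empty data.frame", "pdbia_precondition_error")
  }
  if (format == "csv") {
    utils::write.csv(results, path, row.names = FALSE)
  } else {
    jsonlite::write_json(results, path, dataframe = "rows", digits = NA, pretty = TRUE)
  }
  invisible(path)
}
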