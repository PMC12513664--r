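# Domain types, validation, bundled parameter set, and portfolio file I/O.

test_that("bundled portfolio reproduces every published cost and count cell", {
  p <- bundled_portfolio()
  expect_named(p$countries, c("ES", "SE", "DE", "IT", "UK"))
  for (code in rownames(printed_direct_costs)) {
    ct <- p$countries[[code]]$costs
    for (s in c("mild", "moderate", "advanced")) {
      expect_identical(ct$costs[[s]]$direct_cost, printed_direct_costs[code, s],
                       label = sprintf("%s/%s direct", code, s))
      expect_identical(ct$costs[[s]]$medication_cost,
                       printed_medication_costs[code, s],
                       label = sprintf("%s/%s medication", code, s))
    }
    expect_identical(unname(ct$stage_counts),
                     unname(printed_stage_counts[code, ]),
                     label = sprintf("%s stage counts", code))
  }
  # narrative totals driving the cascade
  totals <- vapply(p$countries, function(ct) ct$epi$total_text, numeric(1))
  expect_identical(unname(totals), c(150000, 20000, 180000, 120000, 127000))
})

test_that("constructors enforce type invariants", {
  expect_error(stage_costs(-1, 100), class = "pdbia_validation_error")
  expect_error(stage_costs(100, Inf), class = "pdbia_validation_error")
  expect_error(stage_distribution(0.5, 0.4, 0.2), "sum to 1")
  expect_error(stage_distribution(1.2, -0.1, -0.1), class = "pdbia_validation_error")
  expect_error(cascade_params(market_penetration = 1.5),
               class = "pdbia_validation_error")
  expect_error(device_params(uses_per_device_year = 0),
               class = "pdbia_validation_error")
  expect_error(device_params(cost_rounding = "banker"),
               class = "pdbia_config_error")
  expect_error(model_config(effectiveness_factor = 0),
               class = "pdbia_validation_error")
  expect_error(model_config(scenarios = character(0)),
               class = "pdbia_config_error")
  expect_error(
    country_cost_table("XX", "X", list(mild = stage_costs(1, 1)),
                       c(mild = 1, moderate = 1, advanced = 1)),
    class = "pdbia_schema_error"
  )
  expect_error(country_epidemiology("XX", hy_counts = c(I = 1, II = 2),
                                    total_text = 3),
               class = "pdbia_schema_error")
})

test_that("portfolio validation rejects corrupted structures", {
  p <- bundled_portfolio()

  dup <- p
  dup$countries <- c(p$countries, p$countries["ES"])
  expect_error(validate_portfolio(dup), "duplicate")

  neg <- p
  neg$countries$DE$costs$costs$moderate$direct_cost <- -5
  expect_error(validate_portfolio(neg), class = "pdbia_validation_error")

  mismatch <- p
  mismatch$countries$ES$epi$code <- "PT"
  expect_error(validate_portfolio(mismatch), "disagree")

  badsum <- p
  badsum$countries$DE$epi$hy_counts[["I"]] <- 1
  expect_error(validate_portfolio(badsum), "sum")
})

test_that("portfolios round-trip through disk losslessly", {
  dir_b <- withr::local_tempdir()
  p <- bundled_portfolio()
  write_portfolio(p, dir_b)
  expect_equal(load_portfolio(dir_b), p, tolerance = 1e-15)

  # synthetic portfolio with non-integer cascade rates
  dir_s <- withr::local_tempdir()
  ps <- generate_portfolio(synth_config(n_countries = 3, cascade_jitter = 0.1,
                                        seed = 42))
  write_portfolio(ps, dir_s)
  expect_equal(load_portfolio(dir_s), ps, tolerance = 1e-15)

  # 1 synthetic country -> exactly 3 cost rows
  dir_1 <- withr::local_tempdir()
  write_portfolio(generate_portfolio(synth_config(n_countries = 1, seed = 3)), dir_1)
  expect_identical(nrow(read.csv(file.path(dir_1, "costs.csv"))), 3L)
})

test_that("bundled token loads the built-in portfolio and bad paths error", {
  expect_equal(load_portfolio("bundled"), bundled_portfolio())
  expect_error(load_portfolio(file.path(tempdir(), "nope-missing")),
               class = "pdbia_io_error")
})

test_that("loading fails with a named schema error when a stage row is missing", {
  dir <- withr::local_tempdir()
  write_portfolio(bundled_portfolio(), dir)
  costs <- read.csv(file.path(dir, "costs.csv"))
  costs <- costs[!(costs$country == "DE" & costs$stage == "moderate"), ]
  write.csv(costs, file.path(dir, "costs.csv"), row.names = FALSE)
  err <- expect_error(load_portfolio(dir), class = "pdbia_schema_error")
  expect_match(conditionMessage(err), "DE")
  expect_match(conditionMessage(err), "moderate")
})

test_that("write_results emits equal CSV and JSON and guards preconditions", {
  res <- savings_table(bundled_portfolio())
  expect_identical(nrow(res), 10L)  # 5 countries x 2 scenarios
  f_csv <- withr::local_tempfile(fileext = ".csv")
  f_json <- withr::local_tempfile(fileext = ".json")
  write_results(res, f_csv, "csv")
  write_results(res, f_json, "json")
  from_csv <- read.csv(f_csv)
  from_json <- jsonlite::read_json(f_json, simplifyVector = TRUE)
  for (col in c("country", "scenario", "total_saving", "per_patient_saving")) {
    expect_equal(from_json[[col]], from_csv[[col]], label = col)
  }
  expect_error(write_results(res[0, ], f_csv, "csv"),
               class = "pdbia_precondition_error")
  expect_error(write_results(res, f_csv, "parquet"), class = "pdbia_config_error")
})
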