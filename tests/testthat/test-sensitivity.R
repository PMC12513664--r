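# One-way sweeps, tornado ranking, Monte-Carlo propagation, break-even.

test_that("one-way sweeps evaluate the model per grid point without side effects", {
  p <- bundled_portfolio()
  snapshot <- p

  zero <- one_way_sweep(p, "cascade.market_penetration", 0, "SE", "advanced_detected")
  expect_identical(zero$total_saving, 0)

  # linearity: totals at {0.1, 0.2, 0.4} sit in exact ratio 1:2:4
  sw <- one_way_sweep(p, "cascade.market_penetration", c(0.1, 0.2, 0.4),
                      "SE", "advanced_detected")
  expect_equal(sw$total_saving / sw$total_saving[1], c(1, 2, 4), tolerance = 1e-12)

  price <- one_way_sweep(p, "device.unit_price", c(2000, 2500, 3000),
                         "DE", "advanced_detected")
  expect_true(all(diff(price$total_saving) < 0))

  expect_error(one_way_sweep(p, "cascade.nonexistent", 0.1, "SE",
                             "advanced_detected"),
               class = "pdbia_config_error")
  expect_equal(p, snapshot)  # base portfolio untouched
})

test_that("tornado ranks parameter spans descending with lexicographic ties", {
  p <- bundled_portfolio()

  single <- tornado(p, list(param_range("device.unit_price", 2000, 3000, 2500)),
                    "DE", "advanced_detected")
  expect_identical(nrow(single), 1L)

  ranges <- list(
    param_range("cascade.market_penetration", 0.1, 0.3, 0.2),
    param_range("device.unit_price", 2000, 3000, 2500)
  )
  tor <- tornado(p, ranges, "DE", "advanced_detected")
  expect_identical(tor$parameter[1], "cascade.market_penetration")
  expect_true(all(diff(tor$span) <= 0))

  # degenerate range ranks last with span exactly 0
  with_deg <- tornado(p, c(ranges, list(
    param_range("cascade.detection_sensitivity", 0.9, 0.9, 0.9))),
    "DE", "advanced_detected")
  expect_identical(with_deg$parameter[nrow(with_deg)],
                   "cascade.detection_sensitivity")
  expect_identical(with_deg$span[nrow(with_deg)], 0)

  # zero-span ties break lexicographically by parameter path
  tied <- tornado(p, list(
    param_range("device.unit_price", 2500, 2500, 2500),
    param_range("cascade.detection_sensitivity", 0.9, 0.9, 0.9)),
    "SE", "moderate_detected")
  expect_identical(tied$parameter,
                   c("cascade.detection_sensitivity", "device.unit_price"))

  expect_error(tornado(p, list(), "DE", "advanced_detected"),
               class = "pdbia_precondition_error")
})

test_that("tornado span of a linear parameter equals |slope| * width", {
  p <- bundled_portfolio()
  tor <- tornado(p, list(param_range("cascade.market_penetration", 0.1, 0.3, 0.2)),
                 "DE", "advanced_detected")
  per_unit <- pdbia:::evaluate_total_saving(
    set_param(p, "cascade.market_penetration", 1), "DE", "advanced_detected")
  expect_equal(tor$span, per_unit * (0.3 - 0.1), tolerance = 1e-12)
})

test_that("Monte-Carlo point masses collapse to the deterministic total", {
  p <- bundled_portfolio()
  spec <- mc_spec(list(
    "cascade.market_penetration" = dist_point(0.2),
    "device.unit_price" = dist_point(2500)
  ), n_draws = 50, seed = 9)
  mc <- monte_carlo(p, spec, "SE", "advanced_detected", keep_draws = TRUE)
  det <- pdbia:::evaluate_total_saving(p, "SE", "advanced_detected")
  expect_identical(unique(mc$draws), det)
  expect_identical(mc$sd, 0)
  expect_identical(mc$mean, det)
})

test_that("Monte-Carlo is seed-reproducible and respects parameter domains", {
  p <- bundled_portfolio()
  spec <- mc_spec(list("cascade.market_penetration" = dist_uniform(0.1, 0.3)),
                  n_draws = 200, seed = 123)
  a <- monte_carlo(p, spec, "DE", "advanced_detected")
  b <- monte_carlo(p, spec, "DE", "advanced_detected")
  expect_identical(a, b)

  bad <- mc_spec(list("cascade.market_penetration" = dist_uniform(0.5, 1.5)),
                 n_draws = 10, seed = 1)
  expect_error(monte_carlo(p, bad, "DE", "advanced_detected"),
               class = "pdbia_validation_error")
})

test_that("uniform penetration Monte-Carlo mean matches the midpoint model", {
  p <- bundled_portfolio()
  spec <- mc_spec(list("cascade.market_penetration" = dist_uniform(0.1, 0.3)),
                  n_draws = 10000, seed = 2024)
  mc <- monte_carlo(p, spec, "DE", "advanced_detected")
  det <- pdbia:::evaluate_total_saving(p, "DE", "advanced_detected")  # at 0.2
  se <- mc$sd / sqrt(mc$n_draws)
  expect_lt(abs(mc$mean - det), 3 * se)
})

test_that("triangular draws stay inside their support", {
  d <- dist_triangular(0.1, 0.2, 0.3)
  set.seed(4)
  x <- pdbia:::sample_dist(d, 5000)
  expect_true(all(x >= 0.1 & x <= 0.3))
  expect_equal(mean(x), (0.1 + 0.2 + 0.3) / 3, tolerance = 0.01)
})

test_that("break-even device cost inverts the savings equation", {
  p <- bundled_portfolio()
  expect_identical(break_even_device_cost(p$countries$SE$costs,
                                          "moderate_detected", 1.0),
                   4953 - 1509)  # 3444
  expect_identical(break_even_device_cost(p$countries$DE$costs,
                                          "advanced_detected", 1.0),
                   44901 - 10976)  # 33925
  flat <- country_cost_table("FL", "Flat",
                             list(mild = stage_costs(9, 2),
                                  moderate = stage_costs(9, 2),
                                  advanced = stage_costs(9, 2)),
                             c(mild = 0, moderate = 0, advanced = 0))
  expect_identical(break_even_device_cost(flat, "moderate_detected", 0.8), 0)
})

test_that("saving at the break-even cost is exactly zero (property)", {
  cfg <- synth_config(n_countries = 20, seed = 31)
  for (i in 1:20) {
    ct <- generate_country(cfg, i)
    for (sc in c("moderate_detected", "advanced_detected")) {
      for (f in c(0.8, 1.0)) {
        be <- break_even_device_cost(ct$costs, sc, f)
        expect_identical(per_patient_saving(ct$costs, sc, f, be), 0)
      }
    }
  }
})
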