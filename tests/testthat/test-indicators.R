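test_that("single-timestep indicators match their defining ratios and sums", {
  p <- compute_indicator_panel(tiny_record(), default_scores())
  expect_equal(unname(p["ROS"]), 0.2)                    # 20 / 100
  expect_equal(unname(p["Procedural Complexity"]), 0.8)  # 8 / 10
  expect_equal(unname(p["Technological Efficiency"]), 8)
  expect_equal(unname(p["Clinical Efficiency"]), 6 + 1 - 1)
  expect_equal(unname(p["Effectiveness"]), 0.7)
  expect_equal(unname(p["Side Effects"]), 0 + 1)
  expect_equal(unname(p["Human Resources"]), 3)
  expect_equal(unname(p["Technological Safety"]), 40)    # five 8s
  expect_equal(unname(p["Respect for legal issues"]), 12)
  expect_equal(unname(p["Respect for ethical principles"]), 1)
  expect_equal(unname(p["Investments"]), 0.2)            # 1e4 / 5e4
  # zero denominators are named errors
  expect_error(
    compute_indicator_panel(tiny_record(net_revenues = 0), default_scores()),
    "ROS")
  expect_error(
    compute_indicator_panel(tiny_record(incoming_requests = 0),
                            default_scores()),
    "effectiveness")
})

test_that("window indicators equal a naive loop accumulation", {
  sc <- paper_scenario()
  ts <- generate_timesteps(sc, T = 50, seed = 21)
  d <- ts[ts$alternative == "Biosensor LOF", ]
  p <- compute_indicator_panel(d[, setdiff(names(d), "alternative")],
                               default_scores())
  # brute-force accumulation over rows
  acc <- c(executed = 0, faults = 0, profit = 0, mon = 0, rev = 0,
           eff = 0, inc = 0, refused = 0, side = 0, err = 0)
  for (i in seq_len(nrow(d))) {
    acc["executed"] <- acc["executed"] + d$executed_exams[i]
    acc["faults"] <- acc["faults"] + d$queued_exams_for_faults[i]
    acc["profit"] <- acc["profit"] + d$net_profit[i]
    acc["mon"] <- acc["mon"] + d$mon[i]
    acc["rev"] <- acc["rev"] + d$net_revenues[i]
    acc["eff"] <- acc["eff"] + d$effective_tests[i]
    acc["inc"] <- acc["inc"] + d$incoming_requests[i]
    acc["refused"] <- acc["refused"] + d$refused_exams_surgeon[i] +
      d$refused_exams_patient[i]
    acc["side"] <- acc["side"] + d$exams_with_side_effects[i] +
      d$effective_exams_with_error[i]
  }
  expect_equal(unname(p["Technological Efficiency"]), unname(acc["executed"]))
  expect_equal(unname(p["Reliability"]), unname(acc["faults"]))
  expect_equal(unname(p["Usefulness"]), unname(acc["profit"]))
  expect_equal(unname(p["ROS"]), unname(acc["mon"] / acc["rev"]))
  expect_equal(unname(p["Effectiveness"]), unname(acc["eff"] / acc["inc"]))
  expect_equal(unname(p["Respect for ethical principles"]),
               unname(acc["refused"]))
  expect_equal(unname(p["Side Effects"]), unname(acc["side"]))
  expect_equal(unname(p["Respect for social aspects"]),
               unname(acc["executed"]))
})

test_that("indicators are monotone in their stated direction", {
  base <- compute_indicator_panel(tiny_record(), default_scores())
  more_exec <- compute_indicator_panel(tiny_record(executed_exams = 9),
                                       default_scores())
  expect_gt(more_exec[["Technological Efficiency"]],
            base[["Technological Efficiency"]])
  more_faults <- compute_indicator_panel(
    tiny_record(queued_exams_for_faults = 2), default_scores())
  expect_gt(more_faults[["Reliability"]], base[["Reliability"]])
  orient <- attr(base, "orientation")
  expect_equal(unname(orient["Reliability"]), "cost")
  expect_equal(unname(orient["Effectiveness"]), "benefit")
})

test_that("local_alternative_weights normalizes by orientation", {
  expect_equal(local_alternative_weights(c(2, 3, 5), "benefit"),
               c(0.2, 0.3, 0.5))
  expect_equal(local_alternative_weights(c(1, 1, 1), "cost"), rep(1 / 3, 3))
  # inversion duality: benefit weights of v equal cost weights of 1/v
  set.seed(13)
  for (i in 1:50) {
    v <- runif(3, 0.05, 10)
    expect_equal(local_alternative_weights(v, "benefit"),
                 local_alternative_weights(1 / v, "cost"), tolerance = 1e-9)
    w <- local_alternative_weights(v, "cost")
    expect_equal(sum(w), 1, tolerance = 1e-12)
    # cost weights order opposite to values
    expect_equal(order(w), rev(order(v)))
  }
  expect_error(local_alternative_weights(c(0, 0), "benefit"), "degenerate")
  expect_error(local_alternative_weights(5, "benefit"), "two alternatives")
})

test_that("indicator_local_weights builds unit-sum rows across alternatives", {
  sc <- paper_scenario()
  ts <- generate_timesteps(sc, T = 30, seed = 4)
  panels <- sapply(sc$hierarchy$alternatives, function(alt) {
    compute_indicator_panel(ts[ts$alternative == alt, ], default_scores())
  }, simplify = FALSE)
  lw <- indicator_local_weights(panels)
  expect_equal(dim(lw), c(14, 3))
  expect_equal(unname(rowSums(lw)), rep(1, 14), tolerance = 1e-12)
  expect_true(all(lw >= 0))
})
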