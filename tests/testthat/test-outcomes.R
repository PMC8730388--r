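test_that("discount factors match the closed form", {
  expect_equal(discount_factor(0, 0.035), 1)
  expect_equal(discount_factor(1, 0.035), 1 / 1.035)
  expect_equal(discount_factor(20, 0.035), 1.035^-20)
  expect_equal(discount_factor(1, 0.035), 0.966184, tolerance = 1e-6)
  expect_equal(discount_factor(20, 0.035), 0.502566, tolerance = 1e-6)
  expect_error(discount_factor(-1, 0.035), "non-negative")
})

test_that("annual accrual charges the published unit costs and stage utility", {
  p <- fx_params()
  st <- mini_population(4, gfr = c(95, 95, 95, 50))
  st$on_rrt[1] <- TRUE
  st$tested_this_cycle[2] <- TRUE
  st$acei_from_test[3] <- TRUE
  out <- accrue_year(st, p, cycle = 0)
  expect_equal(out$cost_rrt_undisc, c(63000, 0, 0, 0))
  expect_equal(out$cost_test_undisc, c(0, 36.18, 0, 0))
  expect_equal(out$cost_med_undisc, c(0, 0, 15 * 365.25 / 100, 0))
  expect_equal(out$cost_med_undisc[3], 54.7875)
  u <- p$utilities
  expect_equal(out$qaly_undisc,
               u$utility[match(ckd_stage(st$gfr), u$stage)])
  # cycle 0 is undiscounted; later cycles scale by the discount factor
  expect_equal(out$cost_rrt_disc, out$cost_rrt_undisc)
  out1 <- accrue_year(st, p, cycle = 1)
  expect_equal(out1$cost_rrt_disc, out1$cost_rrt_undisc / 1.035)
  expect_equal(out1$qaly_disc, out1$qaly_undisc / 1.035)
  # the dead accrue nothing
  st$alive <- FALSE
  gone <- accrue_year(st, p, cycle = 0)
  expect_true(all(gone$qaly_undisc == 0 & gone$cost_rrt_undisc == 0))
})

test_that("scenario summaries match hand arithmetic on a tiny ledger", {
  p <- fx_params()
  st <- mini_population(3)
  st$age_at_rrt <- c(70, NA, NA)
  st$age_at_death <- c(75, 80, NA) # third censored at the cap
  st$qaly_undisc <- c(20, 25, 30)
  st$qaly_disc <- c(12, 14, 16)
  st$cost_rrt_undisc <- c(126000, 0, 0)
  st$cost_test_undisc <- c(36.18, 72.36, 0)
  s <- summarize_scenario(st, p, "toy")
  val <- function(q) s$mean[s$quantity == q]
  expect_equal(val("rrt_lifetime_prevalence_pct"), 100 / 3)
  expect_equal(val("mean_age_at_rrt"), 70)
  expect_equal(val("mean_age_at_death"), 77.5)
  expect_equal(val("censored_at_cap_pct"), 100 / 3)
  expect_equal(val("qaly_per_individual_undisc"), 25)
  expect_equal(val("cost_rrt_per_individual_undisc"), 42000)
  expect_equal(val("cost_test_per_individual_undisc"), (36.18 + 72.36) / 3)
  expect_error(summarize_scenario(st[0, ], p), "empty")
})

test_that("incremental ratios follow the published cost formulas", {
  mk <- function(name, qu, qd, test, med, rrt) {
    q <- c("qaly_per_individual_undisc", "qaly_per_individual_disc",
           "cost_test_per_individual_undisc", "cost_test_per_individual_disc",
           "cost_med_per_individual_undisc", "cost_med_per_individual_disc",
           "cost_rrt_per_individual_undisc", "cost_rrt_per_individual_disc")
    data.frame(scenario = name, quantity = q,
               mean = c(qu, qd, test, test, med, med, rrt, rrt),
               low = NA, high = NA)
  }
  base <- mk("base", 30.0, 16.0, 0, 0, 1000)
  alt <- mk("alt", 30.057, 16.057, 35, 32, 1000 - 654)
  inc <- compare_scenarios(base, alt)
  u <- inc[inc$stream == "undisc", ]
  expect_equal(u$qaly_gained, 0.057)
  expect_equal(u$cost_per_qaly, (35 + 32) / 0.057, tolerance = 1e-10)
  expect_equal(u$cost_per_qaly, 1175.44, tolerance = 1e-5)
  expect_equal(u$net_cost_per_qaly, (35 + 32 - 654) / 0.057, tolerance = 1e-10)
  expect_equal(u$net_cost_per_qaly, -10298.25, tolerance = 1e-6)

  # no QALY gain: ratios are undefined, flagged, never numeric
  tie <- compare_scenarios(base, mk("tie", 30.0, 16.0, 35, 32, 1000))
  expect_true(all(is.na(tie$cost_per_qaly)))
  expect_false(any(tie$ratio_defined))
  expect_equal(tie$qaly_gained, c(0, 0))
})

test_that("confidence intervals are Wald with the right width and coverage", {
  expect_equal(confidence_interval(rep(5, 10)),
               c(mean = 5, low = 5, high = 5))
  x <- c(rep(1, 50), rep(0, 50))
  ci <- confidence_interval(x)
  half <- qnorm(0.975) * sd(x) / 10
  expect_equal(unname(ci), c(0.5, 0.5 - half, 0.5 + half))
  expect_equal(unname(ci["high"] - ci["low"]), 2 * 1.96 * 0.05, tolerance = 0.01)
  expect_error(confidence_interval(3), "at least 2")

  set.seed(4)
  cover <- replicate(2000, {
    v <- rnorm(50, mean = 1)
    ci <- confidence_interval(v)
    ci["low"] <= 1 && 1 <= ci["high"]
  })
  expect_gt(mean(cover), 0.92)
  expect_lt(mean(cover), 0.975)
})

test_that("cea_table needs a base arm and stacks the comparisons", {
  p <- fx_params()
  st <- mini_population(3)
  s <- summarize_scenario(st, p, "alt")
  expect_error(cea_table(list(alt = s)), "base")
})
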