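test_that("eligibility follows the scenario rule, exclusions and interval", {
  p <- fx_params()
  st <- mini_population(7)
  st$diabetes <- c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  st$hypertensive <- c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  st$ht_drug <- c("none", "none", "none", "ARB", "none", "none", "none")
  st$on_raas_blocker <- st$ht_drug %in% c("ACEI", "ARB")
  st$tested_positive[5] <- TRUE
  st$on_rrt[6] <- TRUE
  st$alive[7] <- FALSE

  dia <- ckd_scenario("d", "diabetes")
  expect_equal(select_eligible(st, dia, 0, p),
               c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  both <- ckd_scenario("dh", "diabetes-or-hypertension")
  expect_equal(select_eligible(st, both, 0, p),
               c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  all_s <- ckd_scenario("a", "all")
  expect_equal(select_eligible(st, all_s, 0, p),
               c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  # off-interval year: nobody is tested
  expect_false(any(select_eligible(st, all_s, 1, p)))
  expect_true(any(select_eligible(st, all_s, 2, p)))
  # base case never tests
  expect_false(any(select_eligible(st, ckd_scenario("b", "none"), 0, p)))
})

test_that("eligibility is nested across the three testing scenarios", {
  p <- fx_params()
  st <- fx_population(3000, seed = 15)
  m1 <- select_eligible(st, ckd_scenario("d", "diabetes"), 0, p)
  m2 <- select_eligible(st, ckd_scenario("dh", "diabetes-or-hypertension"), 0, p)
  m3 <- select_eligible(st, ckd_scenario("a", "all"), 0, p)
  expect_true(all(m2[m1]))
  expect_true(all(m3[m2]))
  expect_gt(sum(m3), sum(m2))
})

test_that("the two-repeat cascade hits the exact binomial rates", {
  p <- fx_params()
  n <- 40000
  st <- mini_population(n, alb = 1L)
  mask <- rep(TRUE, n)
  out <- perform_test(st, mask, p, cycle = 0, seed = 19)
  p_tp <- dbinom(2, 2, p$test_sensitivity) # 0.7569
  expect_lt(abs(mean(out$positive) - p_tp), 3 * sqrt(p_tp * (1 - p_tp) / n))

  st0 <- mini_population(n, alb = 0L)
  out0 <- perform_test(st0, mask, p, cycle = 0, seed = 19)
  p_fp <- dbinom(2, 2, 1 - p$test_specificity) # 0.0144
  expect_lt(abs(mean(out0$positive) - p_fp), 3 * sqrt(p_fp * (1 - p_fp) / n))

  # untested individuals: no result, no cost
  none <- perform_test(st, rep(FALSE, n), p, 0, 19)
  expect_false(any(none$tested) || any(none$positive))
  expect_true(all(none$cost == 0))
  expect_true(all(out$cost[out$tested] == p$cost_test))
})

test_that("positives start sticky therapy with adherence drawn once", {
  p <- fx_params()
  n <- 20000
  st <- mini_population(n, alb = 2L)
  out <- perform_test(st, rep(TRUE, n), p, 0, 23)
  st2 <- apply_positive_result(st, out, p, 0, 23)
  pos <- st2$tested_positive
  expect_equal(pos, out$positive)
  expect_true(all(st2$acei_from_test[pos] & st2$on_raas_blocker[pos]))
  expect_false(any(st2$false_positive)) # all truly albuminuric here
  adh <- mean(st2$adherent[pos])
  expect_lt(abs(adh - p$adherence_prob), 3 * sqrt(0.91 * 0.09 / sum(pos)))

  stfp <- mini_population(n, alb = 0L)
  outfp <- perform_test(stfp, rep(TRUE, n), p, 0, 23)
  st3 <- apply_positive_result(stfp, outfp, p, 0, 23)
  expect_true(all(st3$false_positive[st3$tested_positive]))
})

test_that("clinical effects require adherence for test therapy but not for
           hypertension therapy", {
  p <- fx_params()
  p$effect_acei_rr_progression <- 0 # treated micro never progresses
  p$albuminuria_progression$prob <- 0.5
  p$albuminuria_incidence$prob <- 0
  n <- 3000
  st <- mini_population(n, alb = 1L)
  grp <- rep(1:3, length.out = n)
  st$acei_from_test <- grp != 3
  st$adherent <- grp == 1
  st$ht_drug[grp == 3] <- "ACEI" # hypertension therapy, never adherence-gated
  out <- update_albuminuria(st, p, cycle = 0, seed = 29)
  expect_true(all(out$albuminuria[grp == 1] == 1L)) # adherent: protected
  expect_true(all(out$albuminuria[grp == 3] == 1L)) # ht-ACEI: protected
  prog <- mean(out$albuminuria[grp == 2] == 2L)     # non-adherent: base rate
  expect_lt(abs(prog - 0.5), 3 * sqrt(0.25 / (n / 3)))
})

test_that("a dead test cascade leaves every arm at the base-case outcome", {
  p <- fx_params()
  p$test_sensitivity <- 0
  p$test_specificity <- 1
  prof <- fx_profile()
  init <- init_population(800, p, prof, seed = 33)
  scen <- default_scenarios()
  run_arm <- function(s) {
    st <- init
    for (t in 0:14) st <- advance_year(st, p, s, cycle = t, seed = 33)
    st
  }
  base <- run_arm(scen$base)
  all_arm <- run_arm(scen$all)
  for (col in c("age", "alive", "gfr", "albuminuria", "diabetes", "on_rrt",
                "age_at_death", "qaly_undisc", "cost_rrt_undisc"))
    expect_identical(base[[col]], all_arm[[col]])
  expect_gt(sum(all_arm$cost_test_undisc), 0) # tests still happen and cost
  expect_equal(sum(base$cost_test_undisc), 0)
})
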