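test_that("age/sex sampling reproduces the population table", {
  p <- fx_params()
  pop <- sample_age_sex(2e5, p, seed = 9)
  tab <- p$population_age_sex
  sim <- table(factor(paste(pop$age, pop$sex),
                      levels = paste(tab$age, tab$sex))) / nrow(pop)
  band <- 3 * sqrt(tab$share * (1 - tab$share) / nrow(pop))
  inside <- abs(as.numeric(sim) - tab$share) <= band
  expect_gte(mean(inside), 0.97) # 3-sigma bound holds for ~99.7% of cells

  one <- sample_age_sex(1, p, seed = 2)
  expect_true(one$age %in% 18:90 && one$sex %in% c("F", "M"))

  degen <- p
  degen$population_age_sex$share <-
    as.numeric(degen$population_age_sex$age == 40 &
                 degen$population_age_sex$sex == "F")
  all40 <- sample_age_sex(200, degen, seed = 3)
  expect_true(all(all40$age == 40) && all(all40$sex == "F"))
})

test_that("BMI is the LMS value of a lifelong SDS that tracks its percentile", {
  p <- fx_params()
  pop <- fx_population(20000)
  lms <- ckdscreen:::lms_at(p$bmi_lms_full, pop$age, pop$sex)
  expect_equal(pop$bmi, lms_value(lms$L, lms$M, lms$S, pop$bmi_sds))
  # SDS draws are standard normal (CLT bound, truncation negligible)
  expect_lt(abs(mean(pop$bmi_sds)), 0.03)

  aged <- update_anthropometrics(pop, p, cycle = 0, seed = 42)
  moved <- aged$alive & !aged$censored
  expect_equal(aged$bmi_sds, pop$bmi_sds) # percentile kept for life
  lms2 <- ckdscreen:::lms_at(p$bmi_lms_full, aged$age, aged$sex)
  expect_equal(aged$bmi[moved],
               lms_value(lms2$L[moved], lms2$M[moved], lms2$S[moved],
                         aged$bmi_sds[moved]))
  expect_equal(aged$age[moved], pop$age[moved] + 1L)
})

test_that("SBP elevation above the reference BMI shifts the definitive SDS", {
  p0 <- fx_params()
  # no elevation: definitive SDS equals the (mean-shifted) draw
  p_flat <- p0; p_flat$sbp_bmi_slope <- 0; p_flat$sbp_mu_adjust <- 0
  st <- sample_age_sex(5000, p_flat, seed = 5)
  st <- assign_bmi(st, p_flat, 5)
  flat <- assign_sbp(st, p_flat, 5)
  z <- ckdscreen:::.trunc_z(ckdscreen:::stream_norm(5000, 5, "sbp"))
  expect_equal(flat$sbp_sds, z, tolerance = 1e-8)

  p_steep <- p_flat; p_steep$sbp_bmi_slope <- 1.5
  steep <- assign_sbp(st, p_steep, 5)
  above <- st$bmi > p_steep$sbp_bmi_ref
  expect_true(all(steep$sbp_sds[above] > flat$sbp_sds[above]))
  expect_equal(steep$sbp[!above], flat$sbp[!above]) # no elevation below ref
})

test_that("hypertension uses a strict 140 mmHg threshold and a once-only drug", {
  p <- fx_params()
  st <- mini_population(4)
  st$sbp <- c(141, 140, 139.9, 180)
  st <- assign_hypertension_therapy(st, p, seed = 8)
  expect_equal(st$hypertensive, c(TRUE, FALSE, FALSE, TRUE))
  expect_true(all(st$ht_drug[!st$hypertensive] == "none"))
  # diabetes without hypertension never yields a renin-angiotensin blocker
  pop <- fx_population()
  expect_false(any(pop$on_raas_blocker[!pop$hypertensive]))
})

test_that("prevalent diabetes reproduces the marginal when relative risks are 1", {
  p <- fx_params()
  p$rr_diabetes_obesity <- 1
  p$rr_diabetes_hypertension <- 1
  st <- sample_age_sex(50000, p, seed = 6)
  st <- assign_bmi(st, p, 6); st <- assign_sbp(st, p, 6)
  st <- assign_hypertension_therapy(st, p, 6)
  st <- assign_diabetes_prevalent(st, p, 6)
  marg <- ckdscreen:::age_sex_lookup(p$diabetes_prevalence, "prob", st$age, st$sex)
  expect_lt(abs(mean(st$diabetes) - mean(marg)),
            3 * sqrt(mean(marg) / nrow(st)))

  p0 <- fx_params()
  p0$diabetes_prevalence$prob <- 0
  st0 <- assign_diabetes_prevalent(st, p0, 6)
  expect_false(any(st0$diabetes))
})

test_that("renal age profiles copy age 30 down to 18 and stay consistent", {
  prof <- fx_profile()
  base <- prof[prof$age == 30, c("gfr_mean", "gfr_sd", "p_micro", "p_macro")]
  for (a in 18:29) {
    young <- prof[prof$age == a, c("gfr_mean", "gfr_sd", "p_micro", "p_macro")]
    expect_equal(unname(as.matrix(young)), unname(as.matrix(base)))
  }
  expect_true(all(prof$gfr_mean > 0, na.rm = TRUE))
  # GFR declines with attained age in the pre-simulated cohort
  for (sx in c("F", "M")) {
    g <- prof$gfr_mean[prof$sex == sx & prof$age %in% c(30, 50, 70)]
    expect_true(all(diff(g) < 0))
  }
})

test_that("albuminuria burden accumulates with age absent mortality", {
  p <- fx_params()
  prof <- derive_renal_age_profiles(p, 4000, seed = 11, mortality = FALSE)
  for (sx in c("F", "M")) {
    tot <- with(prof[prof$sex == sx & prof$age %in% seq(30, 60, 5), ],
                p_micro + p_macro)
    expect_true(all(diff(tot) > -0.01)) # non-decreasing up to RRT-exit noise
  }
})

test_that("renal initialisation honours the profile and the 0.75 loss scale", {
  p <- fx_params()
  prof <- data.frame(age = 40, sex = c("F", "M"), gfr_mean = 100, gfr_sd = 10,
                     p_micro = 0.2, p_macro = 0.1, n = 1)
  st <- mini_population(20000, age = 40)
  st$sex <- rep(c("F", "M"), length.out = 20000)
  p_det <- p; p_det$gfr_loss_factor_sdlog <- 0
  st2 <- initialize_renal_state(st, prof, p_det, seed = 13)
  expect_equal(unique(st2$gfr_loss_factor), 0.75)
  p_det$gfr_loss_calibration_scale <- 1
  expect_equal(unique(initialize_renal_state(st, prof, p_det, 13)$gfr_loss_factor), 1)
  # drawn GFR matches the profile distribution and respects the RRT floor
  expect_gt(min(st2$gfr), p$gfr_rrt)
  expect_lt(abs(mean(st2$gfr) - 100), 0.3)
  expect_lt(abs(sd(st2$gfr) - 10), 0.3)
  expect_lt(abs(mean(st2$albuminuria == 1L) - 0.2), 0.01)
  expect_lt(abs(mean(st2$albuminuria == 2L) - 0.1), 0.01)
  expect_error(initialize_renal_state(mini_population(2, age = 80), prof, p, 1),
               "cover")
})

test_that("the same seed yields a bit-identical initial population", {
  p <- fx_params(); prof <- fx_profile()
  a <- init_population(1000, p, prof, seed = 99)
  b <- init_population(1000, p, prof, seed = 99)
  expect_identical(a, b)
  c <- init_population(1000, p, prof, seed = 100)
  expect_false(identical(a, c))
})
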