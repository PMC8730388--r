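#' Calibrate the SBP mean shift
#'
#' The BMI-dependent elevation shifts the simulated SBP distribution to the
#' right of its reference. This hook finds the mean \code{mu} of the SDS
#' draw such that the median of the post-elevation SBP distribution matches
#' the reference median (the SBP at SDS 0 for each individual's age and
#' sex), by bisection on a fixed set of draws; tolerance 0.1 mmHg.
#'
#' @param p prepared \code{ckd_parameters}.
#' @param n sample size for the calibration population (>= 1e4 recommended).
#' @param seed master seed.
#' @param tol tolerance on the median difference, mmHg.
#' @param max_iter maximum bisection iterations.
#' @return calibrated \code{mu} (store in \code{p$sbp_mu_adjust}).
#' @export
calibrate_sbp_mean <- function(p, n = 2e4, seed = 1L, tol = 0.1,
                               max_iter = 100L) {
  p <- prepare_parameters(p)
  state <- sample_age_sex(n, p, seed)
  state <- assign_bmi(state, p, seed)
  z0 <- .trunc_z(stream_norm(n, seed, "sbp"))
  lms <- lms_at(p$sbp_lms, state$age, state$sex)
  elev <- p$sbp_bmi_slope * pmax(0, state$bmi - p$sbp_bmi_ref)
  target <- stats::median(lms_value(lms$L, lms$M, lms$S, z0))
  med_diff <- function(mu)
    stats::median(lms_value(lms$L, lms$M, lms$S, z0 + mu) + elev) - target
  lo <- -4; hi <- 1
  flo <- med_diff(lo); fhi <- med_diff(hi)
  if (flo > 0 || fhi < 0)
    stop("bisection bracket does not contain the root: f(", lo, ") = ",
         signif(flo, 4), ", f(", hi, ") = ", signif(fhi, 4))
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- med_diff(mid)
    if (abs(fm) < tol) return(mid)
    if (fm > 0) hi <- mid else lo <- mid
  }
  stop("SBP mean calibration did not converge in ", max_iter,
       " iterations; bracket [", signif(lo, 6), ", ", signif(hi, 6), "]")
}

#' Calibrate the baseline mortality factor
#'
#' Finds the scalar multiplying the life-table probabilities such that the
#' simulated all-ages annual death rate in a base-case run matches the
#' life-table expectation on the same person-years, by iterative
#' proportional fitting (<= \code{max_iter} iterations, relative tolerance
#' \code{tol}). With all CKD mortality relative risks at 1 the factor is 1
#' up to Monte-Carlo error.
#'
#' @param p \code{ckd_parameters}.
#' @param n cohort size per iteration.
#' @param seed master seed.
#' @param profile optional pre-computed renal age profile.
#' @param tol relative tolerance on the death-rate ratio.
#' @param max_iter maximum iterations.
#' @return calibrated factor (store in \code{p$mortality_calibration_factor}).
#' @export
calibrate_mortality_factor <- function(p, n = 2e4, seed = 1L, profile = NULL,
                                       tol = 0.01, max_iter = 20L) {
  p <- prepare_parameters(p)
  if (is.null(profile)) profile <- derive_renal_age_profiles(p, n, seed)
  base <- ckd_scenario("base", "none")
  rate <- function(pp) {
    state <- init_population(n, pp, profile, seed)
    deaths <- 0; expected <- 0; py <- 0
    n_cycles <- pp$age_cap - min(state$age)
    for (t in seq_len(n_cycles) - 1L) {
      act_before <- state$alive & !state$censored
      if (!any(act_before)) break
      state <- advance_year(state, pp, base, cycle = t, seed = seed,
                            accrue = FALSE)
      died <- act_before & !state$alive
      q <- age_sex_lookup(pp$life_table, "qx",
                          pmin(state$age, max(pp$life_table$age)), state$sex)
      deaths <- deaths + sum(died)
      expected <- expected + sum(q[act_before])
      py <- py + sum(act_before)
    }
    c(observed = deaths / py, expected = expected / py)
  }
  f <- p$mortality_calibration_factor
  for (i in seq_len(max_iter)) {
    p$mortality_calibration_factor <- f
    r <- rate(p)
    ratio <- r[["observed"]] / r[["expected"]]
    if (abs(ratio - 1) < tol) return(f)
    f <- f / ratio
  }
  stop("mortality calibration did not converge in ", max_iter, " iterations")
}

#' One-way sensitivity sweep
#'
#' Reruns the base case with one input scaled multiplicatively over a grid
#' of multipliers (0.80 to 1.20 in steps of 0.05 by default), under a common
#' seed, and records per cell the lifetime RRT cost per individual and the
#' lifetime RRT prevalence. Multipliers act on table values: the BMI and SBP
#' reference medians, the diabetes prevalence and incidence probabilities,
#' the albuminuria incidence, or the annual GFR loss.
#'
#' @param p \code{ckd_parameters}.
#' @param parameters subset of \code{c("bmi", "sbp", "diabetes_prev_inc",
#'   "albuminuria_incidence", "gfr_loss")}.
#' @param n cohort size per cell.
#' @param seed master seed (shared across cells).
#' @param multipliers multiplier grid.
#' @param profile_cohort_size size of the age-30 pre-simulation cohort
#'   (profiles are re-derived per cell since the perturbation feeds them).
#' @return data.frame with one row per parameter x multiplier.
#' @export
run_sensitivity_sweep <- function(p,
                                  parameters = c("bmi", "sbp",
                                                 "diabetes_prev_inc",
                                                 "albuminuria_incidence",
                                                 "gfr_loss"),
                                  n = 1e4, seed = 1L,
                                  multipliers = seq(0.80, 1.20, by = 0.05),
                                  profile_cohort_size = n) {
  parameters <- match.arg(parameters, several.ok = TRUE)
  perturb <- function(p, param, m) {
    switch(param,
      bmi = { p$bmi_lms$M <- p$bmi_lms$M * m; p },
      sbp = {
        pc <- grep("^P", names(p$sbp_percentiles), value = TRUE)
        p$sbp_percentiles[pc] <- p$sbp_percentiles[pc] * m
        p
      },
      diabetes_prev_inc = {
        p$diabetes_prevalence$prob <- pmin(p$diabetes_prevalence$prob * m, 1)
        p$diabetes_incidence$prob <- pmin(p$diabetes_incidence$prob * m, 1)
        p
      },
      albuminuria_incidence = {
        p$albuminuria_incidence$prob <- pmin(p$albuminuria_incidence$prob * m, 1)
        p
      },
      gfr_loss = { p$gfr_annual_loss$loss <- p$gfr_annual_loss$loss * m; p }
    )
  }
  rows <- list()
  for (param in parameters) {
    for (m in multipliers) {
      pm <- perturb(p, param, m)
      attr(pm, "prepared") <- NULL
      pm$bmi_lms_full <- NULL; pm$sbp_lms <- NULL
      run <- run_simulation(pm, n_individuals = n, seed = seed,
                            scenarios = list(base = ckd_scenario("base", "none")),
                            profile_cohort_size = profile_cohort_size)
      s <- run$summaries$base
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = param, multiplier = m,
        rrt_cost_per_individual = .summary_value(s, "cost_rrt_per_individual_undisc"),
        rrt_lifetime_prevalence_pct = .summary_value(s, "rrt_lifetime_prevalence_pct"),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validation report: simulated marginals vs input tables
#'
#' Compares the base-case population's marginals with the tables the model
#' was built from: sex shares, age distribution, BMI and SBP percentile
#' agreement against the references, diabetes prevalence by age band, annual
#' mortality vs the life table, albuminuria prevalence by age band, RRT
#' lifetime prevalence, and mean years in CKD stages 3a-5. Sampling-error
#' bands are 3 standard errors.
#'
#' @param state final base-case \code{ckd_population} (from a run with
#'   \code{keep_states = TRUE}) or an initial population for
#'   initialisation-only checks.
#' @param init the initial population of the same run.
#' @param p prepared \code{ckd_parameters}.
#' @return data.frame with columns \code{quantity}, \code{group},
#'   \code{simulated}, \code{reference}, \code{se_band}.
#' @export
validation_report <- function(state, init, p) {
  if (nrow(init) == 0) stop("empty population")
  p <- prepare_parameters(p)
  rows <- list()
  add <- function(quantity, group, simulated, reference, se_band) {
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, group = as.character(group),
      simulated = simulated, reference = reference, se_band = se_band,
      stringsAsFactors = FALSE)
  }
  n <- nrow(init)
  # sex shares
  ref_sex <- tapply(p$population_age_sex$share, p$population_age_sex$sex, sum)
  for (sx in names(ref_sex)) {
    pr <- ref_sex[[sx]]
    add("sex_share", sx, mean(init$sex == sx), pr, 3 * sqrt(pr * (1 - pr) / n))
  }
  # age bands
  breaks <- c(18, 30, 45, 60, 75, 91)
  ref_age <- tapply(p$population_age_sex$share,
                    cut(p$population_age_sex$age, breaks, right = FALSE), sum)
  sim_age <- table(cut(init$age, breaks, right = FALSE)) / n
  for (b in names(ref_age))
    add("age_share", b, as.numeric(sim_age[b]), ref_age[[b]],
        3 * sqrt(ref_age[[b]] * (1 - ref_age[[b]]) / n))
  # BMI / SBP median agreement at initialisation
  lms <- lms_at(p$bmi_lms_full, init$age, init$sex)
  add("bmi_median_ratio", "all", stats::median(init$bmi / lms$M), 1, 0.05)
  lms <- lms_at(p$sbp_lms, init$age, init$sex)
  add("sbp_median_ratio", "all", stats::median(init$sbp / lms$M), 1, 0.05)
  # diabetes prevalence by age band at initialisation
  marg <- age_sex_lookup(p$diabetes_prevalence, "prob", init$age, init$sex)
  for (b in levels(cut(init$age, breaks, right = FALSE))) {
    i <- cut(init$age, breaks, right = FALSE) == b
    if (sum(i) < 50) next
    pr <- mean(marg[i])
    add("diabetes_prevalence", b, mean(init$diabetes[i]), pr,
        3 * sqrt(pr * (1 - pr) / sum(i)))
  }
  # albuminuria prevalence at initialisation
  pr <- mean(init$albuminuria > 0L)
  add("albuminuria_prevalence", "all", pr, pr, 3 * sqrt(pr * (1 - pr) / n))
  # lifetime outcomes on the completed run
  rrt <- mean(!is.na(state$age_at_rrt))
  add("rrt_lifetime_prevalence", "all", rrt, NA_real_,
      3 * sqrt(rrt * (1 - rrt) / n))
  add("mean_years_ckd3a_to_5", "all", mean(state$years_ckd3a5), NA_real_,
      3 * stats::sd(state$years_ckd3a5) / sqrt(n))
  out <- do.call(rbind, rows)
  out$within_band <- is.na(out$reference) |
    abs(out$simulated - out$reference) <= out$se_band
  out
}
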