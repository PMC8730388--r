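#' Per-individual population state
#'
#' The simulated cohort is a data.frame (class \code{ckd_population}) with
#' one row per individual. Albuminuria is coded as an ordered integer
#' (0 = none, 1 = microalbuminuria, 2 = macroalbuminuria) so monotone
#' progression is a simple numeric comparison; [alb_label()] maps codes to
#' labels. SDS values (\code{bmi_sds}, \code{sbp_sds}) are fixed for life:
#' individuals track their percentile while the reference shifts with age.
#'
#' @name ckd_population
NULL

.alb_levels <- c("none", "micro", "macro")

#' Map albuminuria codes to labels
#' @param code integer vector in 0:2.
#' @return character vector in \code{none/micro/macro}.
#' @export
alb_label <- function(code) .alb_levels[code + 1L]

.sex_i <- function(sex) ifelse(sex == "M", 2L, 1L)

# truncate SDS draws so LMS domain violations cannot occur in the tails
.trunc_z <- function(z, lim = 4) pmin(pmax(z, -lim), lim)

# L/M/S at (age, sex) with linear interpolation in age
lms_at <- function(tab, age, sex) {
  n <- length(age)
  L <- M <- S <- numeric(n)
  for (sx in c("F", "M")) {
    i <- sex == sx
    if (!any(i)) next
    t2 <- tab[tab$sex == sx, ]
    t2 <- t2[order(t2$age), ]
    a <- pmin(pmax(age[i], min(t2$age)), max(t2$age))
    L[i] <- stats::approx(t2$age, t2$L, a, rule = 2)$y
    M[i] <- stats::approx(t2$age, t2$M, a, rule = 2)$y
    S[i] <- stats::approx(t2$age, t2$S, a, rule = 2)$y
  }
  list(L = L, M = M, S = S)
}

# value of an (age, sex)-keyed probability table for each individual
age_sex_lookup <- function(tab, col, age, sex) {
  key <- paste(tab$age, tab$sex)
  v <- tab[[col]][match(paste(age, sex), key)]
  if (anyNA(v)) stop("table does not cover all requested (age, sex) cells")
  v
}

#' Sample ages and sexes for a new cohort
#'
#' Draws (age, sex) cells from the population distribution table.
#'
#' @param n cohort size.
#' @param p prepared \code{ckd_parameters}.
#' @param seed master seed for the run's random streams.
#' @return a \code{ckd_population} data.frame with demographic columns and
#'   empty state columns.
#' @export
sample_age_sex <- function(n, p, seed) {
  stopifnot(n >= 1)
  tab <- p$population_age_sex
  u <- stream_unif(n, seed, "age_sex")
  cs <- cumsum(tab$share)
  cs[length(cs)] <- 1
  idx <- findInterval(u, cs, left.open = TRUE) + 1L
  pop <- data.frame(
    id = seq_len(n),
    age = tab$age[idx],
    sex = tab$sex[idx],
    bmi_sds = NA_real_, bmi = NA_real_,
    sbp_sds = NA_real_, sbp = NA_real_,
    hypertensive = FALSE, ht_drug = "none", ht_drug_assigned = FALSE,
    on_raas_blocker = FALSE,
    diabetes = FALSE,
    albuminuria = 0L, gfr = NA_real_, gfr_loss_factor = NA_real_,
    on_rrt = FALSE, tested_positive = FALSE, acei_from_test = FALSE,
    adherent = FALSE, false_positive = FALSE, tested_this_cycle = FALSE,
    n_tests = 0L,
    alive = TRUE, censored = FALSE,
    age_at_rrt = NA_real_, age_at_death = NA_real_,
    years_ckd3a5 = 0,
    qaly_undisc = 0, qaly_disc = 0,
    cost_test_undisc = 0, cost_test_disc = 0,
    cost_med_undisc = 0, cost_med_disc = 0,
    cost_rrt_undisc = 0, cost_rrt_disc = 0,
    stringsAsFactors = FALSE
  )
  class(pop) <- c("ckd_population", "data.frame")
  pop
}

#' Assign BMI from the LMS reference
#'
#' Each individual draws a lifelong BMI SDS (standard normal, truncated at
#' +/- 4) and receives the corresponding BMI for their current age and sex.
#'
#' @param state a \code{ckd_population}.
#' @inheritParams sample_age_sex
#' @return updated state.
#' @export
assign_bmi <- function(state, p, seed) {
  z <- .trunc_z(stream_norm(nrow(state), seed, "bmi"))
  lms <- lms_at(p$bmi_lms_full, state$age, state$sex)
  state$bmi_sds <- z
  state$bmi <- lms_value(lms$L, lms$M, lms$S, z)
  state
}

#' Assign systolic blood pressure
#'
#' Draws an SDS from Normal(\code{sbp_mu_adjust}, 1), converts it to an SBP
#' under the (age, sex) LMS reference, raises the SBP linearly for BMI above
#' the reference BMI, and stores the SDS of the elevated value as the
#' definitive, lifelong \code{sbp_sds}. The mean shift compensates for the
#' right shift that the BMI elevation induces; it is a calibrated parameter
#' (see [calibrate_sbp_mean()]), zero by default.
#'
#' @inheritParams assign_bmi
#' @return updated state.
#' @export
assign_sbp <- function(state, p, seed) {
  z <- .trunc_z(stream_norm(nrow(state), seed, "sbp")) + p$sbp_mu_adjust
  lms <- lms_at(p$sbp_lms, state$age, state$sex)
  raw <- lms_value(lms$L, lms$M, lms$S, z)
  sbp <- raw + p$sbp_bmi_slope * pmax(0, state$bmi - p$sbp_bmi_ref)
  state$sbp <- sbp
  state$sbp_sds <- lms_sds(lms$L, lms$M, lms$S, sbp)
  state
}

#' Assign hypertension status and antihypertensive drug class
#'
#' Individuals with SBP strictly exceeding the hypertension threshold
#' (140 mmHg) are hypertensive and draw a drug class once from the therapy
#' distribution (which includes "none"); the assigned drug never changes.
#'
#' @inheritParams assign_bmi
#' @param stream internal: which random stream to use (initial assignment
#'   vs. incident hypertension during follow-up).
#' @param cycle internal: cycle index for the stream.
#' @return updated state.
#' @export
assign_hypertension_therapy <- function(state, p, seed,
                                        stream = "ht_drug", cycle = 0L) {
  state$hypertensive <- state$sbp > p$sbp_hypertension
  need <- state$hypertensive & !state$ht_drug_assigned
  if (any(need)) {
    u <- stream_unif(nrow(state), seed, stream, cycle)
    cs <- cumsum(p$ht_drug_distribution$prob)
    cs[length(cs)] <- 1
    idx <- findInterval(u, cs, left.open = TRUE) + 1L
    state$ht_drug[need] <- p$ht_drug_distribution$drug[idx[need]]
    state$ht_drug_assigned[need] <- TRUE
  }
  state$on_raas_blocker <- state$acei_from_test |
    state$ht_drug %in% c("ACEI", "ARB")
  state
}

#' Assign prevalent diabetes
#'
#' The marginal (age, sex) prevalence is decomposed into a baseline risk for
#' the unexposed stratum via [solve_baseline_risk()], using the relative
#' risks for obesity (BMI > 30) and hypertension and the stratum shares
#' observed in the simulated cohort itself; each individual then faces
#' baseline x own-stratum RR (capped at 1).
#'
#' @inheritParams assign_bmi
#' @return updated state.
#' @export
assign_diabetes_prevalent <- function(state, p, seed) {
  marg <- age_sex_lookup(p$diabetes_prevalence, "prob", state$age, state$sex)
  rr <- p$rr_diabetes_obesity^(state$bmi > 30) *
    p$rr_diabetes_hypertension^(state$hypertensive)
  pr <- .risk_from_marginal(marg, rr, paste(state$age, state$sex),
                            rep(TRUE, nrow(state)))
  u <- stream_unif(nrow(state), seed, "diabetes_prev")
  state$diabetes <- u < pr
  state
}

# per-individual probability from a cell marginal and individual RRs:
# baseline(cell) = marginal(cell) / mean(RR | cell, risk set); p_i = b * rr_i
.risk_from_marginal <- function(marginal, rr, cell, in_risk_set) {
  pr <- numeric(length(rr))
  if (!any(in_risk_set)) return(pr)
  mrr <- stats::ave(rr[in_risk_set], cell[in_risk_set], FUN = mean)
  pr[in_risk_set] <- pmin(marginal[in_risk_set] / mrr * rr[in_risk_set], 1)
  pr
}

#' Pre-simulate renal age profiles from an age-30 cohort
#'
#' Initial GFR distributions and albuminuria prevalences are only valid at
#' age 30, so a cohort of \code{cohort_size} thirty-year-olds is initialised
#' and advanced (base case, no screening) to the age cap; the surviving,
#' non-RRT individuals' GFR mean/sd and albuminuria prevalences are
#' tabulated per attained age and sex. Ages 18-29 copy the age-30 row.
#'
#' @param p prepared \code{ckd_parameters}.
#' @param cohort_size number of simulated thirty-year-olds.
#' @param seed master seed.
#' @param mortality apply mortality during the pre-simulation (default TRUE;
#'   FALSE gives the pure-progression profile used in diagnostics).
#' @return data.frame: age, sex, gfr_mean, gfr_sd, p_micro, p_macro, n.
#' @export
derive_renal_age_profiles <- function(p, cohort_size = 1e5, seed = 1L,
                                      mortality = TRUE) {
  sex_share <- tapply(p$population_age_sex$share, p$population_age_sex$sex, sum)
  u <- stream_unif(cohort_size, seed, "profile")
  state <- sample_age_sex(cohort_size, p, seed)
  state$age <- 30L
  state$sex <- ifelse(u < sex_share[["F"]] / sum(sex_share), "F", "M")
  state <- assign_bmi(state, p, seed)
  state <- assign_sbp(state, p, seed)
  state <- assign_hypertension_therapy(state, p, seed)
  state <- assign_diabetes_prevalent(state, p, seed)
  state <- .init_renal_age30(state, p, seed)

  rec <- list(.profile_row(state))
  scen <- ckd_scenario("profile", "none")
  n_cycles <- p$age_cap - 30L
  for (t in seq_len(n_cycles) - 1L) {
    state <- advance_year(state, p, scen, cycle = t, seed = seed,
                          mortality = mortality, accrue = FALSE)
    if (!any(state$alive)) stop("profile cohort extinct before the age cap")
    rec[[length(rec) + 1L]] <- .profile_row(state)
  }
  prof <- do.call(rbind, rec)
  # carry forward sparse cells (few survivors near the cap)
  prof <- prof[order(prof$sex, prof$age), ]
  for (col in c("gfr_mean", "gfr_sd", "p_micro", "p_macro"))
    for (sx in c("F", "M")) {
      i <- which(prof$sex == sx)
      v <- prof[[col]][i]
      for (k in seq_along(v)) if (is.na(v[k]) && k > 1) v[k] <- v[k - 1]
      prof[[col]][i] <- v
    }
  base <- prof[prof$age == 30, ]
  young <- do.call(rbind, lapply(18:29, function(a) transform(base, age = a)))
  prof <- rbind(young, prof)
  rownames(prof) <- NULL
  prof
}

.profile_row <- function(state) {
  i <- state$alive & !state$censored & !state$on_rrt
  out <- list()
  for (sx in c("F", "M")) {
    j <- i & state$sex == sx
    n <- sum(j)
    out[[sx]] <- data.frame(
      age = state$age[which(j)[1]] %||% NA_integer_,
      sex = sx,
      gfr_mean = if (n >= 2) mean(state$gfr[j]) else NA_real_,
      gfr_sd = if (n >= 2) stats::sd(state$gfr[j]) else NA_real_,
      p_micro = if (n >= 1) mean(state$albuminuria[j] == 1L) else NA_real_,
      p_macro = if (n >= 1) mean(state$albuminuria[j] == 2L) else NA_real_,
      n = n, stringsAsFactors = FALSE
    )
    if (n == 0) out[[sx]]$age <- max(state$age)
  }
  do.call(rbind, out)
}

# renal initialisation at the profile base age, straight from the age-30
# prevalence table and initial-GFR distribution
.init_renal_age30 <- function(state, p, seed) {
  tab <- p$albuminuria_prevalence
  key <- paste(tab$sex, tab$diabetes, tab$sbp_ge_140)
  idx <- match(paste(state$sex, as.integer(state$diabetes),
                     as.integer(state$sbp >= p$sbp_hypertension)), key)
  u <- stream_unif(nrow(state), seed, "alb_init")
  pm <- tab$p_macro[idx]; pmi <- tab$p_micro[idx]
  state$albuminuria <- ifelse(u < pm, 2L, ifelse(u < pm + pmi, 1L, 0L))
  g0 <- p$gfr_initial
  m <- g0$mean[match(state$sex, g0$sex)]
  s <- g0$sd[match(state$sex, g0$sex)]
  state$gfr <- .rtrunc_norm(stream_unif(nrow(state), seed, "gfr_init"),
                            m, s, lower = p$gfr_rrt)
  state$gfr_loss_factor <-
    exp(p$gfr_loss_factor_meanlog + p$gfr_loss_factor_sdlog *
          .trunc_z(stats::qnorm(stream_unif(nrow(state), seed, "loss_factor")))) *
    p$gfr_loss_calibration_scale
  state
}

# inverse-CDF truncated normal from uniforms
.rtrunc_norm <- function(u, mean, sd, lower) {
  lo <- stats::pnorm((lower - mean) / sd)
  q <- lo + u * (1 - lo)
  mean + sd * stats::qnorm(pmin(q, 1 - 1e-12))
}

#' Initialise renal state from pre-simulated age profiles
#'
#' GFR is drawn from a normal distribution (truncated above the RRT
#' threshold) with the profile's (age, sex) mean and sd; the albuminuria
#' category is drawn from the profile's prevalences; the individual annual
#' GFR-loss factor is drawn lognormal and multiplied by the GFR-loss
#' calibration scale (0.75 in the published calibration).
#'
#' @inheritParams assign_bmi
#' @param profile output of [derive_renal_age_profiles()].
#' @return updated state.
#' @export
initialize_renal_state <- function(state, profile, p, seed) {
  idx <- match(paste(state$age, state$sex), paste(profile$age, profile$sex))
  if (anyNA(idx)) stop("profile does not cover all (age, sex) cells in the population")
  u <- stream_unif(nrow(state), seed, "alb_init")
  pm <- profile$p_macro[idx]; pmi <- profile$p_micro[idx]
  state$albuminuria <- ifelse(u < pm, 2L, ifelse(u < pm + pmi, 1L, 0L))
  state$gfr <- .rtrunc_norm(stream_unif(nrow(state), seed, "gfr_init"),
                            profile$gfr_mean[idx], pmax(profile$gfr_sd[idx], 1e-6),
                            lower = p$gfr_rrt)
  state$gfr_loss_factor <-
    exp(p$gfr_loss_factor_meanlog + p$gfr_loss_factor_sdlog *
          .trunc_z(stats::qnorm(stream_unif(nrow(state), seed, "loss_factor")))) *
    p$gfr_loss_calibration_scale
  state
}

#' Build a complete initial population
#'
#' Runs the full initialisation cascade: demographics, BMI, SBP,
#' hypertension therapy, prevalent diabetes, and renal state from the age
#' profiles. The same seed yields a bit-identical population, so every
#' scenario arm can start from one common cohort.
#'
#' @inheritParams sample_age_sex
#' @param profile output of [derive_renal_age_profiles()].
#' @return a fully initialised \code{ckd_population}.
#' @export
init_population <- function(n, p, profile, seed) {
  state <- sample_age_sex(n, p, seed)
  state <- assign_bmi(state, p, seed)
  state <- assign_sbp(state, p, seed)
  state <- assign_hypertension_therapy(state, p, seed)
  state <- assign_diabetes_prevalent(state, p, seed)
  state <- initialize_renal_state(state, profile, p, seed)
  state$censored <- state$age >= p$age_cap
  state
}

#' @export
print.ckd_population <- function(x, ...) {
  cat(sprintf("<ckd_population> %d individuals; %.1f%% alive, %.1f%% censored\n",
              nrow(x), 100 * mean(x$alive), 100 * mean(x$censored)))
  cat(sprintf("  age %d-%d; %.1f%% diabetic; albuminuria none/micro/macro = %.1f/%.1f/%.1f%%\n",
              min(x$age), max(x$age), 100 * mean(x$diabetes),
              100 * mean(x$albuminuria == 0L), 100 * mean(x$albuminuria == 1L),
              100 * mean(x$albuminuria == 2L)))
  invisible(x)
}
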