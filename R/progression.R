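#' CKD stage from GFR
#'
#' Stages by GFR band: 1 (>= 90), 2 (60-89), 3a (45-59), 3b (30-44),
#' 4 (15-29), 5 (< 15), in ml/min.
#'
#' @param gfr numeric vector of GFR values (ml/min).
#' @return character vector of stage labels.
#' @export
ckd_stage <- function(gfr) {
  c("5", "4", "3b", "3a", "2", "1")[findInterval(gfr, c(15, 30, 45, 60, 90)) + 1L]
}

#' Solve the baseline risk of the unexposed stratum
#'
#' Given a marginal probability for the whole population and strata with
#' shares and relative risks, returns the baseline probability \code{r0}
#' such that the mixture reproduces the marginal exactly:
#' \code{r0 = marginal / sum(share * RR)}.
#'
#' @param marginal overall probability in [0, 1].
#' @param strata data.frame (or list) with columns/elements \code{share}
#'   (non-negative, summing to 1) and \code{rr} (non-negative).
#' @return baseline probability for an RR-1 individual.
#' @export
#' @examples
#' solve_baseline_risk(0.10, data.frame(share = c(.5, .5), rr = c(1, 3))) # 0.05
solve_baseline_risk <- function(marginal, strata) {
  share <- strata$share; rr <- strata$rr
  stopifnot(all(share >= 0), abs(sum(share) - 1) < 1e-9, all(rr >= 0))
  denom <- sum(share * rr)
  if (denom == 0) {
    if (marginal > 0) stop("all strata have zero relative risk but the marginal is positive")
    return(0)
  }
  marginal / denom
}

# effective renin-angiotensin blockade: test-initiated ACEI gated on
# adherence; therapy assigned for hypertension (ACEI or ARB) always effective
.effective_raas <- function(state) {
  (state$acei_from_test & state$adherent) |
    state$ht_drug %in% c("ACEI", "ARB")
}

.active <- function(state) state$alive & !state$censored

#' Advance age and re-evaluate anthropometrics
#'
#' Ages everyone one year; BMI and SBP are re-evaluated from the fixed SDS
#' values under the reference for the new age; hypertension status is
#' re-checked and newly hypertensive individuals draw a drug class once.
#'
#' @param state a \code{ckd_population}.
#' @param p prepared \code{ckd_parameters}.
#' @param cycle zero-based cycle index.
#' @param seed master seed.
#' @return updated state.
#' @export
update_anthropometrics <- function(state, p, cycle, seed) {
  act <- .active(state)
  state$age[act] <- state$age[act] + 1L
  lms <- lms_at(p$bmi_lms_full, state$age, state$sex)
  state$bmi[act] <- lms_value(lms$L[act], lms$M[act], lms$S[act],
                              state$bmi_sds[act])
  lms <- lms_at(p$sbp_lms, state$age, state$sex)
  state$sbp[act] <- lms_value(lms$L[act], lms$M[act], lms$S[act],
                              state$sbp_sds[act])
  newly <- act & !state$hypertensive & state$sbp > p$sbp_hypertension
  state$hypertensive <- state$hypertensive | newly
  if (any(newly)) {
    u <- stream_unif(nrow(state), seed, "new_ht_drug", cycle)
    cs <- cumsum(p$ht_drug_distribution$prob); cs[length(cs)] <- 1
    idx <- findInterval(u, cs, left.open = TRUE) + 1L
    draw <- newly & !state$ht_drug_assigned
    state$ht_drug[draw] <- p$ht_drug_distribution$drug[idx[draw]]
    state$ht_drug_assigned[draw] <- TRUE
    state$on_raas_blocker <- state$acei_from_test |
      state$ht_drug %in% c("ACEI", "ARB")
  }
  state
}

#' Incident diabetes
#'
#' Non-diabetic individuals convert with baseline(age, sex) x stratum RR,
#' with the baseline solved from the marginal incidence and the stratum
#' shares of the current at-risk population; diabetes is absorbing.
#'
#' @inheritParams update_anthropometrics
#' @return updated state.
#' @export
update_diabetes_incidence <- function(state, p, cycle, seed) {
  at_risk <- .active(state) & !state$diabetes
  marg <- age_sex_lookup(p$diabetes_incidence, "prob", state$age, state$sex)
  rr <- p$rr_diabetes_obesity^(state$bmi > 30) *
    p$rr_diabetes_hypertension^(state$hypertensive)
  pr <- .risk_from_marginal(marg, rr, paste(state$age, state$sex), at_risk)
  u <- stream_unif(nrow(state), seed, "diabetes_inc", cycle)
  state$diabetes <- state$diabetes | (at_risk & u < pr)
  state
}

#' Albuminuria onset and progression
#'
#' None -> micro with the (age, sex, diabetes, SBP-stratum) incidence;
#' micro -> macro with the progression probability, multiplied by the
#' ACEI progression relative risk when the individual is effectively on
#' renin-angiotensin blockade; macro is absorbing, regression impossible.
#'
#' @inheritParams update_anthropometrics
#' @return updated state.
#' @export
update_albuminuria <- function(state, p, cycle, seed) {
  act <- .active(state)
  sbp_hi <- as.integer(state$sbp >= p$sbp_hypertension)
  diab <- as.integer(state$diabetes)

  tab <- p$albuminuria_incidence
  inc <- tab$prob[match(paste(state$age, state$sex, diab, sbp_hi),
                        paste(tab$age, tab$sex, tab$diabetes, tab$sbp_ge_140))]
  tabp <- p$albuminuria_progression
  prog <- tabp$prob[match(paste(state$sex, diab, sbp_hi),
                          paste(tabp$sex, tabp$diabetes, tabp$sbp_ge_140))]
  prog <- prog * ifelse(.effective_raas(state), p$effect_acei_rr_progression, 1)

  u1 <- stream_unif(nrow(state), seed, "alb_onset", cycle)
  u2 <- stream_unif(nrow(state), seed, "alb_prog", cycle)
  onset <- act & state$albuminuria == 0L & u1 < inc
  progress <- act & state$albuminuria == 1L & u2 < prog
  state$albuminuria[onset] <- 1L
  state$albuminuria[progress] <- 2L
  state
}

#' Annual GFR decline
#'
#' loss = base(sex, diabetes, SBP stratum, albuminuria) x age factor x
#' individual loss factor (already scaled by the 0.75 calibration);
#' effectively treated albuminuric individuals have the loss reduced by the
#' ACEI GFR effect. GFR is floored at 0 and never increases.
#'
#' @inheritParams update_anthropometrics
#' @return updated state.
#' @export
update_gfr <- function(state, p, cycle, seed) {
  act <- .active(state)
  tab <- p$gfr_annual_loss
  base <- tab$loss[match(
    paste(state$sex, as.integer(state$diabetes),
          as.integer(state$sbp >= p$sbp_hypertension), alb_label(state$albuminuria)),
    paste(tab$sex, tab$diabetes, tab$sbp_ge_140, tab$albuminuria))]
  loss <- base * (1 + p$gfr_loss_age_coef * pmax(state$age - 30, 0)) *
    state$gfr_loss_factor
  treated <- state$albuminuria > 0L & .effective_raas(state)
  loss[treated] <- loss[treated] * (1 - p$effect_acei_e_gfr)
  state$gfr[act] <- pmax(0, state$gfr[act] - loss[act])
  state
}

#' Initiate renal replacement therapy
#'
#' Alive individuals whose GFR has fallen below the RRT threshold (7 ml/min)
#' start RRT and record their age; RRT is absorbing.
#'
#' @inheritParams update_anthropometrics
#' @return updated state.
#' @export
check_rrt <- function(state, p) {
  new_rrt <- .active(state) & !state$on_rrt & state$gfr < p$gfr_rrt
  state$on_rrt <- state$on_rrt | new_rrt
  state$age_at_rrt[new_rrt] <- state$age[new_rrt]
  state
}

#' Annual mortality
#'
#' q = life-table(age, sex) x mortality calibration factor x CKD
#' stage/albuminuria relative risk x ACEI mortality relative risk (if
#' albuminuric and effectively treated), capped at 1. Deaths record the age
#' at death; dead individuals never change state again.
#'
#' @inheritParams update_anthropometrics
#' @return updated state.
#' @export
apply_mortality <- function(state, p, cycle, seed) {
  act <- .active(state)
  q <- age_sex_lookup(p$life_table, "qx", pmin(state$age, max(p$life_table$age)),
                      state$sex) * p$mortality_calibration_factor
  tab <- p$rr_death_ckd
  rr <- tab$rr[match(paste(ckd_stage(state$gfr), alb_label(state$albuminuria)),
                     paste(tab$stage, tab$albuminuria))]
  rr <- rr * ifelse(state$albuminuria > 0L & .effective_raas(state),
                    p$effect_acei_rr_death, 1)
  q <- pmin(q * rr, 1)
  u <- stream_unif(nrow(state), seed, "mortality", cycle)
  die <- act & u < q
  state$alive[die] <- FALSE
  state$age_at_death[die] <- state$age[die]
  state
}

#' Advance the population one annual cycle
#'
#' Applies, in fixed order: anthropometrics (ageing) -> incident diabetes ->
#' albuminuria -> GFR decline -> RRT check -> scenario-gated screening ->
#' mortality -> outcome accrual; individuals reaching the age cap are
#' censored after accrual. Screening precedes mortality so therapy initiated
#' in a cycle affects that cycle's death risk.
#'
#' @inheritParams update_anthropometrics
#' @param scenario a \code{ckd_scenario}.
#' @param mortality logical; FALSE suppresses deaths (used for profile
#'   diagnostics).
#' @param accrue logical; FALSE skips QALY/cost accrual.
#' @return updated state.
#' @export
advance_year <- function(state, p, scenario, cycle, seed,
                         mortality = TRUE, accrue = TRUE) {
  if (!any(.active(state))) return(state)
  state$tested_this_cycle <- FALSE
  state <- update_anthropometrics(state, p, cycle, seed)
  state <- update_diabetes_incidence(state, p, cycle, seed)
  state <- update_albuminuria(state, p, cycle, seed)
  state <- update_gfr(state, p, cycle, seed)
  state <- check_rrt(state, p)
  if (scenario$eligibility != "none") {
    mask <- select_eligible(state, scenario, cycle, p)
    out <- perform_test(state, mask, p, cycle, seed)
    state <- apply_positive_result(state, out, p, cycle, seed)
  }
  if (mortality) state <- apply_mortality(state, p, cycle, seed)
  if (accrue) state <- accrue_year(state, p, cycle)
  state$censored <- state$censored | state$age >= p$age_cap
  state
}
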