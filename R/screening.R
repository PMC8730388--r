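#' Select individuals eligible for testing this cycle
#'
#' Eligible iff alive, not censored, matching the scenario rule
#' (\code{diabetes}, \code{diabetes-or-hypertension} or \code{all}), not
#' already on a renin-angiotensin blocker (when the scenario excludes them,
#' as all published comparators do), never previously tested positive, not
#' on RRT, and the cycle falls on the testing interval.
#'
#' @param state a \code{ckd_population}.
#' @param scenario a \code{ckd_scenario}.
#' @param year_index zero-based cycle index.
#' @param p \code{ckd_parameters}.
#' @return logical eligibility mask.
#' @export
select_eligible <- function(state, scenario, year_index, p) {
  if (scenario$eligibility == "none") return(rep(FALSE, nrow(state)))
  if (year_index %% scenario$testing_interval_years != 0L)
    return(rep(FALSE, nrow(state)))
  rule <- switch(scenario$eligibility,
    diabetes = state$diabetes,
    `diabetes-or-hypertension` = state$diabetes | state$hypertensive,
    all = rep(TRUE, nrow(state))
  )
  mask <- state$alive & !state$censored & rule &
    !state$tested_positive & !state$on_rrt
  if (scenario$exclude_if_on_raas_blocker) mask <- mask & !state$on_raas_blocker
  mask
}

#' Perform the repeated albumin-creatinine test
#'
#' Each tested individual undergoes the configured number of test repeats
#' (two in the published cascade) within the same annual follow-up; repeats
#' are independent conditional on the true albuminuric state. Each repeat is
#' positive with probability = sensitivity for albuminuric individuals and
#' 1 - specificity otherwise; the occasion is positive iff all repeats are.
#' One testing-occasion cost is charged per tested individual.
#'
#' @inheritParams select_eligible
#' @param mask logical eligibility mask from [select_eligible()].
#' @param cycle zero-based cycle index.
#' @param seed master seed.
#' @return list with logical vectors \code{tested}, \code{positive}, the
#'   albuminuric state at test time \code{true_state}, and per-individual
#'   \code{cost}.
#' @export
perform_test <- function(state, mask, p, cycle, seed) {
  n <- nrow(state)
  albuminuric <- state$albuminuria > 0L
  p_pos <- ifelse(albuminuric, p$test_sensitivity, 1 - p$test_specificity)
  positive <- mask
  for (k in seq_len(as.integer(p$test_repeats))) {
    u <- stream_unif(n, seed, "test1", cycle * 16L + k)
    positive <- positive & (u < p_pos)
  }
  list(tested = mask, positive = positive, true_state = albuminuric,
       cost = ifelse(mask, p$cost_test, 0))
}

#' Apply positive test results: sticky ACEI therapy and adherence
#'
#' Every positive (including false positives) starts lifelong ACEI therapy:
#' \code{tested_positive}, \code{acei_from_test} and \code{on_raas_blocker}
#' are set and never revert. Adherence is drawn once at therapy start
#' (probability 0.91); medication costs accrue every subsequent year
#' regardless of adherence, while the clinical effects (GFR-loss reduction,
#' progression RR, mortality RR) require adherence and an albuminuric state.
#' False positives therefore incur costs but no clinical effect.
#'
#' @inheritParams perform_test
#' @param outcomes result of [perform_test()].
#' @return updated state.
#' @export
apply_positive_result <- function(state, outcomes, p, cycle, seed) {
  state$tested_this_cycle <- state$tested_this_cycle | outcomes$tested
  state$n_tests <- state$n_tests + as.integer(outcomes$tested)
  newpos <- outcomes$positive & !state$tested_positive
  if (any(newpos)) {
    u <- stream_unif(nrow(state), seed, "adherence", cycle)
    state$adherent[newpos] <- u[newpos] < p$adherence_prob
    state$tested_positive[newpos] <- TRUE
    state$acei_from_test[newpos] <- TRUE
    state$on_raas_blocker[newpos] <- TRUE
    state$false_positive[newpos & !outcomes$true_state] <- TRUE
  }
  state
}
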