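#' Discount factor
#'
#' \code{(1 + rate)^(-t)} for a year index \code{t} counted from simulation
#' start; year-0 events are undiscounted.
#'
#' @param t non-negative year index (vectorised).
#' @param rate annual discount rate (default 0.035, the published choice).
#' @return discount factor(s).
#' @export
#' @examples
#' discount_factor(1, 0.035) # 0.966184...
discount_factor <- function(t, rate = 0.035) {
  if (any(t < 0)) stop("year index must be non-negative")
  (1 + rate)^(-t)
}

#' Accrue one cycle's QALYs and costs
#'
#' Alive, non-censored individuals accrue the EQ-5D utility of their CKD
#' stage as that year's QALY, the annual RRT cost if on RRT, and the
#' annualised ACEI price (100-day price x 365.25/100) if on test-initiated
#' therapy; testing-occasion costs are charged for everyone tested this
#' cycle. Undiscounted and discounted accumulators are updated in the same
#' pass using [discount_factor()] at the shared cycle clock.
#'
#' @param state a \code{ckd_population}.
#' @param p \code{ckd_parameters}.
#' @param cycle zero-based cycle index.
#' @return updated state.
#' @export
accrue_year <- function(state, p, cycle) {
  d <- discount_factor(cycle, p$discount_rate)
  act <- state$alive & !state$censored

  util <- p$utilities$utility[match(ckd_stage(state$gfr), p$utilities$stage)]
  q <- ifelse(act, util, 0)
  state$qaly_undisc <- state$qaly_undisc + q
  state$qaly_disc <- state$qaly_disc + q * d

  ct <- ifelse(state$tested_this_cycle, p$cost_test, 0)
  state$cost_test_undisc <- state$cost_test_undisc + ct
  state$cost_test_disc <- state$cost_test_disc + ct * d

  cm <- ifelse(act & state$acei_from_test, p$cost_med_100d * 365.25 / 100, 0)
  state$cost_med_undisc <- state$cost_med_undisc + cm
  state$cost_med_disc <- state$cost_med_disc + cm * d

  cr <- ifelse(act & state$on_rrt, p$cost_rrt_year, 0)
  state$cost_rrt_undisc <- state$cost_rrt_undisc + cr
  state$cost_rrt_disc <- state$cost_rrt_disc + cr * d

  state$years_ckd3a5 <- state$years_ckd3a5 +
    as.integer(act & state$gfr < 60)
  state
}

#' Normal-approximation 95\% confidence interval
#'
#' mean +/- z(0.975) x sd/sqrt(n); for 0/1 indicators this is the Wald
#' interval for a proportion.
#'
#' @param values numeric vector (per-individual values or indicators),
#'   length >= 2.
#' @param level confidence level (default 0.95).
#' @return named numeric vector \code{c(mean =, low =, high =)}.
#' @export
confidence_interval <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values for a confidence interval")
  m <- mean(values)
  half <- stats::qnorm(1 - (1 - level) / 2) * stats::sd(values) / sqrt(n)
  c(mean = m, low = m - half, high = m + half)
}

#' Summarise one completed scenario run
#'
#' Computes the per-scenario block of the cost-effectiveness comparison:
#' lifetime RRT prevalence, mean ages at RRT start and death, share censored
#' at the age cap, QALYs per individual and cost components per individual
#' (undiscounted and discounted), and the false-positive share, each with a
#' 95\% confidence interval over individuals.
#'
#' @param state a completed \code{ckd_population}.
#' @param p \code{ckd_parameters}.
#' @param name scenario label.
#' @return a \code{ckd_summary}: data.frame with columns \code{scenario},
#'   \code{quantity}, \code{mean}, \code{low}, \code{high}.
#' @export
summarize_scenario <- function(state, p, name = "scenario") {
  if (nrow(state) == 0) stop("empty population")
  row <- function(quantity, values, scale = 1) {
    ci <- if (length(values) >= 2) confidence_interval(values) else
      c(mean = mean(values), low = NA_real_, high = NA_real_)
    data.frame(scenario = name, quantity = quantity,
               mean = ci[["mean"]] * scale, low = ci[["low"]] * scale,
               high = ci[["high"]] * scale, stringsAsFactors = FALSE)
  }
  rrt <- !is.na(state$age_at_rrt)
  died <- !is.na(state$age_at_death)
  out <- rbind(
    row("rrt_lifetime_prevalence_pct", as.numeric(rrt), 100),
    row("mean_age_at_rrt", if (any(rrt)) state$age_at_rrt[rrt] else NA_real_),
    row("mean_age_at_death", if (any(died)) state$age_at_death[died] else NA_real_),
    row("censored_at_cap_pct", as.numeric(!died), 100),
    row("qaly_per_individual_undisc", state$qaly_undisc),
    row("qaly_per_individual_disc", state$qaly_disc),
    row("cost_rrt_per_individual_undisc", state$cost_rrt_undisc),
    row("cost_rrt_per_individual_disc", state$cost_rrt_disc),
    row("cost_test_per_individual_undisc", state$cost_test_undisc),
    row("cost_test_per_individual_disc", state$cost_test_disc),
    row("cost_med_per_individual_undisc", state$cost_med_undisc),
    row("cost_med_per_individual_disc", state$cost_med_disc),
    row("false_positive_pct", as.numeric(state$false_positive), 100),
    row("mean_years_ckd3a_to_5", state$years_ckd3a5)
  )
  class(out) <- c("ckd_summary", "data.frame")
  out
}

.summary_value <- function(summary, quantity) {
  v <- summary$mean[summary$quantity == quantity]
  if (length(v) != 1) stop("quantity not found in summary: ", quantity)
  v
}

#' Incremental cost-effectiveness of a scenario against the base case
#'
#' For undiscounted and discounted streams separately: QALYs gained per
#' individual, (testing + medication cost)/QALY gained, and the net ratio
#' after subtracting RRT cost savings. A non-positive QALY gain makes the
#' ratios undefined (reported as NA with a diagnostic attribute, never a
#' number).
#'
#' @param base,alt \code{ckd_summary} objects from [summarize_scenario()]
#'   for runs with the same population size and seed lineage.
#' @return data.frame with one row per discounting stream.
#' @export
compare_scenarios <- function(base, alt) {
  one <- function(sfx) {
    dq <- .summary_value(alt, paste0("qaly_per_individual_", sfx)) -
      .summary_value(base, paste0("qaly_per_individual_", sfx))
    intervention <- .summary_value(alt, paste0("cost_test_per_individual_", sfx)) +
      .summary_value(alt, paste0("cost_med_per_individual_", sfx))
    saved_rrt <- .summary_value(base, paste0("cost_rrt_per_individual_", sfx)) -
      .summary_value(alt, paste0("cost_rrt_per_individual_", sfx))
    undefined <- dq <= 0
    data.frame(
      scenario = alt$scenario[1], stream = sfx,
      qaly_gained = dq,
      cost_per_qaly = if (undefined) NA_real_ else intervention / dq,
      net_cost_per_qaly = if (undefined) NA_real_ else (intervention - saved_rrt) / dq,
      ratio_defined = !undefined,
      stringsAsFactors = FALSE
    )
  }
  rbind(one("undisc"), one("disc"))
}

#' Assemble the full comparison table for a set of scenario summaries
#'
#' @param summaries named list of \code{ckd_summary} objects; must include
#'   one named \code{"base"}.
#' @return list with \code{outcomes} (long table of all scenario summaries)
#'   and \code{incremental} (ratios of each non-base scenario vs base).
#' @export
cea_table <- function(summaries) {
  if (!"base" %in% names(summaries))
    stop("a summary named 'base' is required for incremental results")
  outcomes <- do.call(rbind, summaries)
  rownames(outcomes) <- NULL
  alts <- setdiff(names(summaries), "base")
  incremental <- if (length(alts) > 0)
    do.call(rbind, lapply(summaries[alts], function(s)
      compare_scenarios(summaries$base, s)))
  else NULL
  if (!is.null(incremental)) rownames(incremental) <- NULL
  list(outcomes = outcomes, incremental = incremental)
}
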