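# Deterministic cohort state-transition engine: cycle-dependent cost and
# QALY accrual over a five-year horizon with annual cycles.
#
# Within-cycle competing risks are composed in a fixed order shared with
# the microsimulation (see event_flows): other-cause death first, then a
# state-specific bleed among survivors, then the bleed-death split. The
# ordering is isolated here so alternatives are one-line swaps.

# Annual bleed probability by state. Non-HRV states (including the
# scenario NSBB strata without HRV) use the optional background rate.
state_bleed_probs <- function(params) {
  tr <- params$transitions
  bg <- params$structure$p_bleed_background
  c(NO_HRV_SURV = bg, NO_HRV_ENDO = bg,
    HRV_NSBB = tr$p_bleed_nsbb, HRV_LIG = tr$p_bleed_ligation,
    HRV_MISSED = tr$p_bleed_missed_hrv,
    POST_BLEED = 0,                      # one-bleed maximum
    CSPH_NSBB = bg, NSBB_NO_CSPH = bg)
}

# Per-year utility by state.
state_utilities <- function(params) {
  u <- params$utilities
  stats::setNames(
    c(u$u_no_hrv, u$u_no_hrv, u$u_nsbb, u$u_ligation, u$u_hrv_untreated,
      u$u_post_bleed, 0, 0, u$u_nsbb, params$scenario$u_nsbb_no_csph),
    health_states())
}

# Expected within-cycle event flows from a start-of-cycle occupancy:
# bleeds, bleed deaths, other-cause deaths, and (optionally) missed-HRV
# detections among event-free survivors. Single source of the composition
# rule for the engine, the cycle costing, and the tally.
event_flows <- function(params, occupancy) {
  if (any(occupancy < -1e-9)) stop("negative occupancy", call. = FALSE)
  bp <- state_bleed_probs(params)
  p_do <- params$transitions$p_death_other
  p_db <- params$transitions$p_death_after_bleed
  alive <- occupancy[names(bp)]
  bleeds_by_state <- alive * (1 - p_do) * bp
  bleeds <- sum(bleeds_by_state)
  detected <- 0
  if (isTRUE(params$structure$detect_missed_next_cycle)) {
    detected <- occupancy[["HRV_MISSED"]] * (1 - p_do) *
      (1 - bp[["HRV_MISSED"]]) * params$accuracy$sensitivity
  }
  list(bleeds = bleeds,
       deaths_bleed = bleeds * p_db,
       deaths_other = sum(occupancy[alive_states()]) * p_do,
       detected = detected)
}

#' Build the one-cycle transition matrix
#'
#' From each alive state the within-cycle competing risks compose as:
#' other-cause death (`p_death_other`) applied first; the state-specific
#' bleed probability applied to survivors; a bleed is fatal with
#' `p_death_after_bleed`, otherwise the patient enters `POST_BLEED`.
#' `POST_BLEED` faces only other-cause death (one-bleed maximum); dead
#' states are absorbing. With `detect_missed_next_cycle` enabled,
#' event-free missed-HRV survivors are detected with probability equal to
#' the criteria's sensitivity and start prophylaxis next cycle.
#'
#' The matrix is time-homogeneous in the base model; `cycle_index` is part
#' of the interface for cycle-dependent extensions.
#'
#' @inheritParams allocate_cohort
#' @param cycle_index Cycle number in `1..horizon_cycles`.
#' @return Row-stochastic matrix over [health_states()] (rows sum to 1
#'   within 1e-12; checked).
#' @export
build_transition_matrix <- function(strategy, params, cycle_index = 1) {
  assert_strategy(strategy)
  if (cycle_index < 1 || cycle_index > params$econ$horizon_cycles) {
    stop("cycle_index out of 1..horizon_cycles", call. = FALSE)
  }
  st <- health_states()
  tr <- params$transitions
  bp <- state_bleed_probs(params)
  M <- matrix(0, length(st), length(st), dimnames = list(st, st))
  for (s in names(bp)) {
    b <- bp[[s]]
    M[s, "DEAD_OTHER"] <- tr$p_death_other
    surv <- 1 - tr$p_death_other
    M[s, "DEAD_BLEED"] <- surv * b * tr$p_death_after_bleed
    M[s, "POST_BLEED"] <- M[s, "POST_BLEED"] + surv * b * (1 - tr$p_death_after_bleed)
    stay <- surv * (1 - b)
    if (s == "HRV_MISSED" && isTRUE(params$structure$detect_missed_next_cycle)) {
      det <- stay * params$accuracy$sensitivity
      M[s, "HRV_NSBB"] <- M[s, "HRV_NSBB"] + det * tr$p_nsbb_treatment
      M[s, "HRV_LIG"]  <- M[s, "HRV_LIG"] + det * tr$p_ligation_treatment
      stay <- stay - det
    }
    M[s, s] <- M[s, s] + stay
  }
  M["DEAD_BLEED", "DEAD_BLEED"] <- 1
  M["DEAD_OTHER", "DEAD_OTHER"] <- 1
  bad <- abs(rowSums(M) - 1) > 1e-12
  if (any(bad)) {
    stop("transition rows do not sum to 1: ", paste(st[bad], collapse = ", "),
         call. = FALSE)
  }
  M
}

# cycles in which scheduled procedures fall: ligation and its anchor at
# treatment initiation (cycles 1, 3, 5); biennial repeat endoscopy for
# endoscopy-negative patients anchored after the initial exam (cycles 3, 5)
is_ligation_cycle <- function(cycle_index) cycle_index %% 2 == 1
is_followup_endo_cycle <- function(cycle_index) cycle_index > 1 && cycle_index %% 2 == 1

#' Cohort cost accrued during one cycle
#'
#' Charges, on the start-of-cycle (during-cycle) occupancy: annual NSBB
#' drug cost to all NSBB states; annual endoscopy plus biennial ligation
#' (cycles 1, 3, 5) to the ligation state; biennial repeat endoscopy
#' (cycles 3, 5) to endoscopy-negative follow-up; the annual non-invasive
#' panel (elastography + platelet count) to surveillance and missed-HRV
#' states; hospitalization per expected bleed this cycle; and the
#' diagnostic endoscopy for detected missed HRV when that pathway is
#' enabled. Dead states cost nothing. Decision-tree test costs are not
#' included here (the engine adds them at cycle 1).
#'
#' @inheritParams build_transition_matrix
#' @param occupancy Named nonnegative vector over [health_states()].
#' @return Cost in USD for the cohort for this cycle (undiscounted).
#' @export
cycle_cost <- function(strategy, params, cycle_index, occupancy) {
  if (any(occupancy < -1e-9)) stop("negative occupancy", call. = FALSE)
  co <- params$costs
  fl <- event_flows(params, occupancy)
  cost <- occupancy[["HRV_NSBB"]] * co$nsbb_annual +
    occupancy[["CSPH_NSBB"]] * co$nsbb_annual +
    occupancy[["NSBB_NO_CSPH"]] * co$nsbb_annual +
    occupancy[["HRV_LIG"]] * co$endoscopy +
    (occupancy[["NO_HRV_SURV"]] + occupancy[["HRV_MISSED"]]) *
      (co$elastography + co$blood_routine) +
    fl$bleeds * co$bleed_hospitalization +
    fl$detected * co$endoscopy
  if (is_ligation_cycle(cycle_index)) {
    cost <- cost + occupancy[["HRV_LIG"]] * co$band_ligation
  }
  if (is_followup_endo_cycle(cycle_index)) {
    cost <- cost + occupancy[["NO_HRV_ENDO"]] * co$endoscopy
  }
  unname(cost)
}

#' Cohort QALYs accrued during one cycle
#'
#' Sum over alive states of occupancy times the state utility times the
#' cycle length; dead states contribute zero.
#'
#' @inheritParams cycle_cost
#' @return QALYs (undiscounted).
#' @export
cycle_qaly <- function(params, occupancy) {
  if (any(occupancy < -1e-9)) stop("negative occupancy", call. = FALSE)
  sum(occupancy * state_utilities(params)[names(occupancy)]) *
    params$econ$cycle_length_years
}

#' Run the deterministic cohort simulation
#'
#' Starts from the decision-tree allocation and iterates the annual
#' transition matrix over the horizon. Costs and QALYs accrue on the state
#' occupied *during* each cycle (the start-of-cycle occupancy) and are
#' discounted at `(1 + r)^-(t-1)` for cycle `t = 1..horizon` — the first
#' cycle is undiscounted, matching the default of standard cohort-modelling
#' tools; no half-cycle correction is applied. Decision-tree test costs are
#' charged at cycle 1. Patients who die during a cycle still accrue that
#' cycle's reward.
#'
#' @inheritParams allocate_cohort
#' @return A `state_trace` object: list with `occupancy` (matrix, rows
#'   cycles `0..horizon` where row `t` is the occupancy after `t`
#'   transitions), `cycles` (per-cycle data.frame of cost, QALY, discount
#'   factor and discounted accruals), `discounted_cost`,
#'   `discounted_qaly` (cohort totals), `cost_per_capita`,
#'   `qaly_per_capita`, and `tally` (expected event counts: bleeds, bleed
#'   deaths, other deaths, endoscopies, ligation procedures, NSBB
#'   person-years).
#' @export
#' @examples
#' tr <- run_cohort("universal", default_parameters())
#' tr$cost_per_capita
#' tr$qaly_per_capita
run_cohort <- function(strategy, params) {
  assert_strategy(strategy)
  validate_parameters(params)
  n <- params$econ$cohort_size
  horizon <- as.integer(params$econ$horizon_cycles)
  r <- params$econ$discount_rate
  cyl <- params$econ$cycle_length_years

  alloc <- allocate_cohort(strategy, params)
  occ <- alloc$occupancy
  occupancy <- matrix(0, horizon + 1, length(occ),
                      dimnames = list(0:horizon, names(occ)))
  occupancy[1, ] <- occ

  tally <- c(bleeds = 0, deaths_bleed = 0, deaths_other = 0,
             endoscopies = unname(alloc$first_cycle_tests["endoscopies"]),
             ligations = 0, nsbb_person_years = 0)
  cyc <- data.frame(cycle = seq_len(horizon), cost = NA_real_, qaly = NA_real_,
                    discount_factor = NA_real_)

  for (t in seq_len(horizon)) {
    M <- build_transition_matrix(strategy, params, t)
    fl <- event_flows(params, occ)
    cost <- cycle_cost(strategy, params, t, occ)
    if (t == 1) cost <- cost + alloc$first_cycle_cost
    qaly <- cycle_qaly(params, occ)
    df <- (1 + r)^(-(t - 1) * cyl)
    cyc$cost[t] <- cost
    cyc$qaly[t] <- qaly
    cyc$discount_factor[t] <- df

    tally["bleeds"] <- tally["bleeds"] + fl$bleeds
    tally["deaths_bleed"] <- tally["deaths_bleed"] + fl$deaths_bleed
    tally["deaths_other"] <- tally["deaths_other"] + fl$deaths_other
    tally["nsbb_person_years"] <- tally["nsbb_person_years"] +
      occ[["HRV_NSBB"]] + occ[["CSPH_NSBB"]] + occ[["NSBB_NO_CSPH"]]
    tally["endoscopies"] <- tally["endoscopies"] + occ[["HRV_LIG"]] +
      fl$detected +
      if (is_followup_endo_cycle(t)) occ[["NO_HRV_ENDO"]] else 0
    if (is_ligation_cycle(t)) {
      tally["ligations"] <- tally["ligations"] + occ[["HRV_LIG"]]
    }

    occ <- drop(occ %*% M)
    if (abs(sum(occ) - n) > 1e-9) {
      stop(sprintf("mass not conserved at cycle %d: %.12f", t, sum(occ)),
           call. = FALSE)
    }
    occupancy[t + 1, ] <- occ
  }

  cyc$disc_cost <- cyc$cost * cyc$discount_factor
  cyc$disc_qaly <- cyc$qaly * cyc$discount_factor
  out <- list(strategy = strategy,
              occupancy = occupancy,
              cycles = cyc,
              discounted_cost = sum(cyc$disc_cost),
              discounted_qaly = sum(cyc$disc_qaly),
              cost_per_capita = sum(cyc$disc_cost) / n,
              qaly_per_capita = sum(cyc$disc_qaly) / n,
              tally = tally,
              allocation = alloc)
  class(out) <- "state_trace"
  out
}

#' @export
print.state_trace <- function(x, ...) {
  cat(sprintf("Cohort trace — %s: per-capita discounted cost $%.2f, %.4f QALYs\n",
              x$strategy, x$cost_per_capita, x$qaly_per_capita))
  cat(sprintf("  events: %.1f bleeds (%.2f fatal), %.1f other deaths, %.1f endoscopies, %.1f ligations\n",
              x$tally["bleeds"], x$tally["deaths_bleed"], x$tally["deaths_other"],
              x$tally["endoscopies"], x$tally["ligations"]))
  invisible(x)
}

#' Export a cohort trace as a long table
#'
#' One row per (cycle, state) with during-cycle occupancy, plus per-cycle
#' cost, QALY and discount factor columns.
#'
#' @param trace A `state_trace` from [run_cohort()].
#' @param path Optional CSV output path.
#' @return data.frame.
#' @export
trace_table <- function(trace, path = NULL) {
  horizon <- nrow(trace$occupancy) - 1
  df <- do.call(rbind, lapply(seq_len(horizon), function(t) {
    data.frame(cycle = t, state = colnames(trace$occupancy),
               occupancy = trace$occupancy[t, ],
               cycle_cost = trace$cycles$cost[t],
               cycle_qaly = trace$cycles$qaly[t],
               discount_factor = trace$cycles$discount_factor[t],
               row.names = NULL)
  }))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
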