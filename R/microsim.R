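# Individual-level microsimulation: synthetic patient trajectories drawn
# under the exact model probabilities. The stochastic oracle for the
# deterministic cohort engine — within-cycle events use the same ordered
# composition (other-cause death, then bleed among survivors, then the
# bleed-death split, then optional missed-HRV detection) and the same
# accrual and discounting conventions, so per-capita means converge to the
# cohort expectations at rate ~ 1/sqrt(n).

#' Simulate individual patient trajectories
#'
#' Each patient draws a true HRV status (Bernoulli at prevalence), a
#' triage classification conditional on truth (sensitivity/specificity),
#' an initial state per strategy, and then per-cycle death/bleed/detection
#' events. Costs, utilities and discounting replicate the cohort engine
#' exactly (state costs and utilities accrue on the state occupied during
#' the cycle; event costs in the cycle of the event; discount factor
#' `(1+r)^-(t-1)`).
#'
#' @inheritParams allocate_cohort
#' @param n_patients Number of patients (>= 1).
#' @param seed Integer seed; identical seed gives identical output.
#' @param keep_trajectories Keep per-cycle records (`$records`)? Defaults
#'   to `TRUE` for `n_patients <= 5000`, otherwise only aggregates are
#'   returned.
#' @return A `microsim_result`: list with `summary` (mean and standard
#'   error of per-capita discounted cost and QALYs; event totals scaled to
#'   the model cohort size), `per_patient` (discounted cost/QALY, bleed
#'   and death flags per patient), and optionally `records` (long
#'   data.frame: patient_id, cycle, state, bleed_flag, death_flag, cost,
#'   utility, discount_factor).
#' @export
#' @examples
#' ms <- simulate_patients("universal", default_parameters(), 500, seed = 7)
#' ms$summary
simulate_patients <- function(strategy, params, n_patients, seed = 1,
                              keep_trajectories = n_patients <= 5000) {
  assert_strategy(strategy)
  validate_parameters(params)
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  n <- as.integer(n_patients)
  set.seed(seed)

  st <- health_states()
  code <- stats::setNames(seq_along(st), st)
  tr <- params$transitions
  co <- params$costs
  ac <- params$accuracy
  ec <- params$econ
  horizon <- as.integer(ec$horizon_cycles)
  bp_state <- stats::setNames(numeric(length(st)), st)
  bp_state[names(state_bleed_probs(params))] <- state_bleed_probs(params)
  u_state <- state_utilities(params)

  draw_treatment <- function(k) {
    ifelse(stats::runif(k) < tr$p_nsbb_treatment, code["HRV_NSBB"], code["HRV_LIG"])
  }

  # ---- decision tree: initial states and first-cycle test costs ----
  true_hrv <- meets_baveno <- logical(n)
  state <- integer(n)
  tree_cost <- numeric(n)
  if (strategy == "universal") {
    true_hrv <- stats::runif(n) < ac$prevalence_hrv
    state[true_hrv] <- draw_treatment(sum(true_hrv))
    state[!true_hrv] <- code["NO_HRV_ENDO"]
    tree_cost[] <- co$endoscopy
  } else if (strategy == "selective") {
    true_hrv <- stats::runif(n) < ac$prevalence_hrv
    u <- stats::runif(n)
    meets_baveno <- ifelse(true_hrv, u < (1 - ac$sensitivity), u < ac$specificity)
    state[true_hrv & meets_baveno] <- code["HRV_MISSED"]
    state[!true_hrv & meets_baveno] <- code["NO_HRV_SURV"]
    nh <- true_hrv & !meets_baveno
    state[nh] <- draw_treatment(sum(nh))
    state[!true_hrv & !meets_baveno] <- code["NO_HRV_ENDO"]
    tree_cost[] <- co$elastography + co$blood_routine
    tree_cost[!meets_baveno] <- tree_cost[!meets_baveno] + co$endoscopy
  } else { # baveno7_scenario
    sc <- params$scenario
    high <- stats::runif(n) < sc$p_lsm_ge_25
    u <- stats::runif(n)
    # within the high stratum: HRV, then misclassified no-CSPH, then true CSPH
    hrv_hi <- high & (u < sc$prev_hrv_in_csph)
    mis_hi <- high & !hrv_hi & (u < sc$prev_hrv_in_csph + sc$p_misclassified_nsbb)
    state[hrv_hi] <- code["HRV_NSBB"]
    state[mis_hi] <- code["NSBB_NO_CSPH"]
    state[high & !hrv_hi & !mis_hi] <- code["CSPH_NSBB"]
    low <- !high
    hrv_lo <- low & (stats::runif(n) < prev_hrv_below_25(params))
    state[hrv_lo] <- draw_treatment(sum(hrv_lo))
    state[low & !hrv_lo] <- code["NO_HRV_ENDO"]
    true_hrv <- hrv_hi | hrv_lo
    tree_cost[] <- co$elastography
    tree_cost[low] <- tree_cost[low] + co$endoscopy
  }
  initial_state <- state

  nsbb_codes <- code[c("HRV_NSBB", "CSPH_NSBB", "NSBB_NO_CSPH")]
  panel_codes <- code[c("NO_HRV_SURV", "HRV_MISSED")]
  detect <- isTRUE(params$structure$detect_missed_next_cycle)

  disc_cost <- disc_qaly <- numeric(n)
  ever_bled <- dead_bleed <- dead_other <- logical(n)
  if (keep_trajectories) {
    rec_state <- matrix(0L, n, horizon)
    rec_bleed <- matrix(FALSE, n, horizon)
    rec_death <- matrix(FALSE, n, horizon)
    rec_cost  <- matrix(0, n, horizon)
    rec_util  <- matrix(0, n, horizon)
  }

  for (t in seq_len(horizon)) {
    df <- (1 + ec$discount_rate)^(-(t - 1) * ec$cycle_length_years)
    # state costs and utilities on the state occupied during the cycle
    cost_t <- numeric(n)
    if (t == 1) cost_t <- cost_t + tree_cost
    cost_t[state %in% nsbb_codes] <- cost_t[state %in% nsbb_codes] + co$nsbb_annual
    lig <- state == code["HRV_LIG"]
    cost_t[lig] <- cost_t[lig] + co$endoscopy +
      if (is_ligation_cycle(t)) co$band_ligation else 0
    if (is_followup_endo_cycle(t)) {
      fe <- state == code["NO_HRV_ENDO"]
      cost_t[fe] <- cost_t[fe] + co$endoscopy
    }
    pan <- state %in% panel_codes
    cost_t[pan] <- cost_t[pan] + co$elastography + co$blood_routine
    util_t <- u_state[state]

    # within-cycle events: other-cause death, then bleed, then bleed death,
    # then optional detection of missed HRV among event-free survivors
    alive <- !(state %in% code[dead_states()])
    die_other <- alive & (stats::runif(n) < tr$p_death_other)
    at_risk <- alive & !die_other
    bleed <- at_risk & (stats::runif(n) < bp_state[state])
    die_bleed <- bleed & (stats::runif(n) < tr$p_death_after_bleed)
    cost_t[bleed] <- cost_t[bleed] + co$bleed_hospitalization
    new_state <- state
    new_state[die_other] <- code["DEAD_OTHER"]
    new_state[bleed & !die_bleed] <- code["POST_BLEED"]
    new_state[die_bleed] <- code["DEAD_BLEED"]
    if (detect) {
      cand <- at_risk & !bleed & state == code["HRV_MISSED"]
      found <- cand & (stats::runif(n) < ac$sensitivity)
      cost_t[found] <- cost_t[found] + co$endoscopy
      new_state[found] <- draw_treatment(sum(found))
    }

    disc_cost <- disc_cost + cost_t * df
    disc_qaly <- disc_qaly + util_t * ec$cycle_length_years * df
    ever_bled <- ever_bled | bleed
    dead_bleed <- dead_bleed | die_bleed
    dead_other <- dead_other | die_other
    if (keep_trajectories) {
      rec_state[, t] <- state
      rec_bleed[, t] <- bleed
      rec_death[, t] <- die_other | die_bleed
      rec_cost[, t]  <- cost_t
      rec_util[, t]  <- util_t
    }
    state <- new_state
  }

  summary <- list(
    n_patients = n,
    mean_cost = mean(disc_cost), se_cost = stats::sd(disc_cost) / sqrt(n),
    mean_qaly = mean(disc_qaly), se_qaly = stats::sd(disc_qaly) / sqrt(n),
    bleed_rate = mean(ever_bled),
    bleeds_per_cohort = mean(ever_bled) * ec$cohort_size,
    deaths_bleed_per_cohort = mean(dead_bleed) * ec$cohort_size,
    deaths_other_per_cohort = mean(dead_other) * ec$cohort_size)

  out <- list(strategy = strategy, seed = seed, summary = summary,
              per_patient = data.frame(
                patient_id = seq_len(n), true_hrv = true_hrv,
                meets_baveno = meets_baveno,
                initial_state = st[initial_state],
                disc_cost = disc_cost, disc_qaly = disc_qaly,
                bled = ever_bled, dead_bleed = dead_bleed,
                dead_other = dead_other))
  if (keep_trajectories) {
    dfs <- (1 + ec$discount_rate)^(-(seq_len(horizon) - 1) * ec$cycle_length_years)
    out$records <- data.frame(
      patient_id = rep(seq_len(n), horizon),
      cycle = rep(seq_len(horizon), each = n),
      state = st[as.vector(rec_state)],
      bleed_flag = as.vector(rec_bleed),
      death_flag = as.vector(rec_death),
      cost = as.vector(rec_cost),
      utility = as.vector(rec_util),
      discount_factor = rep(dfs, each = n))
    out$records <- out$records[order(out$records$patient_id, out$records$cycle), ]
    rownames(out$records) <- NULL
  }
  class(out) <- "microsim_result"
  out
}

#' @export
print.microsim_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Microsimulation — %s, n = %d (seed %d)\n", x$strategy,
              s$n_patients, x$seed))
  cat(sprintf("  per-capita cost $%.2f (SE %.2f), QALYs %.4f (SE %.4f)\n",
              s$mean_cost, s$se_cost, s$mean_qaly, s$se_qaly))
  cat(sprintf("  bleeds/cohort %.1f, bleed deaths %.1f, other deaths %.1f\n",
              s$bleeds_per_cohort, s$deaths_bleed_per_cohort,
              s$deaths_other_per_cohort))
  invisible(x)
}

#' Write or read a trajectory fixture
#'
#' Fixture CSV schema: `patient_id, cycle, state, bleed_flag, death_flag,
#' cost, utility, discount_factor`. Round-trips losslessly.
#'
#' @param records Trajectory data.frame (`$records` of a
#'   `microsim_result`), possibly empty.
#' @param path File path.
#' @return `export_fixture`: `path`, invisibly. `read_fixture`: the
#'   data.frame.
#' @export
export_fixture <- function(records, path) {
  cols <- c("patient_id", "cycle", "state", "bleed_flag", "death_flag",
            "cost", "utility", "discount_factor")
  if (is.null(records) || !nrow(records)) {
    records <- stats::setNames(
      data.frame(integer(), integer(), character(), logical(), logical(),
                 numeric(), numeric(), numeric()), cols)
  }
  utils::write.csv(records[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_fixture
#' @export
read_fixture <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(patient_id = "integer", cycle = "integer",
                                 state = "character", bleed_flag = "logical",
                                 death_flag = "logical", cost = "numeric",
                                 utility = "numeric",
                                 discount_factor = "numeric"))
}
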