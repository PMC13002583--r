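# First-year decision tree: allocates the cohort to initial Markov states
# and counts first-cycle screening tests and their cost.

#' Allocate the cohort to initial health states
#'
#' Resolves the first-year decision tree for one strategy:
#'
#' * **universal** — every patient undergoes endoscopy; true-HRV patients
#'   (prevalence share) split between NSBB and ligation prophylaxis; the
#'   remainder enter biennial endoscopic follow-up.
#' * **selective** — every patient receives elastography plus a platelet
#'   panel; criteria-meeters split by NPV into surveillance (no HRV) and
#'   missed HRV; non-meeters undergo endoscopy and split by PPV into
#'   treated HRV and endoscopic follow-up.
#' * **baveno7_scenario** — every patient receives elastography; the
#'   LSM >= 25 kPa stratum starts NSBBs without endoscopy (true-CSPH HRV,
#'   true-CSPH without HRV, and a misclassified no-CSPH fraction tracked
#'   separately); the LSM < 25 kPa stratum is screened as in the universal
#'   arm at its stratum-specific HRV prevalence.
#'
#' Expected (fractional) patient counts are used throughout: this is the
#' deterministic cohort view of the tree.
#'
#' @param strategy One of [strategies()].
#' @param params A `model_parameters` object.
#' @return An `initial_distribution` object: list with `occupancy` (named
#'   vector over [health_states()], summing to the cohort size),
#'   `first_cycle_cost` (USD, undiscounted; see [first_cycle_costs()]), and
#'   `first_cycle_tests` (named counts of endoscopies and non-invasive
#'   panels performed by the tree).
#' @export
#' @examples
#' allocate_cohort("universal", default_parameters())
allocate_cohort <- function(strategy, params) {
  assert_strategy(strategy)
  validate_parameters(params)
  n  <- params$econ$cohort_size
  ac <- params$accuracy
  tr <- params$transitions
  occ <- stats::setNames(numeric(length(health_states())), health_states())
  tests <- c(endoscopies = 0, noninvasive_panels = 0, elastographies = 0)

  if (strategy == "universal") {
    hrv <- n * ac$prevalence_hrv
    occ["HRV_NSBB"]    <- hrv * tr$p_nsbb_treatment
    occ["HRV_LIG"]     <- hrv * tr$p_ligation_treatment
    occ["NO_HRV_ENDO"] <- n - hrv
    tests["endoscopies"] <- n
  } else if (strategy == "selective") {
    cls <- derive_classification(ac)
    meet <- n * cls$p_meet
    occ["HRV_MISSED"]  <- meet * (1 - cls$npv)
    occ["NO_HRV_SURV"] <- meet * cls$npv
    nonmeet <- n - meet
    hrv <- nonmeet * cls$ppv
    occ["HRV_NSBB"]    <- hrv * tr$p_nsbb_treatment
    occ["HRV_LIG"]     <- hrv * tr$p_ligation_treatment
    occ["NO_HRV_ENDO"] <- nonmeet - hrv
    tests["endoscopies"] <- nonmeet
    tests["noninvasive_panels"] <- n
  } else { # baveno7_scenario
    validate_scenario(params)
    sc <- params$scenario
    high <- n * sc$p_lsm_ge_25              # LSM >= 25 kPa: NSBBs, no endoscopy
    occ["HRV_NSBB"]     <- high * sc$prev_hrv_in_csph
    occ["NSBB_NO_CSPH"] <- high * sc$p_misclassified_nsbb
    occ["CSPH_NSBB"]    <- high - occ["HRV_NSBB"] - occ["NSBB_NO_CSPH"]
    low <- n - high                          # LSM < 25 kPa: endoscopic screening
    hrv_low <- low * prev_hrv_below_25(params)
    occ["HRV_NSBB"]    <- occ["HRV_NSBB"] + hrv_low * tr$p_nsbb_treatment
    occ["HRV_LIG"]     <- hrv_low * tr$p_ligation_treatment
    occ["NO_HRV_ENDO"] <- low - hrv_low
    tests["endoscopies"] <- low
    tests["elastographies"] <- n
    if (occ["CSPH_NSBB"] < -1e-9) {
      stop("scenario misclassified fraction exceeds the non-HRV share of the ",
           "LSM >= 25 kPa stratum", call. = FALSE)
    }
    occ["CSPH_NSBB"] <- max(occ["CSPH_NSBB"], 0)
  }

  out <- list(strategy = strategy,
              occupancy = occ,
              first_cycle_cost = first_cycle_costs(strategy, params),
              first_cycle_tests = tests)
  class(out) <- "initial_distribution"
  stopifnot(abs(sum(occ) - n) < 1e-9)
  out
}

#' First-cycle screening test costs
#'
#' Sums the decision-tree test costs (undiscounted; the cohort engine
#' applies the cycle-1 discount factor): universal charges endoscopy to
#' everyone; selective charges elastography + platelet panel to everyone
#' and endoscopy to criteria non-meeters; the Baveno VII scenario charges
#' elastography to everyone and endoscopy to the LSM < 25 kPa stratum.
#' Treatment-initiation costs (first-year NSBB, first ligation) are charged
#' by the Markov engine at cycle 1, not here.
#'
#' @inheritParams allocate_cohort
#' @return Cost in USD for the whole cohort.
#' @export
first_cycle_costs <- function(strategy, params) {
  assert_strategy(strategy)
  n <- params$econ$cohort_size
  co <- params$costs
  if (strategy == "universal") {
    n * co$endoscopy
  } else if (strategy == "selective") {
    cls <- derive_classification(params$accuracy)
    n * (co$elastography + co$blood_routine) + n * (1 - cls$p_meet) * co$endoscopy
  } else {
    n * co$elastography + n * (1 - params$scenario$p_lsm_ge_25) * co$endoscopy
  }
}

#' @export
print.initial_distribution <- function(x, ...) {
  cat("Initial distribution —", x$strategy, "\n")
  occ <- x$occupancy[x$occupancy > 0]
  print(data.frame(state = names(occ), expected_count = as.numeric(occ),
                   fraction = as.numeric(occ) / sum(x$occupancy),
                   row.names = NULL))
  cat(sprintf("First-cycle test cost: $%.2f (%s)\n", x$first_cycle_cost,
              paste(names(x$first_cycle_tests), x$first_cycle_tests,
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Export an initial allocation as a tabular report
#'
#' @param dist An `initial_distribution` from [allocate_cohort()].
#' @param path Optional CSV output path.
#' @return data.frame with state, expected count and fraction.
#' @export
allocation_table <- function(dist, path = NULL) {
  df <- data.frame(state = names(dist$occupancy),
                   expected_count = as.numeric(dist$occupancy),
                   fraction = as.numeric(dist$occupancy) / sum(dist$occupancy))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
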