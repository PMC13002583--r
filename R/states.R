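# Health-state space shared by the cohort engine and the microsimulation.

#' Health states of the variceal screening model
#'
#' The model tracks eight core states plus two states used only by the
#' Baveno VII scenario arm (zero occupancy in the base strategies):
#'
#' * `NO_HRV_SURV` — criteria met, truly no high-risk varices (HRV); annual
#'   non-invasive monitoring (selective arm only).
#' * `NO_HRV_ENDO` — endoscopy-negative; biennial repeat endoscopy.
#' * `HRV_NSBB` — HRV on non-selective beta-blocker prophylaxis.
#' * `HRV_LIG` — HRV on band ligation (biennial procedure, annual endoscopy).
#' * `HRV_MISSED` — criteria met but HRV present; untreated.
#' * `POST_BLEED` — survived a variceal bleed (absorbing for bleeding).
#' * `DEAD_BLEED`, `DEAD_OTHER` — absorbing death states.
#' * `CSPH_NSBB` — scenario: LSM >= 25 kPa, true clinically significant
#'   portal hypertension, on NSBBs without endoscopy.
#' * `NSBB_NO_CSPH` — scenario: LSM >= 25 kPa but misclassified (no true
#'   CSPH), on NSBBs.
#'
#' @return Character vector of state labels, in canonical order.
#' @export
health_states <- function() {
  c("NO_HRV_SURV", "NO_HRV_ENDO", "HRV_NSBB", "HRV_LIG", "HRV_MISSED",
    "POST_BLEED", "DEAD_BLEED", "DEAD_OTHER", "CSPH_NSBB", "NSBB_NO_CSPH")
}

#' @rdname health_states
#' @export
dead_states <- function() c("DEAD_BLEED", "DEAD_OTHER")

#' @rdname health_states
#' @export
alive_states <- function() setdiff(health_states(), dead_states())

#' Screening strategies
#'
#' @return Character vector of the three strategy labels.
#' @export
strategies <- function() c("universal", "selective", "baveno7_scenario")

assert_strategy <- function(strategy) {
  if (!(is.character(strategy) && length(strategy) == 1 &&
        strategy %in% strategies())) {
    stop("unknown strategy: must be one of ",
         paste(strategies(), collapse = ", "), call. = FALSE)
  }
  strategy
}
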