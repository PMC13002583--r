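# Shared test helpers: parameter constructors and closed forms.

# report every expectation rather than aborting at the default failure cap
options(testthat.progress.max_fails = 10000)

# default parameters with leaf overrides by path, e.g.
# params_with("accuracy.sensitivity" = 1)
params_with <- function(...) {
  ov <- list(...)
  p <- default_parameters()
  for (k in names(ov)) p <- set_parameter(p, k, ov[[k]])
  p
}

# parameters with every event probability zero (no bleeds, no deaths)
params_no_events <- function(p = default_parameters()) {
  for (k in c("transitions.p_bleed_missed_hrv", "transitions.p_bleed_nsbb",
              "transitions.p_bleed_ligation", "transitions.p_death_after_bleed",
              "transitions.p_death_other")) {
    p <- set_parameter(p, k, 0)
  }
  p
}

# parameters with every unit cost zero
params_zero_costs <- function(p = default_parameters()) {
  for (k in paste0("costs.", names(p$costs))) p <- set_parameter(p, k, 0)
  p
}

# discounted annuity over the horizon under the engine's convention:
# cycle t = 1..H accrues with factor (1+r)^-(t-1)
annuity <- function(horizon = 5, r = 0.035) {
  sum((1 + r)^(-(seq_len(horizon) - 1)))
}

# brute-force 2x2 contingency enumeration of a large pseudo-cohort:
# exact expected cell counts, independent of the analytic formulas
enumerate_classification <- function(prev, sens, spec, n = 1e6) {
  hrv <- n * prev
  no_hrv <- n - hrv
  meet_hrv <- hrv * (1 - sens)      # false negatives of the triage
  meet_no_hrv <- no_hrv * spec      # true negatives spared endoscopy
  meet <- meet_hrv + meet_no_hrv
  nonmeet <- n - meet
  list(p_meet = meet / n,
       npv = meet_no_hrv / meet,
       ppv = (hrv - meet_hrv) / nonmeet)
}
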