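# Model inputs: diagnostic accuracy, transition probabilities, costs
# (2022 USD), utilities, economic settings, scenario inputs, and the
# Bayesian derivation of the triage classification probabilities.

#' Default model parameters
#'
#' Point estimates for every model input: diagnostic accuracy of the
#' Baveno VI criteria, annual transition probabilities, unit costs in 2022
#' USD, health-state utilities, economic settings, Baveno VII scenario
#' inputs, and structural flags. All values can be overridden through
#' [load_parameters()] or by editing the returned object (then revalidate
#' with [validate_parameters()]).
#'
#' Structural flags:
#' * `detect_missed_next_cycle` — if `TRUE`, untreated missed-HRV patients
#'   who neither die nor bleed in a cycle are detected at the annual
#'   non-invasive retest (probability = sensitivity), undergo endoscopy and
#'   start prophylaxis the next cycle. Default `FALSE`: missed HRV persists
#'   untreated for the whole horizon.
#' * `p_bleed_background` — annual bleed probability applied to the
#'   endoscopy-negative and surveillance states. Default 0.
#'
#' @return An object of class `model_parameters`: a nested list with
#'   components `accuracy`, `transitions`, `costs`, `utilities`, `econ`,
#'   `scenario`, and `structure`.
#' @export
#' @examples
#' p <- default_parameters()
#' derive_classification(p$accuracy)
default_parameters <- function() {
  p <- list(
    accuracy = list(
      prevalence_hrv = 0.20,
      sensitivity    = 0.97,  # P(criteria NOT met | HRV): flags HRV for endoscopy
      specificity    = 0.32   # P(criteria met | no HRV)
    ),
    transitions = list(
      p_nsbb_treatment     = 0.8,
      p_ligation_treatment = 0.2,
      p_bleed_missed_hrv   = 0.10,
      p_bleed_nsbb         = 0.068,
      p_bleed_ligation     = 0.043,
      p_death_after_bleed  = 0.022,
      p_death_other        = 0.034
    ),
    costs = list(
      endoscopy             = 96.73,
      blood_routine         = 2.68,
      elastography          = 18.60,
      nsbb_annual           = 52.68,
      band_ligation         = 744.05,
      bleed_hospitalization = 1934.52
    ),
    utilities = list(
      u_nsbb          = 0.65,
      u_ligation      = 0.67,
      u_no_hrv        = 0.76,
      u_hrv_untreated = 0.72,
      u_post_bleed    = 0.54
    ),
    econ = list(
      discount_rate      = 0.035,
      horizon_cycles     = 5L,
      cycle_length_years = 1,
      cohort_size        = 1000,
      wtp_per_qaly       = 12714.11,
      psa_iterations     = 10000L
    ),
    scenario = list(
      p_lsm_ge_25          = 0.30,
      prev_hrv_in_csph     = 0.40,
      p_misclassified_nsbb = 0.075,
      u_nsbb_no_csph       = 0.73
    ),
    structure = list(
      detect_missed_next_cycle = FALSE,
      p_bleed_background       = 0
    )
  )
  class(p) <- "model_parameters"
  validate_parameters(p)
}

# field -> c(low, high) validity bounds used by the validator
.param_bounds <- function() {
  list(
    accuracy    = list(prevalence_hrv = c(0, 1), sensitivity = c(0, 1),
                       specificity = c(0, 1)),
    transitions = list(p_nsbb_treatment = c(0, 1), p_ligation_treatment = c(0, 1),
                       p_bleed_missed_hrv = c(0, 1), p_bleed_nsbb = c(0, 1),
                       p_bleed_ligation = c(0, 1), p_death_after_bleed = c(0, 1),
                       p_death_other = c(0, 1)),
    costs       = list(endoscopy = c(0, Inf), blood_routine = c(0, Inf),
                       elastography = c(0, Inf), nsbb_annual = c(0, Inf),
                       band_ligation = c(0, Inf), bleed_hospitalization = c(0, Inf)),
    utilities   = list(u_nsbb = c(0, 1), u_ligation = c(0, 1), u_no_hrv = c(0, 1),
                       u_hrv_untreated = c(0, 1), u_post_bleed = c(0, 1)),
    econ        = list(discount_rate = c(0, Inf), horizon_cycles = c(1, Inf),
                       cycle_length_years = c(0, Inf), cohort_size = c(1, Inf),
                       wtp_per_qaly = c(0, Inf), psa_iterations = c(1, Inf)),
    scenario    = list(p_lsm_ge_25 = c(0, 1), prev_hrv_in_csph = c(0, 1),
                       p_misclassified_nsbb = c(0, 1), u_nsbb_no_csph = c(0, 1)),
    structure   = list(detect_missed_next_cycle = NULL,
                       p_bleed_background = c(0, 1))
  )
}

#' Validate a model parameter set
#'
#' Checks every field against its validity domain (probabilities and
#' utilities in \[0, 1\], costs nonnegative, horizon >= 1 cycle) and that
#' the NSBB/ligation treatment split sums to 1. Scenario stratum coherence
#' is checked separately by [validate_scenario()].
#'
#' @param params A `model_parameters` object (or bare list with the same
#'   shape).
#' @return The validated object, invisibly classed `model_parameters`.
#' @export
validate_parameters <- function(params) {
  bounds <- .param_bounds()
  for (grp in names(bounds)) {
    if (is.null(params[[grp]])) {
      stop("parameter group missing: ", grp, call. = FALSE)
    }
    extra <- setdiff(names(params[[grp]]), names(bounds[[grp]]))
    if (length(extra)) {
      stop("unknown parameter field(s) in ", grp, ": ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    for (fld in names(bounds[[grp]])) {
      v <- params[[grp]][[fld]]
      if (is.null(v)) stop("parameter missing: ", grp, ".", fld, call. = FALSE)
      b <- bounds[[grp]][[fld]]
      if (is.null(b)) {  # logical flag
        if (!(is.logical(v) && length(v) == 1 && !is.na(v))) {
          stop(grp, ".", fld, " must be TRUE or FALSE", call. = FALSE)
        }
        next
      }
      if (!(is.numeric(v) && length(v) == 1 && is.finite(v))) {
        stop(grp, ".", fld, " must be a single finite number", call. = FALSE)
      }
      if (v < b[1] || v > b[2]) {
        stop(sprintf("%s.%s = %g out of range [%g, %g]", grp, fld, v, b[1], b[2]),
             call. = FALSE)
      }
    }
  }
  tr <- params$transitions
  if (abs(tr$p_nsbb_treatment + tr$p_ligation_treatment - 1) > 1e-9) {
    stop("p_nsbb_treatment + p_ligation_treatment must equal 1", call. = FALSE)
  }
  class(params) <- "model_parameters"
  invisible(params)
}

#' Validate the Baveno VII scenario strata
#'
#' Checks HRV mass conservation across the LSM strata: the derived HRV
#' prevalence below 25 kPa must be a probability. Enforced when a config
#' is loaded and before any scenario run; base-strategy analyses (e.g.
#' prevalence sweeps) are not constrained by the scenario strata.
#'
#' @param params A `model_parameters` object.
#' @return `params`, invisibly.
#' @export
validate_scenario <- function(params) {
  pb <- prev_hrv_below_25(params)
  if (pb < -1e-12 || pb > 1 + 1e-12) {
    stop(sprintf(paste0("scenario stratum violates HRV mass conservation: derived ",
                        "HRV prevalence below 25 kPa = %.4f is outside [0, 1]"), pb),
         call. = FALSE)
  }
  invisible(params)
}

#' Derived HRV prevalence in the LSM < 25 kPa stratum
#'
#' Cohort-level HRV mass is conserved across the Baveno VII strata:
#' `p_lsm_ge_25 * prev_hrv_in_csph + (1 - p_lsm_ge_25) * prev_below = prevalence_hrv`.
#'
#' @param params A `model_parameters` object.
#' @return The derived prevalence (may fall outside \[0, 1\] for
#'   inconsistent configurations; [validate_parameters()] rejects those).
#' @export
prev_hrv_below_25 <- function(params) {
  s <- params$scenario
  if (s$p_lsm_ge_25 >= 1) return(0)
  (params$accuracy$prevalence_hrv - s$p_lsm_ge_25 * s$prev_hrv_in_csph) /
    (1 - s$p_lsm_ge_25)
}

#' Classification probabilities of the Baveno VI triage
#'
#' Derives, from HRV prevalence and the criteria's sensitivity and
#' specificity, the probability of meeting the criteria (being spared
#' endoscopy), the negative predictive value among criteria-meeters, and
#' the positive predictive value among non-meeters:
#' \deqn{p_{meet} = \pi(1-se) + (1-\pi)sp}
#' \deqn{NPV = (1-\pi)sp / p_{meet}, \quad PPV = \pi \, se / (1-p_{meet})}
#' where \eqn{\pi} is prevalence, \eqn{se} the probability that a true HRV
#' patient does NOT meet the low-risk criteria, and \eqn{sp} the
#' probability that a non-HRV patient meets them.
#'
#' @param accuracy List with `prevalence_hrv`, `sensitivity`, `specificity`,
#'   all in \[0, 1\] (e.g. `default_parameters()$accuracy`).
#' @return List with `p_meet`, `npv`, `ppv` (full precision, never rounded).
#' @export
#' @examples
#' derive_classification(list(prevalence_hrv = 0.20,
#'                            sensitivity = 0.97, specificity = 0.32))
derive_classification <- function(accuracy) {
  pi_ <- accuracy$prevalence_hrv
  se  <- accuracy$sensitivity
  sp  <- accuracy$specificity
  for (v in c(pi_, se, sp)) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop("prevalence, sensitivity and specificity must be probabilities in [0, 1]",
           call. = FALSE)
    }
  }
  p_meet <- pi_ * (1 - se) + (1 - pi_) * sp
  if (p_meet <= 0 || p_meet >= 1) {
    stop(sprintf("degenerate classification: p_meet = %g makes NPV or PPV undefined",
                 p_meet), call. = FALSE)
  }
  list(p_meet = p_meet,
       npv = (1 - pi_) * sp / p_meet,
       ppv = pi_ * se / (1 - p_meet))
}

# ---- config file I/O --------------------------------------------------------

# flat-key <-> nested mapping: "group.field" YAML keys
.flat_key_table <- function() {
  bounds <- .param_bounds()
  do.call(rbind, lapply(names(bounds), function(grp) {
    data.frame(group = grp, field = names(bounds[[grp]]),
               key = paste0(grp, ".", names(bounds[[grp]])),
               stringsAsFactors = FALSE)
  }))
}

#' Load model parameters from a YAML config file
#'
#' The config is a flat key-value YAML document whose keys are
#' `group.field` in snake_case (e.g. `costs.endoscopy: 44.64`,
#' `accuracy.prevalence_hrv: 0.30`). Any omitted key takes its default
#' point estimate; unknown keys and out-of-range values are errors, never
#' silently ignored. Currency is always 2022 USD.
#'
#' @param config_path Path to the YAML file, or `NULL` for all defaults.
#' @return A validated `model_parameters` object.
#' @seealso [serialize_parameters()] for the inverse.
#' @export
load_parameters <- function(config_path = NULL) {
  params <- default_parameters()
  if (is.null(config_path)) return(params)
  if (!file.exists(config_path)) {
    stop("config file not found: ", config_path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(config_path)
  if (is.null(cfg)) return(params)
  tab <- .flat_key_table()
  unknown <- setdiff(names(cfg), tab$key)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (k in names(cfg)) {
    row <- tab[tab$key == k, ]
    params[[row$group]][[row$field]] <- cfg[[k]]
  }
  validate_parameters(params)
  validate_scenario(params)
  params
}

#' Serialize model parameters to a flat YAML config
#'
#' Writes every field as a flat `group.field` key so that
#' `load_parameters(serialize_parameters(p, path))` round-trips losslessly.
#'
#' @param params A `model_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
serialize_parameters <- function(params, path) {
  validate_parameters(params)
  tab <- .flat_key_table()
  out <- stats::setNames(
    lapply(seq_len(nrow(tab)), function(i) params[[tab$group[i]]][[tab$field[i]]]),
    tab$key)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Model parameters (variceal screening CEA, 2022 USD)\n")
  cls <- derive_classification(x$accuracy)
  cat(sprintf("  HRV prevalence %.2f | sens %.2f | spec %.2f -> p_meet %.3f, NPV %.3f, PPV %.3f\n",
              x$accuracy$prevalence_hrv, x$accuracy$sensitivity,
              x$accuracy$specificity, cls$p_meet, cls$npv, cls$ppv))
  cat(sprintf("  cohort %d, %d x %g-year cycles, discount %.1f%%, WTP $%.2f/QALY\n",
              as.integer(x$econ$cohort_size), as.integer(x$econ$horizon_cycles),
              x$econ$cycle_length_years, 100 * x$econ$discount_rate,
              x$econ$wtp_per_qaly))
  invisible(x)
}

# ---- deterministic sensitivity ranges --------------------------------------

#' Default deterministic sensitivity (DSA) ranges
#'
#' One row per tunable leaf parameter with its low/high range. Printed
#' ranges are used verbatim where they are informative; parameters whose
#' printed range is the whole \[0, 1\] support (the NSBB/ligation split and
#' other-cause death) and the untreated-HRV utility (whose printed range
#' excludes its own point estimate) fall back to +/-20% around the point
#' estimate, the same fallback rule used for any parameter without a
#' usable interval. Derived quantities (p_meet, NPV, PPV) are not listed:
#' they vary through their parents.
#'
#' @param params A `model_parameters` object (defaults used for means).
#' @return data.frame with columns `path`, `base`, `low`, `high`, `psa_family`.
#' @export
default_dsa_ranges <- function(params = default_parameters()) {
  rng <- function(path, low, high, family) {
    data.frame(path = path, base = get_parameter(params, path),
               low = low, high = high, psa_family = family,
               stringsAsFactors = FALSE)
  }
  pm20 <- function(path, family, cap01 = TRUE) {
    b <- get_parameter(params, path)
    lo <- 0.8 * b; hi <- 1.2 * b
    if (cap01) { lo <- max(0, lo); hi <- min(1, hi) }
    rng(path, lo, hi, family)
  }
  rbind(
    rng("accuracy.prevalence_hrv", 0.10, 0.30, "beta"),
    rng("accuracy.sensitivity",    0.95, 0.98, "beta"),
    rng("accuracy.specificity",    0.26, 0.39, "beta"),
    pm20("transitions.p_nsbb_treatment", "beta"),   # printed 0-1 carries no information
    rng("transitions.p_bleed_missed_hrv", 0.08, 0.12, "beta"),
    rng("transitions.p_bleed_nsbb",     0, 0.1,  "beta"),
    rng("transitions.p_bleed_ligation", 0, 0.1,  "beta"),
    rng("transitions.p_death_after_bleed", 0.01, 0.04, "beta"),
    pm20("transitions.p_death_other", "beta"),      # printed 0-1 carries no information
    rng("costs.endoscopy",     44.64, 178.57, "gamma"),
    rng("costs.blood_routine",  2.23,   3.72, "gamma"),
    rng("costs.elastography",  12.65,  24.55, "gamma"),
    rng("costs.nsbb_annual",   26.34,  79.02, "gamma"),
    rng("costs.band_ligation", 446.43, 1026.79, "gamma"),
    rng("costs.bleed_hospitalization", 758.93, 2976.19, "gamma"),
    rng("utilities.u_nsbb",     0.52, 0.95, "beta"),
    rng("utilities.u_ligation", 0.52, 0.95, "beta"),
    rng("utilities.u_no_hrv",   0.52, 0.95, "beta"),
    pm20("utilities.u_hrv_untreated", "beta"),      # printed range excludes the estimate
    rng("utilities.u_post_bleed", 0.26, 0.66, "beta")
  )
}

# ---- parameter paths --------------------------------------------------------

.derived_paths <- c("p_meet", "npv", "ppv",
                    "accuracy.p_meet", "accuracy.npv", "accuracy.ppv")

#' Get or set a model parameter by path
#'
#' Paths are `group.field` strings, e.g. `"costs.endoscopy"` or
#' `"accuracy.prevalence_hrv"`. Setting a parameter revalidates the whole
#' object; the treatment-split complement is kept in sync when either half
#' is set. Derived classification quantities (`p_meet`, `npv`, `ppv`)
#' cannot be set or swept directly: vary their parents
#' (prevalence/sensitivity/specificity) instead.
#'
#' @param params A `model_parameters` object.
#' @param path Parameter path string.
#' @param value Replacement value (for `set_parameter`).
#' @return `get_parameter`: the value. `set_parameter`: the modified,
#'   revalidated `model_parameters` object.
#' @export
get_parameter <- function(params, path) {
  pp <- .split_path(path)
  v <- params[[pp[1]]][[pp[2]]]
  if (is.null(v)) stop("unknown parameter path: ", path, call. = FALSE)
  v
}

#' @rdname get_parameter
#' @export
set_parameter <- function(params, path, value) {
  if (path %in% .derived_paths) {
    stop(path, " is a derived quantity; sweep its parents ",
         "(accuracy.prevalence_hrv / sensitivity / specificity) instead",
         call. = FALSE)
  }
  pp <- .split_path(path)
  if (is.null(params[[pp[1]]][[pp[2]]])) {
    stop("unknown parameter path: ", path, call. = FALSE)
  }
  params[[pp[1]]][[pp[2]]] <- value
  # keep the treatment split summing to one when either half is set
  if (path == "transitions.p_nsbb_treatment") {
    params$transitions$p_ligation_treatment <- 1 - value
  } else if (path == "transitions.p_ligation_treatment") {
    params$transitions$p_nsbb_treatment <- 1 - value
  }
  validate_parameters(params)
  params
}

.split_path <- function(path) {
  pp <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(pp) != 2) stop("parameter path must be 'group.field': ", path,
                            call. = FALSE)
  pp
}
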