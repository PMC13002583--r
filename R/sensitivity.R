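# Deterministic sensitivity machinery: one-way sweeps, tornado ranking,
# bisection threshold search, and two-way accuracy grids.

#' One-way parameter sweep
#'
#' Re-runs the base-case comparison (selective vs. universal) at each grid
#' point with only the named parameter changed. Derived classification
#' quantities are recomputed from their parents at every point, so
#' sweeping prevalence/sensitivity/specificity propagates automatically;
#' attempting to sweep a derived quantity (`p_meet`, `npv`, `ppv`) is an
#' error directing the user to the parents.
#'
#' @param spec List (or one-row data.frame) with `path`, `low`, `high`,
#'   and optionally `n_points` (default 50).
#' @param params Base `model_parameters`.
#' @return data.frame with one row per grid point: `value`, per-strategy
#'   cost/qaly, incrementals, `icer`, `dominance`, `inmb` (incremental net
#'   monetary benefit of selective at the configured WTP).
#' @export
one_way_sweep <- function(spec, params = default_parameters()) {
  spec <- as.list(spec)
  n_points <- if (is.null(spec$n_points)) 50L else as.integer(spec$n_points)
  if (n_points < 1) stop("n_points must be positive", call. = FALSE)
  if (spec$low > spec$high) stop("sweep low must be <= high", call. = FALSE)
  values <- if (spec$low == spec$high) rep(spec$low, n_points) else
    seq(spec$low, spec$high, length.out = n_points)
  rows <- lapply(values, function(v) {
    p <- set_parameter(params, spec$path, v)
    res <- base_case(p)
    data.frame(path = spec$path, value = v,
               cost_universal = res$reference[["cost"]],
               qaly_universal = res$reference[["qaly"]],
               cost_selective = res$comparator[["cost"]],
               qaly_selective = res$comparator[["qaly"]],
               incremental_cost = res$incremental_cost,
               incremental_qaly = res$incremental_qaly,
               icer = res$icer, dominance = res$dominance,
               inmb = unname(res$nmb["comparator"] - res$nmb["reference"]))
  })
  do.call(rbind, rows)
}

#' Tornado analysis
#'
#' Evaluates each parameter at its range endpoints, holding all others at
#' base, and ranks parameters by the absolute span of the incremental net
#' monetary benefit (selective vs. universal). NMB spans are used for the
#' ranking because dominance outcomes have no finite ICER and ratio spans
#' are pathological near zero incremental QALYs; the endpoint ICERs (with
#' dominance flags) are reported alongside.
#'
#' @param params Base `model_parameters`.
#' @param specs data.frame with columns `path`, `low`, `high` (default:
#'   [default_dsa_ranges()]).
#' @param path Optional CSV output path.
#' @return data.frame ranked by decreasing `abs_span`, with endpoint ICERs,
#'   dominance flags and incremental-NMB values.
#' @export
tornado <- function(params = default_parameters(),
                    specs = default_dsa_ranges(params), path = NULL) {
  if (!nrow(specs)) stop("specs must be nonempty", call. = FALSE)
  ep <- function(p, path_, v) {
    res <- base_case(set_parameter(p, path_, v))
    c(icer = res$icer,
      inmb = unname(res$nmb["comparator"] - res$nmb["reference"]),
      dom = res$dominance)
  }
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    lo <- ep(params, specs$path[i], specs$low[i])
    hi <- ep(params, specs$path[i], specs$high[i])
    data.frame(path = specs$path[i],
               low = specs$low[i], high = specs$high[i],
               icer_at_low = as.numeric(lo["icer"]),
               icer_at_high = as.numeric(hi["icer"]),
               dominance_at_low = lo["dom"], dominance_at_high = hi["dom"],
               inmb_at_low = as.numeric(lo["inmb"]),
               inmb_at_high = as.numeric(hi["inmb"]),
               row.names = NULL)
  })
  df <- do.call(rbind, rows)
  df$abs_span <- abs(df$inmb_at_high - df$inmb_at_low)
  df <- df[order(-df$abs_span), ]
  rownames(df) <- NULL
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

# Built-in threshold criteria. Each returns a signed number whose zero
# crossing is the threshold.
threshold_criteria <- function() {
  list(
    # > 0 while universal is the cheaper strategy
    cost_parity = function(params) {
      res <- base_case(params)
      unname(res$incremental_cost)
    },
    # > 0 while selective is cost-effective at the configured WTP
    # (positive incremental NMB, equivalent to ICER <= WTP for dQ > 0)
    nmb_parity = function(params) {
      res <- base_case(params)
      unname(res$nmb["comparator"] - res$nmb["reference"])
    }
  )
}

#' Bisection threshold search
#'
#' Finds the parameter value at which a criterion changes sign, by plain
#' bisection to an absolute tolerance (default 0.01 USD for costs, 0.001
#' otherwise). The criterion is either the name of a built-in
#' (`"cost_parity"`: incremental cost of selective vs. universal;
#' `"nmb_parity"`: incremental NMB of selective at the configured WTP) or
#' any function `params -> signed numeric`.
#'
#' @param parameter_path Path of the parameter to vary.
#' @param criterion Criterion name or function (see above).
#' @param bracket Length-2 numeric search interval; the criterion must
#'   change sign across it.
#' @param params Base `model_parameters`.
#' @param tol Absolute tolerance on the threshold (default by parameter
#'   type: 0.01 for `costs.*`, 0.001 otherwise).
#' @return A `threshold_result`: list with `parameter_path`, `criterion`,
#'   `threshold_value`, `bracket`, `tol`, and the criterion values at the
#'   original bracket ends.
#' @export
#' @examples
#' \donttest{
#' threshold_search("costs.endoscopy", "cost_parity", c(10, 400))
#' }
threshold_search <- function(parameter_path, criterion, bracket,
                             params = default_parameters(), tol = NULL) {
  if (is.character(criterion)) {
    crit_name <- criterion
    criterion <- threshold_criteria()[[criterion]]
    if (is.null(criterion)) {
      stop("unknown criterion; built-ins: ",
           paste(names(threshold_criteria()), collapse = ", "), call. = FALSE)
    }
  } else crit_name <- "custom"
  if (length(bracket) != 2 || bracket[1] >= bracket[2]) {
    stop("bracket must be c(low, high) with low < high", call. = FALSE)
  }
  if (is.null(tol)) {
    tol <- if (startsWith(parameter_path, "costs.")) 0.01 else 0.001
  }
  g <- function(v) criterion(set_parameter(params, parameter_path, v))
  lo <- bracket[1]; hi <- bracket[2]
  glo0 <- g(lo); ghi0 <- g(hi)
  if (is.na(glo0) || is.na(ghi0)) stop("criterion not finite at bracket ends",
                                       call. = FALSE)
  if (sign(glo0) == sign(ghi0)) {
    stop("criterion monotone over bracket: no sign change in [",
         lo, ", ", hi, "]", call. = FALSE)
  }
  glo <- glo0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (gm == 0) { lo <- mid; hi <- mid; break }
    if (sign(gm) == sign(glo)) { lo <- mid; glo <- gm } else hi <- mid
  }
  out <- list(parameter_path = parameter_path, criterion = crit_name,
              threshold_value = (lo + hi) / 2, bracket = bracket, tol = tol,
              criterion_at_low = unname(glo0),
              criterion_at_high = unname(ghi0))
  class(out) <- "threshold_result"
  out
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("threshold on %s (criterion: %s): %.6g  [bracket %g..%g, tol %g]\n",
              x$parameter_path, x$criterion, x$threshold_value,
              x$bracket[1], x$bracket[2], x$tol))
  invisible(x)
}

#' Two-way grid over Baveno sensitivity and specificity
#'
#' Evaluates cost-effectiveness of selective vs. universal screening over a
#' grid of the criteria's sensitivity and specificity, flagging cells where
#' selective is cost-effective at the configured WTP (positive incremental
#' NMB, which covers both `ICER <= WTP` and selective-dominant outcomes).
#'
#' @param param_a,param_b Parameter paths for the two axes (defaults:
#'   sensitivity and specificity).
#' @param grid_a,grid_b Numeric grids for each axis (defaults: 41 points
#'   over \[0.80, 1.0\] and \[0.10, 0.50\]).
#' @param params Base `model_parameters`.
#' @param path Optional CSV output path (long format with axes).
#' @return List with `a`, `b` (the grids), `cost_effective` (logical
#'   matrix, rows = `a`), and `inmb` (numeric matrix).
#' @export
two_way_grid <- function(param_a = "accuracy.sensitivity",
                         param_b = "accuracy.specificity",
                         grid_a = seq(0.80, 1.0, length.out = 41),
                         grid_b = seq(0.10, 0.50, length.out = 41),
                         params = default_parameters(), path = NULL) {
  inmb <- matrix(NA_real_, length(grid_a), length(grid_b))
  for (i in seq_along(grid_a)) {
    pa <- set_parameter(params, param_a, grid_a[i])
    for (j in seq_along(grid_b)) {
      res <- base_case(set_parameter(pa, param_b, grid_b[j]))
      inmb[i, j] <- unname(res$nmb["comparator"] - res$nmb["reference"])
    }
  }
  out <- list(a = grid_a, b = grid_b, param_a = param_a, param_b = param_b,
              cost_effective = inmb > 0, inmb = inmb)
  if (!is.null(path)) {
    long <- expand.grid(a = grid_a, b = grid_b)
    long$inmb <- as.vector(inmb)
    long$cost_effective <- long$inmb > 0
    names(long)[1:2] <- c(param_a, param_b)
    utils::write.csv(long, path, row.names = FALSE)
  }
  out
}
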