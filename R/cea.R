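# Incremental cost-effectiveness metrics: ICER, dominance classification,
# net monetary benefit, and the multi-strategy efficiency frontier.

#' Incremental cost-effectiveness of a comparator vs. a reference
#'
#' Incremental values are comparator minus reference. If the comparator is
#' cheaper and more effective it dominates ("comparator dominant"); if more
#' costly and less effective the reference dominates; otherwise the ICER is
#' the cost difference per QALY gained. Equal effectiveness with unequal
#' cost yields an explicit "undefined" flag rather than a division.
#'
#' @param reference,comparator Numeric vectors `c(cost, qaly)` (per-capita
#'   discounted), or `state_trace` objects from [run_cohort()].
#' @param wtp Willingness-to-pay per QALY used for the NMB entries.
#' @return A `cea_result` object: list with `reference`, `comparator`
#'   (cost/qaly pairs), `incremental_cost`, `incremental_qaly`, `icer`
#'   (number, or `NA` when flagged), `dominance` (one of `"none"`,
#'   `"comparator dominant"`, `"reference dominant"`,
#'   `"undefined ICER (equal effectiveness)"`), and `nmb` (named vector).
#' @export
#' @examples
#' compute_icer(c(512, 3.4452), c(581, 3.4780))
compute_icer <- function(reference, comparator, wtp = 12714.11) {
  as_cq <- function(x) {
    if (inherits(x, "state_trace")) c(x$cost_per_capita, x$qaly_per_capita)
    else if (is.numeric(x) && length(x) == 2) unname(x)
    else stop("expected c(cost, qaly) or a state_trace", call. = FALSE)
  }
  ref <- as_cq(reference); cmp <- as_cq(comparator)
  if (!all(is.finite(c(ref, cmp)))) stop("non-finite cost/QALY input", call. = FALSE)
  dc <- cmp[1] - ref[1]
  dq <- cmp[2] - ref[2]
  dominance <- "none"
  icer <- NA_real_
  if (dq == 0) {
    dominance <- "undefined ICER (equal effectiveness)"
  } else if (dc <= 0 && dq >= 0 && !(dc == 0 && dq == 0)) {
    dominance <- "comparator dominant"
    icer <- if (dq > 0) dc / dq else NA_real_
  } else if (dc >= 0 && dq <= 0 && !(dc == 0 && dq == 0)) {
    dominance <- "reference dominant"
    icer <- if (dq < 0) dc / dq else NA_real_
  } else if (dq != 0) {
    icer <- dc / dq
  }
  out <- list(reference = c(cost = ref[1], qaly = ref[2]),
              comparator = c(cost = cmp[1], qaly = cmp[2]),
              incremental_cost = dc,
              incremental_qaly = dq,
              icer = icer,
              dominance = dominance,
              wtp = wtp,
              nmb = c(reference = compute_nmb(ref[1], ref[2], wtp),
                      comparator = compute_nmb(cmp[1], cmp[2], wtp)))
  class(out) <- "cea_result"
  out
}

#' Net monetary benefit
#'
#' `NMB = qaly * wtp - cost`. The strategy with the higher NMB at a given
#' willingness-to-pay is preferred; for positive incremental QALYs,
#' `ICER < wtp` is equivalent to a positive incremental NMB.
#'
#' @param cost,qaly Per-capita discounted cost (USD) and QALYs.
#' @param wtp Willingness-to-pay per QALY (USD, >= 0).
#' @return NMB in USD.
#' @export
compute_nmb <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) stop("wtp must be nonnegative", call. = FALSE)
  qaly * wtp - cost
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("reference:  $%.2f, %.4f QALYs (NMB $%.2f)\n",
              x$reference["cost"], x$reference["qaly"], x$nmb["reference"]))
  cat(sprintf("comparator: $%.2f, %.4f QALYs (NMB $%.2f)\n",
              x$comparator["cost"], x$comparator["qaly"], x$nmb["comparator"]))
  cat(sprintf("incremental: $%.2f, %.4f QALYs\n",
              x$incremental_cost, x$incremental_qaly))
  if (x$dominance == "none") {
    cat(sprintf("ICER: $%.2f per QALY (WTP $%.2f)\n", x$icer, x$wtp))
  } else {
    cat("dominance:", x$dominance, "\n")
  }
  invisible(x)
}

#' Base-case comparison of the two screening strategies
#'
#' Runs both base strategies through the decision tree and cohort engine
#' and returns the incremental comparison of selective vs. universal.
#'
#' @param params A `model_parameters` object.
#' @return A `cea_result` (selective as comparator, universal as
#'   reference), with the two `state_trace` objects attached as
#'   `$traces`.
#' @export
#' @examples
#' base_case(default_parameters())
base_case <- function(params = default_parameters()) {
  uni <- run_cohort("universal", params)
  sel <- run_cohort("selective", params)
  res <- compute_icer(uni, sel, wtp = params$econ$wtp_per_qaly)
  res$traces <- list(universal = uni, selective = sel)
  res
}

#' Results table mirroring the base-case report layout
#'
#' Currency to 2 decimals and QALYs to 4, matching conventional reporting;
#' internal precision is full.
#'
#' @param result A `cea_result` (e.g. from [base_case()]).
#' @param labels Strategy labels for the reference and comparator rows.
#' @param path Optional CSV output path.
#' @return data.frame with cost, incremental cost, effectiveness,
#'   incremental effectiveness, and ICER columns.
#' @export
cea_table <- function(result,
                      labels = c("Universal screening", "Selective screening"),
                      path = NULL) {
  icer_cell <- if (result$dominance == "none") {
    sprintf("%.2f", result$icer)
  } else result$dominance
  df <- data.frame(
    strategy = labels,
    cost = round(c(result$reference["cost"], result$comparator["cost"]), 2),
    incremental_cost = c(NA, round(result$incremental_cost, 2)),
    effectiveness = round(c(result$reference["qaly"], result$comparator["qaly"]), 4),
    incremental_effectiveness = c(NA, round(result$incremental_qaly, 4)),
    icer = c(NA, icer_cell),
    nmb = round(unname(result$nmb), 2),
    row.names = NULL)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' Efficiency frontier over multiple strategies
#'
#' Orders strategies by effectiveness, removes strictly dominated ones
#' (more costly, no more effective) and then extendedly dominated ones
#' (higher ICER than the next transition), and reports sequential ICERs
#' along the frontier. Standard multi-strategy CEA practice, used when the
#' scenario arm is co-plotted with the base strategies.
#'
#' @param results Named list of `c(cost, qaly)` vectors or `state_trace`
#'   objects, one per strategy.
#' @return data.frame with cost, qaly, `on_frontier`, `dominated_by`
#'   (`"strict"`, `"extended"` or `""`), and sequential `icer` for frontier
#'   members (NA for the cheapest).
#' @export
frontier <- function(results) {
  cq <- t(vapply(results, function(x) {
    if (inherits(x, "state_trace")) c(x$cost_per_capita, x$qaly_per_capita)
    else unname(x)
  }, numeric(2)))
  df <- data.frame(strategy = names(results), cost = cq[, 1], qaly = cq[, 2],
                   on_frontier = FALSE, dominated_by = "", icer = NA_real_,
                   row.names = NULL, stringsAsFactors = FALSE)
  ord <- order(df$cost, df$qaly)
  idx <- ord
  # strict dominance
  keep <- rep(TRUE, length(idx))
  best_q <- -Inf
  for (i in seq_along(idx)) {
    if (df$qaly[idx[i]] <= best_q) {
      keep[i] <- FALSE
      df$dominated_by[idx[i]] <- "strict"
    } else best_q <- df$qaly[idx[i]]
  }
  idx <- idx[keep]
  # extended dominance: sequential ICERs must increase
  repeat {
    if (length(idx) < 3) break
    icers <- diff(df$cost[idx]) / diff(df$qaly[idx])
    viol <- which(diff(icers) < 0)
    if (!length(viol)) break
    drop_i <- viol[1] + 1
    df$dominated_by[idx[drop_i]] <- "extended"
    idx <- idx[-drop_i]
  }
  df$on_frontier[idx] <- TRUE
  if (length(idx) > 1) {
    df$icer[idx[-1]] <- diff(df$cost[idx]) / diff(df$qaly[idx])
  }
  df
}
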