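# Publication-style outputs and run bookkeeping: CE-plane and CEAC
# figures, summary writers, and a reproducibility manifest.

#' Cost-effectiveness plane
#'
#' Scatter of per-iteration incremental cost vs. incremental QALYs
#' (selective minus universal) with the WTP line; the deterministic base
#' case is overlaid. With a `cea_result` input, plots the strategy points
#' instead.
#'
#' @param x A `psa_output` or `cea_result`.
#' @param params Model parameters (for the WTP line when `x` is a
#'   `psa_output`).
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(x, params = default_parameters()) {
  if (inherits(x, "psa_output")) {
    df <- x$draws
    df$ce <- df$dqaly * x$wtp - df$dcost > 0
    ggplot2::ggplot(df, ggplot2::aes(x = .data$dqaly, y = .data$dcost,
                                     colour = .data$ce)) +
      ggplot2::geom_point(alpha = 0.25, size = 0.6) +
      ggplot2::geom_abline(intercept = 0, slope = x$wtp, linetype = 2) +
      ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
      ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
      ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "grey60"),
                                   name = "selective cost-effective") +
      ggplot2::labs(x = "Incremental QALYs (selective - universal)",
                    y = "Incremental cost, USD",
                    title = sprintf("CE plane, %d PSA iterations (WTP $%s/QALY)",
                                    x$n_iter, format(x$wtp, big.mark = ","))) +
      ggplot2::theme_minimal()
  } else if (inherits(x, "cea_result")) {
    df <- data.frame(strategy = c("reference", "comparator"),
                     cost = c(x$reference["cost"], x$comparator["cost"]),
                     qaly = c(x$reference["qaly"], x$comparator["qaly"]))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$qaly, y = .data$cost,
                                     label = .data$strategy)) +
      ggplot2::geom_point(size = 2) +
      ggplot2::geom_text(vjust = -1) +
      ggplot2::labs(x = "QALYs per capita", y = "Cost per capita, USD") +
      ggplot2::theme_minimal()
  } else stop("expected a psa_output or cea_result", call. = FALSE)
}

#' Cost-effectiveness acceptability curves
#'
#' @param psa A `psa_output` from [run_psa()].
#' @return A ggplot object with one curve per strategy.
#' @export
plot_ceac <- function(psa) {
  df <- rbind(
    data.frame(wtp = psa$ceac$wtp, p = psa$ceac$p_universal,
               strategy = "universal"),
    data.frame(wtp = psa$ceac$wtp, p = psa$ceac$p_selective,
               strategy = "selective"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wtp, y = .data$p,
                                   colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = psa$wtp, linetype = 2) +
    ggplot2::labs(x = "Willingness-to-pay per QALY, USD",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curves") +
    ggplot2::ylim(0, 1) + ggplot2::theme_minimal()
}

#' Tornado diagram
#'
#' Horizontal bars of incremental NMB at each parameter's range endpoints,
#' ordered by span.
#'
#' @param tor Output of [tornado()].
#' @param top Number of parameters to show (default all).
#' @return A ggplot object.
#' @export
plot_tornado <- function(tor, top = nrow(tor)) {
  df <- utils::head(tor, top)
  df$path <- factor(df$path, levels = rev(df$path))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(y = .data$path, yend = .data$path,
                                       x = .data$inmb_at_low,
                                       xend = .data$inmb_at_high),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::labs(x = "Incremental NMB (selective - universal), USD",
                  y = NULL, title = "One-way sensitivity (tornado)") +
    ggplot2::theme_minimal()
}

#' Write a run manifest
#'
#' Records the command label, a hash of the effective parameter set, the
#' seed(s), package version, timestamp and the list of files the run
#' produced, so that deterministic outputs are reproducible from the
#' manifest alone.
#'
#' @param command Short label of the command that ran.
#' @param params The `model_parameters` used.
#' @param seed Seed(s) used (`NA` for deterministic runs).
#' @param outputs Character vector of output file paths.
#' @param path JSON output path.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(command, params, seed = NA, outputs = character(),
                           path) {
  tab <- .flat_key_table()
  flat <- vapply(seq_len(nrow(tab)), function(i) {
    as.numeric(params[[tab$group[i]]][[tab$field[i]]])
  }, numeric(1))
  manifest <- list(
    command = command,
    config_hash = sprintf("%08x", sum(as.integer(
      utf8ToInt(paste(tab$key, signif(flat, 12), collapse = ";")) %% 97L * 31L))),
    seed = seed,
    package_version = as.character(utils::packageVersion("varistrat")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Strategy summary as a list (for JSON/CSV export)
#'
#' @param trace A `state_trace`.
#' @return List with per-capita discounted totals and the event tally.
#' @export
trace_summary <- function(trace) {
  list(strategy = trace$strategy,
       cost_per_capita = trace$cost_per_capita,
       qaly_per_capita = trace$qaly_per_capita,
       discounted_cost = trace$discounted_cost,
       discounted_qaly = trace$discounted_qaly,
       tally = as.list(trace$tally))
}
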