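#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the threshold-selection curves of a coexpression network
#'
#' Observed and random-expected clustering coefficients against the
#' correlation threshold, with the selected tau* marked.
#'
#' @param object A `coexpression_network` built with curves.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coexpression_network <- function(object, ...) {
  if (is.null(object$curves)) stop("network carries no curves", call. = FALSE)
  long <- tidyr::pivot_longer(object$curves, c("c_obs", "c_rand"),
                              names_to = "curve", values_to = "cc")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tau, y = .data$cc,
                                     colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$tau_star, linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(c_obs = "#1b4f72", c_rand = "#b03a2e"),
      labels = c(c_obs = "observed", c_rand = "random expectation")) +
    ggplot2::labs(x = expression(tau), y = "clustering coefficient",
                  colour = NULL,
                  title = sprintf("Threshold selection (tau* = %.2f)",
                                  object$tau_star)) +
    ggplot2::theme_minimal()
}

#' Plot a Kaplan-Meier curve
#'
#' @param object A `km_curve` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot object (step curve with censoring marks).
#' @export
autoplot.km_curve <- function(object, ...) {
  tt <- tidy(object)
  steps <- dplyr::bind_rows(tibble::tibble(time = 0, survival = 1),
                            tt[, c("time", "survival")])
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = tt[tt$n_censor > 0, ], shape = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "overall survival") +
    ggplot2::theme_minimal()
}

#' Bar plot of winner group-presence patterns
#'
#' @param calls Output of [classify_winner()] (optionally TF-annotated); rows
#'   with `status == "none"` are dropped first.
#' @return A ggplot object.
#' @export
plot_winner_patterns <- function(calls) {
  counts <- categorize_table(dplyr::filter(tibble::as_tibble(calls),
                                           .data$status != "none"))
  counts <- dplyr::filter(counts, .data$group_pattern != "none")
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$group_pattern, y = .data$n)) +
    ggplot2::geom_col(fill = "#1b4f72") +
    ggplot2::labs(x = "disease-group presence", y = "winning genes") +
    ggplot2::theme_minimal()
}

#' Compare survival between expression-defined groups
#'
#' Kaplan-Meier curves for the high and low expression groups of one gene,
#' annotated with the log-rank p-value.
#'
#' @param records Data frame with `time`, `event`, `expression` columns.
#' @param mode Passed to [dichotomize()].
#' @return A ggplot object.
#' @export
plot_km_by_expression <- function(records, mode = "median") {
  grp <- dichotomize(records, mode)
  lr <- logrank_test(grp[grp$group == "high", ], grp[grp$group == "low", ])
  curves <- grp |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ tidy(km_estimate(.x))) |>
    dplyr::ungroup()
  base <- tidyr::crossing(group = unique(grp$group),
                          tibble::tibble(time = 0, survival = 1))
  ggplot2::ggplot(dplyr::bind_rows(base, curves),
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "overall survival",
                  subtitle = sprintf("log-rank p = %.3g%s", lr$p_value,
                                     if (attr(grp, "cutoff_optimized"))
                                       " (cutoff-optimized)" else "")) +
    ggplot2::theme_minimal()
}
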