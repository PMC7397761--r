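#' Plot posterior distributions of a hierarchical fit
#'
#' `type = "rho"` shows the posterior density of each cross-task correlation
#' with its 95% HDI; `type = "mratio"` shows the posterior of the group
#' Mratio (`exp(mu_M)`) per task.
#'
#' @param object An `hmeta_posterior`.
#' @param type `"rho"` or `"mratio"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hmeta_posterior <- function(object, type = c("rho", "mratio"), ...) {
  type <- match.arg(type)
  if (type == "rho") {
    if (is.null(object$draws$rho)) abort("No correlation draws to plot.")
    df <- purrr::map_dfr(seq_len(nrow(object$pairs)), function(p) {
      tibble::tibble(pair = object$pairs$pair[p],
                     value = pooled_draws(object, "rho", p))
    })
    hdis <- object$summary |>
      dplyr::filter(grepl("^rho", .data$term))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
      ggplot2::geom_density(fill = "grey80") +
      ggplot2::geom_vline(xintercept = 0, linetype = 2) +
      ggplot2::facet_wrap(~pair) +
      ggplot2::labs(x = expression(rho ~ "(correlation in log-Mratio)"),
                    y = "posterior density") +
      ggplot2::theme_minimal()
  } else {
    df <- purrr::map_dfr(seq_along(object$tasks), function(t) {
      tibble::tibble(task = object$tasks[t],
                     value = exp(pooled_draws(object, "mu", t)))
    })
    ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$task)) +
      ggplot2::geom_density(alpha = 0.5) +
      ggplot2::geom_vline(xintercept = 1, linetype = 2) +
      ggplot2::labs(x = "group Mratio (meta-d'/d')", y = "posterior density") +
      ggplot2::theme_minimal()
  }
}

#' Plot a recovery report
#'
#' Mean absolute error of the recovered cross-task correlation by method and
#' trial count.
#'
#' @param object A `recovery_report` from [run_recovery()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_report <- function(object, ...) {
  s <- summarize_recovery(object)
  ggplot2::ggplot(s, ggplot2::aes(x = factor(.data$n_trials),
                                  y = .data$mean_abs_error,
                                  fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "trials per task",
                  y = expression("mean |" * hat(rho) - rho[true] * "|"),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Per-subject summary plot
#'
#' Scatter of a subject-level measure across a pair of tasks, the raw
#' material of the nonhierarchical correlation analyses.
#'
#' @param summaries Output of [summarize_subject_tasks()] or
#'   [fit_metad_pointwise()].
#' @param measure Column to plot (e.g. `"dprime"`, `"mean_confidence"`,
#'   `"mratio"`).
#' @param task_x,task_y Task ids for the axes.
#' @return A ggplot object.
#' @export
plot_task_pair <- function(summaries, measure, task_x, task_y) {
  wide <- tidyr::pivot_wider(summaries[c("subject", "task", measure)],
                             names_from = "task",
                             values_from = dplyr::all_of(measure))
  ggplot2::ggplot(wide, ggplot2::aes(x = .data[[task_x]], y = .data[[task_y]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "steelblue") +
    ggplot2::labs(x = paste(measure, "-", task_x),
                  y = paste(measure, "-", task_y)) +
    ggplot2::theme_minimal()
}
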