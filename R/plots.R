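#' Block-wise cooperation curves
#'
#' Mean swerve rate per analysis block, split by opponent, with subject-level
#' spread. The characteristic signature of opponent-sensitive learning is a
#' growing separation between the HCO and LCO curves across blocks.
#'
#' @param trials A trial tibble.
#' @return A ggplot object.
#' @export
plot_cooperation <- function(trials) {
  rates <- block_cooperation_rates(trials)
  summ <- rates |>
    dplyr::filter(!is.na(.data$swerve_rate)) |>
    dplyr::group_by(.data$opponent, .data$block) |>
    dplyr::summarise(mean_rate = mean(.data$swerve_rate),
                     se = sd(.data$swerve_rate) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$block, y = .data$mean_rate,
                                     colour = .data$opponent)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_rate - .data$se,
                                          ymax = .data$mean_rate + .data$se)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Block", y = "Cooperation rate (swerve)",
                  colour = "Opponent") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rl_fit <- function(object, ...) {
  est <- tidy(object, level = "subject")
  est$param <- sub("\\[.*", "", est$term)
  ggplot2::ggplot(est, ggplot2::aes(x = .data$estimate)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey40") +
    ggplot2::facet_wrap(~param, scales = "free_x") +
    ggplot2::labs(title = paste("Subject-level posterior means,",
                                object$model$name),
                  x = "Posterior mean", y = "Subjects") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rl_comparison <- function(object, ...) {
  tab <- object$table
  tab$model <- factor(tab$model, levels = rev(tab$model))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$looic, y = .data$model,
                                    fill = .data$family)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$looic - .data$se_looic,
      xmax = .data$looic + .data$se_looic), height = 0.25) +
    ggplot2::labs(x = "LOOIC (lower is better)", y = NULL,
                  fill = "Family") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rl_ppc <- function(object, ...) {
  series <- tidyr::pivot_longer(object$series, c("observed", "simulated"),
                                names_to = "source", values_to = "rate")
  ggplot2::ggplot(series, ggplot2::aes(x = .data$.opp_pos, y = .data$rate,
                                       colour = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~opponent) +
    ggplot2::labs(x = "Trial (within opponent)",
                  y = "Cooperation rate (swerve)",
                  title = paste("Posterior predictive check,", object$model)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rl_recovery <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$winner, y = .data$generator,
                               fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$prob)),
                       colour = "white") +
    ggplot2::scale_fill_gradient(low = "grey85", high = "grey10",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "Best-fitting model", y = "Generating model",
                  fill = "P(win)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rl_param_recovery <- function(object, ...) {
  ok <- dplyr::filter(object$records, .data$status == "ok")
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$truth, y = .data$recovered)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~param, scales = "free") +
    ggplot2::labs(x = "Ground truth (group level)",
                  y = "Recovered posterior mean",
                  title = paste("Parameter recovery,", object$model)) +
    ggplot2::theme_minimal()
}
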