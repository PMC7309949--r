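#' @export
autoplot.nbd_tornado <- function(object, n_top = 12, ...) {
  base <- attr(object, "base_icer")
  df <- head(object, n_top) %>%
    mutate(path = factor(.data$path, levels = rev(.data$path)),
           lo = pmin(.data$icer_low, .data$icer_high),
           hi = pmax(.data$icer_low, .data$icer_high))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$path)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lo, xend = .data$hi,
                                       yend = .data$path),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = 2) +
    ggplot2::labs(x = "ICER (yen/QALY)", y = NULL,
                  title = "One-way sensitivity analysis (+/-20%)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.nbd_psa <- function(object, wtp = 5e6, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$d_qaly, y = .data$d_cost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6, colour = "steelblue") +
    ggplot2::geom_abline(intercept = 0, slope = wtp, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (yen)",
                  title = "Cost-effectiveness plane",
                  subtitle = sprintf("dashed line: WTP %s yen/QALY", format(wtp))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.nbd_ceac <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$wtp, y = .data$prob_cost_effective)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (yen/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.nbd_utility_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$nbds, y = .data$utility)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$utility - 2 * .data$mc_se,
                                      ymax = .data$utility + 2 * .data$mc_se),
                         fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "NBDS", y = "Expected utility",
                  title = "Mapped EQ-5D-5L utility by NBDS") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.nbd_trace <- function(object, ...) {
  tidy(object) %>%
    mutate(state = factor(.data$state, levels = health_states())) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$age, y = .data$occupancy,
                                 fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Age (years)", y = "State occupancy",
                  title = sprintf("Cohort trace, %s arm", attr(object, "arm"))) +
    ggplot2::theme_minimal()
}
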