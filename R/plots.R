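# ggplot2 displays for session logs, activation timecourses and
# sensitivity tables.

#' Plot ball position and PDA timecourses of a session
#'
#' @param object an `npda_session`.
#' @param ... unused.
#' @return a ggplot: per-feedback-run ball trajectory with hits marked.
#' @export
autoplot.npda_session <- function(object, ...) {
  logs <- dplyr::bind_rows(object$logs, .id = "run")
  logs$run <- factor(as.integer(logs$run))
  ggplot2::ggplot(logs, ggplot2::aes(x = .data$volume, y = .data$ball_y)) +
    ggplot2::geom_line(color = "grey30") +
    ggplot2::geom_point(
      data = dplyr::filter(logs, .data$hit),
      color = "red", size = 1.5
    ) +
    ggplot2::facet_wrap(~run, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "volume", y = "ball position",
      title = "Feedback ball trajectories (hits in red)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an activation (PDA) timecourse
#'
#' @param samples tibble of activation samples (`volume`, `z_dmn`, `z_fpn`,
#'   `pda`, `outlier`).
#' @return a ggplot of the three traces with outliers marked.
#' @export
plot_activation <- function(samples) {
  long <- tidyr::pivot_longer(
    samples, c("z_dmn", "z_fpn", "pda"),
    names_to = "signal", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$volume, y = .data$value,
                                     color = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = dplyr::filter(long, .data$outlier), shape = 4
    ) +
    ggplot2::labs(x = "volume", y = "activation (baseline SD)",
                  title = "Network activation and PDA") +
    ggplot2::theme_minimal()
}

#' Plot an MNAR sensitivity table
#'
#' @param sens tibble from [mnar_sensitivity()].
#' @return a ggplot of the focal estimate (with CI) against the
#'   replacement shift.
#' @export
plot_mnar_sensitivity <- function(sens) {
  ggplot2::ggplot(sens, ggplot2::aes(x = .data$shift, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "replacement shift (SD)", y = "focal estimate",
                  title = "MNAR sensitivity of the focal coefficient") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
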