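#' Plot PSA results
#'
#' `autoplot()` on an `lcs_psa` object draws either the cost-effectiveness
#' plane (one point per iteration: incremental QALYs vs incremental cost,
#' with the willingness-to-pay threshold as a dashed line through the
#' origin) or the cost-effectiveness acceptability curve (probability
#' cost-effective against the threshold grid, with the default threshold
#' marked).
#'
#' @param object an `lcs_psa` object from [run_psa()].
#' @param type `"ce_plane"` (default) or `"ceac"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.lcs_psa <- function(object, type = c("ce_plane", "ceac"), ...) {
  type <- match.arg(type)
  if (type == "ce_plane") {
    plot_ce_plane(object)
  } else {
    plot_ceac(object)
  }
}

#' @rdname autoplot.lcs_psa
#' @param psa an `lcs_psa` object.
#' @export
plot_ce_plane <- function(psa) {
  it <- psa$iterations
  wtp <- psa$wtp_threshold
  ggplot2::ggplot(it, ggplot2::aes(x = .data$d_qalys, y = .data$d_cost_total)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_abline(
      slope = wtp, intercept = 0,
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8, colour = "#2c7fb8") +
    ggplot2::labs(
      x = "Incremental QALYs per participant",
      y = "Incremental cost (EUR) per participant",
      title = "Cost-effectiveness plane",
      subtitle = sprintf(
        "%d PSA iterations; dashed line: EUR %s per QALY",
        nrow(it), format(wtp, big.mark = ",")
      )
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.lcs_psa
#' @export
plot_ceac <- function(psa) {
  ggplot2::ggplot(
    psa$ceac,
    ggplot2::aes(x = .data$threshold, y = .data$prob_cost_effective)
  ) +
    ggplot2::geom_line(colour = "#2c7fb8", linewidth = 0.9) +
    ggplot2::geom_vline(
      xintercept = psa$wtp_threshold,
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1), labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(
      x = "Willingness-to-pay threshold (EUR per QALY)",
      y = "Probability cost-effective",
      title = "Cost-effectiveness acceptability curve"
    ) +
    ggplot2::theme_minimal()
}
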