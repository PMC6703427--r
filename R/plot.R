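#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a chain-length energy scan
#'
#' Per-mol-alkane (default) or per-electron Gibbs energy against chain
#' length, with the exergonicity threshold at zero.
#'
#' @param object An `alk_chain_scan` from [chain_scan()].
#' @param quantity Column to plot: `"per_mol_alkane_kJ"` or
#'   `"per_electron_kJ"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot alk_chain_scan
#' @export
autoplot.alk_chain_scan <- function(object,
                                    quantity = c("per_mol_alkane_kJ",
                                                 "per_electron_kJ"), ...) {
  quantity <- match.arg(quantity)
  lab <- if (quantity == "per_mol_alkane_kJ") {
    expression(Delta * G * minute ~ "(kJ per mol alkane)")
  } else {
    expression(Delta * G * minute ~ "(kJ per mol" ~ e^"-" * ")")
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n, y = .data[[quantity]])) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "alkane chain length n (carbon atoms)", y = lab,
                  title = unique(object$fate)) +
    ggplot2::theme_minimal()
}

#' Plot a feasibility screen
#'
#' Histogram of per-scenario in-situ Gibbs energies (per mol alkane) with
#' the exergonicity threshold marked.
#'
#' @param object A `feasibility_summary` from [feasibility_screen()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot feasibility_summary
#' @export
autoplot.feasibility_summary <- function(object, ...) {
  details <- tidy(object)
  ggplot2::ggplot(details,
                  ggplot2::aes(x = .data$dG_per_mol_alkane_kJ,
                               fill = .data$exergonic)) +
    ggplot2::geom_histogram(bins = 40, show.legend = TRUE) +
    ggplot2::geom_vline(xintercept = object$threshold_kJ,
                        linetype = "dashed") +
    ggplot2::labs(
      x = expression(Delta * G["in-situ"] ~ "(kJ per mol alkane)"),
      y = "scenarios",
      title = sprintf("%s, n=%d: %.1f%% of %d scenarios exergonic",
                      object$fate, object$n,
                      100 * object$fraction_exergonic, object$n_scenarios)) +
    ggplot2::theme_minimal()
}
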