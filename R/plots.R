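#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a voltage trace
#'
#' @param object a `trace`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.trace <- function(object, ...) {
  st <- attr(object, "stimulus")
  ggplot2::ggplot(object, ggplot2::aes(.data$time_ms, .data$v_mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)",
                  subtitle = if (!is.null(st))
                    sprintf("bias %.0f pA, step %.0f pA (%.0f ms)",
                            st$bias_pA, st$step_pA, st$dur_ms)) +
    ggplot2::theme_minimal()
}

#' Plot an F-I curve with its Boltzmann fit
#'
#' @param object an `fi_fit`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.fi_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(.data$current_pA, .data$rate_Hz)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "injected current (pA)", y = "firing rate (Hz)") +
    ggplot2::theme_minimal()
  if (object$converged) {
    grid <- tibble::tibble(
      current_pA = seq(min(object$data$current_pA),
                       max(object$data$current_pA), length.out = 200))
    grid$rate_Hz <- object$fmax /
      (1 + exp((object$i_half - grid$current_pA) / object$k))
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick")
  }
  p
}

#' Sag percentage versus step amplitude across conditions
#'
#' @param sag_table tibble with columns `step_pA`, `sag_percent` and
#'   optionally `condition`.
#' @return A ggplot.
#' @export
plot_sag_curve <- function(sag_table) {
  aes <- if ("condition" %in% names(sag_table))
    ggplot2::aes(-.data$step_pA, .data$sag_percent,
                 colour = .data$condition) else
    ggplot2::aes(-.data$step_pA, .data$sag_percent)
  ggplot2::ggplot(sag_table, aes) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "hyperpolarizing step (pA)", y = "sag (%)") +
    ggplot2::theme_minimal()
}

#' Cohort feature distributions by condition
#'
#' @param result a [run_cohort()] result.
#' @param features which feature columns to show.
#' @return A ggplot.
#' @export
plot_cohort <- function(result,
                        features = c("rheobase3_pA", "vrest_mV",
                                     "rebound_spikes", "sag_percent")) {
  long <- result$features |>
    dplyr::filter(!.data$failed) |>
    tidyr::pivot_longer(dplyr::all_of(features), names_to = "feature")
  ggplot2::ggplot(long, ggplot2::aes(.data$condition, .data$value)) +
    ggplot2::geom_boxplot(outliers = FALSE) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 0.8) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
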