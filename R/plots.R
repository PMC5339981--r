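#' Scatter and Bland-Altman panels for one parameter
#'
#' Left panel: each CMR mode against the reference with the identity line;
#' right panel: Bland-Altman differences with bias and 95% limits of
#' agreement per mode.
#'
#' @param reports Cohort report tibble (see [cohort_table()]).
#' @param parameter One of `Vmean`, `Vpeak`, `MG`, `PG`, `VTI`, `SV`,
#'   `AVA_Cine`, `AVA_Flow`.
#' @return A ggplot object (two facets).
#' @export
plot_method_comparison <- function(reports, parameter) {
  col <- .comparison_parameters[[parameter]]
  if (is.null(col)) stop("unknown parameter: ", parameter)
  ref <- .reference_values(reports, parameter)
  m1 <- dplyr::filter(reports, .data$method == "1Dir")
  m3 <- dplyr::filter(reports, .data$method == "3Dir")
  m3 <- m3[match(m1$subject, m3$subject), ]
  df <- dplyr::bind_rows(
    tibble::tibble(subject = m1$subject, method = "1Dir",
                   value = m1[[col]], reference = ref),
    tibble::tibble(subject = m1$subject, method = "3Dir",
                   value = m3[[col]], reference = ref))
  df <- dplyr::filter(df, is.finite(.data$value) & is.finite(.data$reference))
  df <- dplyr::mutate(df, mean_mr = (.data$value + .data$reference) / 2,
                      diff_mr = .data$value - .data$reference)
  ba <- df |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(bias = mean(.data$diff_mr), sd = stats::sd(.data$diff_mr),
                     .groups = "drop")
  units <- .parameter_units[[parameter]]
  ref_lab <- if (parameter == "SV") "cine SV" else "TTE"

  scat <- ggplot2::ggplot(df, ggplot2::aes(.data$reference, .data$value,
                                           colour = .data$method)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = sprintf("%s (%s, %s)", parameter, ref_lab, units),
                  y = sprintf("%s (CMR, %s)", parameter, units),
                  colour = NULL) +
    ggplot2::theme_minimal()

  bland <- ggplot2::ggplot(df, ggplot2::aes(.data$mean_mr, .data$diff_mr,
                                            colour = .data$method)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_hline(data = ba,
                        ggplot2::aes(yintercept = .data$bias,
                                     colour = .data$method),
                        linetype = 1) +
    ggplot2::geom_hline(data = ba,
                        ggplot2::aes(yintercept = .data$bias + 1.96 * .data$sd,
                                     colour = .data$method), linetype = 3) +
    ggplot2::geom_hline(data = ba,
                        ggplot2::aes(yintercept = .data$bias - 1.96 * .data$sd,
                                     colour = .data$method), linetype = 3) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = sprintf("mean of methods (%s)", units),
                  y = sprintf("CMR - %s (%s)", ref_lab, units),
                  colour = NULL) +
    ggplot2::theme_minimal()

  patchwork::wrap_plots(scat, bland, ncol = 2) +
    patchwork::plot_annotation(title = parameter)
}

#' Plot a flow comparison table
#'
#' Correlation coefficients with 95% confidence intervals per parameter and
#' CMR mode — the at-a-glance view of which mode agrees better with the
#' reference.
#'
#' @param object A `flow_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flow_comparison
#' @export
autoplot.flow_comparison <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$parameter, .data$r,
                                   colour = .data$method)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Pearson r (95% CI) vs reference",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a peak-velocity curve
#'
#' @param object A `peak_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot peak_curve
#' @export
autoplot.peak_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t, .data$v)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (ms)", y = "peak velocity (cm/s)") +
    ggplot2::theme_minimal()
}
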