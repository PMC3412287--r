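#' Plot a simulation summary
#'
#' Dot-and-interval display of the mean estimate per strategy and
#' parameter with ±2 Monte-Carlo-SE bars, faceted by parameter, with the
#' nominal truth as a dashed reference line.
#'
#' @param object An `ipwmi_summary` from [run_study()].
#' @param truth Named numeric vector of reference values per term
#'   (optional).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ipwmi_summary <- function(object,
                                   truth = c("(Intercept)" = -3, X2 = 0.5,
                                             X3 = 0.5, `X2:X3` = 1), ...) {
  df <- dplyr::mutate(object, method = factor(method, unique(method)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = mean_est, y = method)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = mean_est - 2 * mcse_mean,
                   xmax = mean_est + 2 * mcse_mean),
      height = 0.2
    ) +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::labs(x = "mean estimate (± 2 Monte-Carlo SE)", y = NULL)
  if (!is.null(truth)) {
    ref <- tibble::tibble(term = names(truth), truth = unname(truth))
    ref <- ref[ref$term %in% unique(df$term), ]
    p <- p + ggplot2::geom_vline(data = ref,
                                 ggplot2::aes(xintercept = truth),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' @export
plot.ipwmi_summary <- function(x, ...) print(autoplot(x, ...))

#' Coefficient plot for a pooled fit
#'
#' @param object A `pooled_fit`.
#' @param conf_level Interval coverage (normal reference). Default 0.95.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pooled_fit <- function(object, conf_level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  df <- tidy(object) |>
    dplyr::mutate(conf.low = estimate - z * std.error,
                  conf.high = estimate + z * std.error,
                  term = factor(term, rev(unique(term))))
  ggplot2::ggplot(df, ggplot2::aes(x = estimate, y = term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = conf.low, xmax = conf.high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted", colour = "grey50") +
    ggplot2::labs(x = "pooled estimate", y = NULL)
}

#' @export
plot.pooled_fit <- function(x, ...) print(autoplot(x, ...))
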