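interval_plot <- function(iv, ylab) {
  iv$label <- if (!is.null(iv$name)) iv$name else as.character(iv$region)
  iv$label <- factor(iv$label, levels = iv$label)
  ggplot2::ggplot(iv, ggplot2::aes(x = .data$label)) +
    ggplot2::geom_linerange(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi,
                   linewidth = .data$flag != "null"),
      colour = "steelblue4"
    ) +
    ggplot2::scale_linewidth_manual(values = c(`FALSE` = 0.5, `TRUE` = 1.4),
                                    guide = "none") +
    ggplot2::geom_point(ggplot2::aes(y = .data$post_mean),
                        colour = "steelblue4", size = 1) +
    ggplot2::geom_point(ggplot2::aes(y = .data$a, colour = "null (resels)"),
                        shape = 16, size = 2) +
    ggplot2::scale_colour_manual(NULL, values = c("null (resels)" = "forestgreen")) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot penalised credible intervals of a fixed-effects fit
#'
#' Regional posterior intervals on the pattern parameters with the null
#' relative resel counts overlaid; intervals excluding the null are drawn
#' bold.
#'
#' @param object an `ffx_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ffx_fit <- function(object, ...) {
  if (is.null(object$intervals)) stop("fit has no interval component")
  interval_plot(tidy(object),
                sprintf("event proportion (penalised %g%% interval)",
                        100 * object$x))
}

#' Plot penalised credible intervals of a random-effects fit
#'
#' @param object an `rfx_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.rfx_fit <- function(object, ...) {
  interval_plot(tidy(object),
                sprintf("population mean proportion (penalised %g%% interval)",
                        100 * object$x))
}

#' Plot a family-wise error report
#'
#' Observed FWER per partition size with its binomial 95% interval and the
#' conventional 0.05 reference line.
#'
#' @param object a `fwer_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.fwer_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  se <- sqrt(pmax(df$fwer * (1 - df$fwer), 1e-12) / df$L)
  df$lo <- pmax(df$fwer - 2 * se, 0)
  df$hi <- df$fwer + 2 * se
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$N), y = .data$fwer)) +
    ggplot2::geom_col(fill = "steelblue4", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.15) +
    ggplot2::geom_hline(yintercept = 0.05, linetype = 2, colour = "firebrick") +
    ggplot2::labs(x = "partition size N", y = "family-wise error rate",
                  title = sprintf("%s inference under the null",
                                  toupper(df$mode[1]))) +
    ggplot2::theme_minimal()
}
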