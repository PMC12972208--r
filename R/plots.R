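#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_point geom_vline
#'   geom_line labs theme_bw scale_y_continuous
NULL

#' Plot a Kaplan-Meier curve
#'
#' @param object A `km_curve` from [km_estimate()], or the stacked two-group
#'   `km` tibble of a `cutoff_scan`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  p <- if ("group" %in% names(object))
    ggplot(object, aes(x = .data$time, y = .data$survival, colour = .data$group))
  else
    ggplot(object, aes(x = .data$time, y = .data$survival))
  p + geom_step() +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "Time (months)", y = "Survival probability") +
    theme_bw()
}

#' Plot the p-value profile of a cutoff scan
#'
#' Shows -log10 of the log-rank p-value at every candidate cutoff in the
#' interquartile window, with the selected minimum-p cutoff marked.
#'
#' @param object A `cutoff_scan` from [scan_cutoffs()].
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot cutoff_scan
#' @export
autoplot.cutoff_scan <- function(object, ...) {
  ggplot(object$candidates, aes(x = .data$cutoff, y = -log10(.data$p_value))) +
    geom_line() + geom_point(size = 0.8) +
    geom_vline(xintercept = object$cutoff, linetype = "dashed") +
    labs(x = "Candidate cutoff (score)", y = "-log10 log-rank p",
         subtitle = sprintf("selected cutoff %.4g, p = %.3g (unadjusted minimum)",
                            object$cutoff, object$p_value)) +
    theme_bw()
}

#' Plot the Kaplan-Meier curves of a selected split
#'
#' @param scan A `cutoff_scan`.
#' @return A ggplot of the high- and low-score group curves.
#' @export
plot_km_split <- function(scan) {
  stopifnot(inherits(scan, "cutoff_scan"))
  km <- scan$km
  class(km) <- c("km_curve", class(km))
  autoplot(km) +
    labs(subtitle = sprintf("high vs low HR = %.3g [%.3g, %.3g], log-rank p = %.3g",
                            scan$fit$terms$hr, scan$fit$terms$ci_low,
                            scan$fit$terms$ci_high, scan$p_value))
}
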