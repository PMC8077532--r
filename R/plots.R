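#' Plot an hourly activity (or rest) profile
#'
#' Line plot over zeitgeber time with the dark phase shaded, in the style of
#' a 24 h activity-profile panel.
#'
#' @param object a `cf_hourly` profile from [bin_hourly()].
#' @param pp a [photoperiod()] used for the dark shading.
#' @param ... unused.
#' @return a ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.cf_hourly <- function(object, pp = photoperiod(), ...) {
  dark <- tibble(xmin = pp$lights_off, xmax = pp$cycle_length)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$zt + 0.5, y = .data$value)) +
    ggplot2::annotate("rect", xmin = dark$xmin, xmax = dark$xmax,
                      ymin = -Inf, ymax = Inf, alpha = 0.15) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(breaks = seq(0, pp$cycle_length, by = 4)) +
    ggplot2::labs(x = "Zeitgeber time (h)", y = "Activity (cm/h)") +
    ggplot2::theme_minimal()
}

#' Plot hourly profiles for several animals or species
#'
#' @param profiles named list of `cf_hourly` profiles (names become panel
#'   labels).
#' @param pp a [photoperiod()].
#' @return a ggplot, faceted by profile name.
#' @export
plot_activity_profiles <- function(profiles, pp = photoperiod()) {
  df <- list_rbind(map2(profiles, names(profiles),
                        function(p, nm) mutate(as_tibble(p), id = nm)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$zt + 0.5, y = .data$value)) +
    ggplot2::annotate("rect", xmin = pp$lights_off, xmax = pp$cycle_length,
                      ymin = -Inf, ymax = Inf, alpha = 0.15) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~id, scales = "free_y") +
    ggplot2::labs(x = "Zeitgeber time (h)", y = "Activity (cm/h)") +
    ggplot2::theme_minimal()
}

#' Plot a phylogenetic regression
#'
#' Scatter of the response against the predictor with the PGLS fit line.
#'
#' @param object a `cf_pgls`.
#' @param ... unused.
#' @return a ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.cf_pgls <- function(object, ...) {
  pred_var <- attr(stats::terms(object$formula), "term.labels")[1]
  resp_var <- all.vars(object$formula)[1]
  df <- object$data
  b <- object$coefficients
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[pred_var]],
                                   y = .data[[resp_var]])) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = b[["(Intercept)"]], slope = b[[pred_var]]) +
    ggplot2::labs(
      subtitle = sprintf("PGLS: lambda = %.2f, R2 = %.2f",
                         object$lambda, object$r.squared)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
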