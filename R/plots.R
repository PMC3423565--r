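#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-stratum survival of a cohort summary
#'
#' Bar chart of survival percentage per (category, treatment) stratum,
#' faceted by hepatitis status; the survey's headline structure at a
#' glance.
#'
#' @param object an `alf_cohort_summary` from [summarize_cohort()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot alf_cohort_summary
#' @export
autoplot.alf_cohort_summary <- function(object, ...) {
  d <- object$survival
  d$category <- factor(d$category,
                       levels = c("no_coma", "acute", "subacute", "lohf"))
  d$hepatitis <- ifelse(d$hepatitis, "with hepatitis", "without hepatitis")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$percent,
                                  fill = .data$treatment)) +
    ggplot2::geom_col(position = ggplot2::position_dodge2(preserve = "single")) +
    ggplot2::facet_wrap(ggplot2::vars(.data$hepatitis)) +
    ggplot2::labs(x = "diagnosis category", y = "survival (%)",
                  fill = "treatment",
                  title = "Survival by ALF stratum") +
    ggplot2::ylim(0, 100)
}

#' Plot the distribution of prognostic total scores
#'
#' Histogram of total scores coloured by the death call, with a dashed line
#' at the death threshold (a total at or beyond the line is called
#' "death").
#'
#' @param scores output of [score_prognosis()].
#' @param config the [alf_config()] used for scoring (for the threshold).
#' @return a ggplot object.
#' @export
plot_score_distribution <- function(scores, config = alf_config()) {
  assert_columns(scores, c("total", "predicted_death"))
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$total,
                                       fill = .data$predicted_death)) +
    ggplot2::geom_bar() +
    ggplot2::geom_vline(xintercept = config$death_threshold - 0.5,
                        linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = 0:11, limits = c(-0.5, 11.5)) +
    ggplot2::labs(x = "prognostic total score", y = "patients",
                  fill = "death call",
                  title = "Prognostic score distribution")
}

#' Plot predicted-mortality bands
#'
#' Step plot of the published predicted-mortality band against the total
#' score: the band's lower and upper bounds as a ribbon over scores 0-11.
#'
#' @return a ggplot object.
#' @export
plot_mortality_bands <- function() {
  d <- mortality_band(0:11)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$total)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower_percent,
                                      ymax = .data$upper_percent),
                         fill = "firebrick", alpha = 0.4) +
    ggplot2::scale_x_continuous(breaks = 0:11) +
    ggplot2::labs(x = "prognostic total score",
                  y = "predicted mortality (%)",
                  title = "Predicted-mortality bands")
}
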