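#' Monthly song-median INI plot
#'
#' Per-song median INI with 25th/75th-quartile whiskers by month,
#' coloured by song year -- the standard view of seasonal short/long
#' INI patterning.
#'
#' @param summaries A song-summary tibble from [summarize_song()].
#' @return A ggplot object.
#' @export
plot_monthly_ini <- function(summaries) {
  # display on a July-June song-year axis
  disp <- dplyr::mutate(summaries,
                        month_sy = ((.data$month - 7) %% 12) + 1,
                        song_year = factor(.data$song_year))
  ggplot2::ggplot(disp, ggplot2::aes(x = .data$month_sy,
                                     y = .data$median_ini,
                                     colour = .data$song_year)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q25,
                                          ymax = .data$q75),
                             position = ggplot2::position_dodge(width = 0.5),
                             size = 0.3) +
    ggplot2::scale_x_continuous(breaks = 1:12,
                                labels = c("Jul", "Aug", "Sep", "Oct", "Nov",
                                           "Dec", "Jan", "Feb", "Mar", "Apr",
                                           "May", "Jun")) +
    ggplot2::labs(x = "Month (song year, July-June)",
                  y = "Song median INI (s)", colour = "Song year") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_ini_model Plot monthly predictions with their 95%
#'   band for each observed song year.
#' @method autoplot fw_trend_fit
#' @export
autoplot.fw_trend_fit <- function(object, ...) {
  years <- sort(unique(object$data$song_year))
  pred <- dplyr::bind_rows(lapply(years, function(y) {
    predict_monthly(object, y)
  }))
  pred$song_year <- factor(pred$song_year)
  ggplot2::ggplot(pred, ggplot2::aes(x = .data$month, y = .data$fit)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~song_year) +
    ggplot2::scale_x_continuous(breaks = seq(1, 12, 2)) +
    ggplot2::labs(x = "Month", y = sprintf("Predicted %s", object$response)) +
    ggplot2::theme_minimal()
}
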