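# End-to-end parameter-recovery driver: synthetic deployment ->
# waveform -> spectrogram measurements -> song filters -> INI filter ->
# pooled period means. Used by tests and by the acceptance script.

period_month_range <- function(period) {
  if (period == "short") c(9, 12) else c(3, 5)
}

# Calendar range of a period within a song year (song year 1 starts
# July 2016).
period_date_range <- function(song_year, period,
                              first_july = as.Date("2016-07-01")) {
  start_year <- lubridate::year(first_july) + song_year - 1
  m <- period_month_range(period)
  cal_year <- if (m[1] >= 7) start_year else start_year + 1
  from <- as.Date(sprintf("%d-%02d-01", cal_year, m[1]))
  to <- lubridate::ceiling_date(
    as.Date(sprintf("%d-%02d-01", cal_year, m[2])), "month") - 1
  c(from, to)
}

#' Run one song-year period end-to-end and recover its pooled mean INI
#'
#' Generates a synthetic deployment for the period's months (song
#' counts and generator INI means from the song-year preset), streams
#' each song day's recording through [measure_notes()], applies the
#' song filters and INI range filter, and pools the period mean.
#'
#' @param song_year Song year (1-5) whose preset parameterises the
#'   generator.
#' @param period `"short"` (September-December) or `"long"`
#'   (March-May).
#' @param seed Root seed for the deployment.
#' @param pattern Generator pattern (`"seasonal"`, or
#'   `"constant_long"` for the song-year-4 regime).
#' @param ... Further arguments to [deployment_spec()].
#' @return A list: `recovered` (the [period_means()] row), `truth_mean`
#'   (mean of kept truth INIs), `songs`, `inis`, `n_excluded`.
#' @export
recover_period_mean <- function(song_year, period, seed = 1,
                                pattern = if (song_year == 4) "constant_long" else "seasonal",
                                ...) {
  dr <- period_date_range(song_year, period)
  spec <- deployment_spec(date_range = dr, pattern = pattern,
                          song_year = song_year, seed = seed, ...)
  meas <- list()
  truth <- list()
  dep <- make_deployment(spec, sink = function(rec, rows) {
    if (is.null(rows)) return(invisible())
    sel <- truth_as_selections(rows)
    m <- measure_notes(rec, sel)
    m$singer <- m$Singer
    meas[[length(meas) + 1]] <<- m
    truth[[length(truth) + 1]] <<- rows
  })
  meas <- dplyr::bind_rows(meas)
  truth <- dplyr::bind_rows(truth)
  songs <- build_songs(meas)
  inis <- compute_inis(songs)
  pm <- period_means(inis, period = period, song_years = song_year)
  truth_kept <- truth$true_ini[!is.na(truth$true_ini) &
                                 truth$true_ini >= 4.5 & truth$true_ini <= 30]
  list(recovered = pm, truth_mean = mean(truth_kept),
       songs = songs, inis = inis,
       n_excluded = sum(!songs$included))
}
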