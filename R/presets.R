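# Study-condition presets for the synthetic deployment generator.
#
# Period means and song counts are parameterised from the New York Bight
# 2017-2020 monitoring results: per song year, the short-INI period
# (September-December) and long-INI period (March-May) pooled mean INIs
# and song counts, and the per-month song counts of the review effort.
# Song years run July 1 - June 30 and are numbered 1 (2016-2017) through
# 5 (2020-2021).

#' Reference period means by song year
#'
#' Pooled mean (+/- s.e.m.) short- and long-period INIs and song counts
#' for New York Bight song years 1-5. These parameterise the
#' [deployment_spec()] presets. `NA` marks periods with no data.
#'
#' @return A tibble with columns `song_year`, `short_mean`, `short_sem`,
#'   `short_n_songs`, `long_mean`, `long_sem`, `long_n_songs`.
#' @export
period_mean_reference <- function() {
  tibble::tribble(
    ~song_year, ~short_mean, ~short_sem, ~short_n_songs, ~long_mean, ~long_sem, ~long_n_songs,
    1L,          NA_real_,    NA_real_,   NA_integer_,    15.68,      0.09,      13L,
    2L,          9.92,        0.04,       16L,            15.38,      0.1,       5L,
    3L,          9.75,        0.02,       36L,            15.67,      0.04,      11L,
    4L,          14.78,       0.04,       39L,            15.90,      0.09,      5L,
    5L,          9.84,        0.02,       34L,            NA_real_,   NA_real_,  NA_integer_
  )
}

#' Reference per-month song counts by song year
#'
#' Number of analysed songs per calendar month and song year in the New
#' York Bight review effort; used by the generator presets to decide how
#' many song days each month receives. `NA` marks months with no
#' archived recordings.
#'
#' @return A tibble with columns `month` (1-12), `song_year`, `n_songs`.
#' @export
song_count_reference <- function() {
  counts <- nyb_song_counts()
  dplyr::select(counts, "month", "song_year", n_songs = "songs")
}

# Monthly generator INI means for a song year under a pattern preset.
#
# SEASONAL: short-period mean in Sep-Dec, long-period mean in Mar-Jun,
# linear interpolation with inflated jitter through the transition
# months (Jan-Feb short->long, Jul-Aug long->short).
#
# CONSTANT_LONG: long INIs in every month. For the song-year-4 regime
# the September-February mean is calibrated so that the Sep-Dec pooled
# truth mean -- long-INI majority plus the short-INI intruder songs
# (1 in October, 2 in November at `intruder_mean`) with equal kept-INI
# counts per song -- equals the reference short-period cell for that
# year; March-May sit at the reference long-period mean.
preset_monthly_ini <- function(pattern = c("seasonal", "constant_long"),
                               song_year = 2,
                               stable_jitter = 0.3, transition_jitter = 1.5,
                               intruder_mean = 9.9) {
  pattern <- match.arg(pattern)
  ref <- period_mean_reference()
  row <- ref[ref$song_year == song_year, ]
  if (nrow(row) != 1) abort("unknown song year for preset")
  typical <- list(short = mean(ref$short_mean[ref$short_mean < 12], na.rm = TRUE),
                  long = mean(ref$long_mean, na.rm = TRUE))
  s <- if (is.na(row$short_mean) || row$short_mean > 12) typical$short else row$short_mean
  l <- if (is.na(row$long_mean)) typical$long else row$long_mean
  month <- 1:12
  if (pattern == "seasonal") {
    mean_by_month <- dplyr::case_when(
      month %in% 9:12 ~ s,
      month %in% 3:6 ~ l,
      month == 1 ~ s + (l - s) / 3,
      month == 2 ~ s + 2 * (l - s) / 3,
      month == 7 ~ s + 2 * (l - s) / 3,
      month == 8 ~ s + (l - s) / 3
    )
    jitter <- ifelse(month %in% c(1, 2, 7, 8), transition_jitter, stable_jitter)
    intruder <- rep(0L, 12)
  } else {
    n_short_period <- row$short_n_songs          # total Sep-Dec songs incl. intruders
    n_intruder <- 3L
    cal <- (n_short_period * row$short_mean - n_intruder * intruder_mean) /
      (n_short_period - n_intruder)
    mean_by_month <- dplyr::case_when(
      month %in% c(9:12, 1, 2) ~ cal,
      month %in% 3:6 ~ l,
      TRUE ~ cal
    )
    jitter <- ifelse(month %in% 7:8, transition_jitter, stable_jitter)
    intruder <- ifelse(month == 10, 1L, ifelse(month == 11, 2L, 0L))
  }
  tibble::tibble(month = month, ini_mean = mean_by_month,
                 ini_jitter_sd = jitter,
                 n_intruder = intruder, intruder_mean = intruder_mean)
}
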