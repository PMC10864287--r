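# Song construction, inclusion filters, INI computation and summaries.
#
# Filter order is fixed: song duration (>= 2 min) -> song mean SNR
# (>= 10 dB) -> INI range filter ([4.5, 30] s). The order matters for
# the audit counts.

#' Song-year of a date
#'
#' Song years align with the singing season and run July 1 - June 30.
#' Year 1 spans July 2016 - June 2017; the default study range covers
#' years 1-5 (through June 2021). Dates outside the range are an error.
#'
#' @param date A `Date` (or something coercible).
#' @param first_july First July 1 of song year 1.
#' @param n_years Number of song years in range.
#' @return Integer song-year label(s).
#' @export
assign_song_year <- function(date, first_july = as.Date("2016-07-01"),
                             n_years = 5) {
  date <- as.Date(date)
  yr0 <- lubridate::year(first_july)
  sy <- lubridate::year(date) - yr0 + (lubridate::month(date) >= 7)
  if (any(is.na(sy)) || any(sy < 1) || any(sy > n_years)) {
    abort(sprintf("date out of study range (%s to %s)",
                  format(first_july),
                  format(first_july + lubridate::years(n_years) - 1)))
  }
  as.integer(sy)
}

#' Assemble songs from note measurements and apply inclusion filters
#'
#' One song per singer (singer ids are recording dates, so one song per
#' day). Songs are excluded, with machine-readable reasons, when their
#' duration (last note end minus first note begin) is under
#' `min_duration` seconds or their mean SNR over unflagged notes is
#' under `min_snr` dB.
#'
#' @param meas A measurement tibble from [measure_notes()] with a
#'   `singer` column (see [assign_singer_ids()]) and a `date` or
#'   parseable singer id.
#' @param min_duration Minimum song duration, seconds.
#' @param min_snr Minimum mean song SNR, dB.
#' @param first_july,n_years Passed to [assign_song_year()].
#' @return A tibble with one row per song: `song_id`, `singer`, `date`,
#'   `month`, `song_year`, `recording_id`, `n_notes`, `duration`,
#'   `mean_snr`, `included`, `exclusion_reason`, and a `notes`
#'   list-column of the song's time-ordered measurements.
#' @export
build_songs <- function(meas, min_duration = 120, min_snr = 10,
                        first_july = as.Date("2016-07-01"), n_years = 5) {
  if (!"singer" %in% names(meas)) abort("`meas` must carry a `singer` column")
  meas <- dplyr::arrange(meas, .data$singer, .data$center_time)
  songs <- meas |>
    dplyr::group_by(.data$singer) |>
    tidyr::nest(notes = !dplyr::all_of("singer")) |>
    dplyr::ungroup()
  songs <- dplyr::mutate(
    songs,
    date = as.Date(.data$singer),
    song_id = .data$singer,
    recording_id = purrr::map_chr(
      .data$notes, ~ as.character(.x$recording_id[1] %||% NA)),
    n_notes = purrr::map_int(.data$notes, nrow),
    duration = purrr::map_dbl(.data$notes, ~ max(.x$end) - min(.x$begin)),
    mean_snr = purrr::map_dbl(.data$notes, ~ mean(.x$snr, na.rm = TRUE)),
    month = lubridate::month(.data$date),
    song_year = assign_song_year(.data$date, first_july, n_years),
    exclusion_reason = dplyr::case_when(
      duration < min_duration ~ "duration",
      is.na(mean_snr) | mean_snr < min_snr ~ "snr",
      TRUE ~ NA_character_
    ),
    included = is.na(.data$exclusion_reason)
  )
  dplyr::select(songs, "song_id", "singer", "date", "month", "song_year",
                "recording_id", "n_notes", "duration", "mean_snr",
                "included", "exclusion_reason", "notes")
}

#' Compute and range-filter inter-note intervals
#'
#' Raw INIs are differences of successive note center times within each
#' song. Intervals outside `[ini_min, ini_max]` are removed with a
#' reason (`"lt_min"` for surfacing-independent short artefacts,
#' `"gt_max"` for breath gaps, missed notes and multipath): one row per
#' raw interval, flagged kept or removed.
#'
#' @param songs A songs tibble from [build_songs()] (included songs are
#'   used; pass `included_only = FALSE` to keep all).
#' @param ini_min,ini_max Range bounds, seconds.
#' @param included_only Drop excluded songs first.
#' @return A tibble with `song_id`, `singer`, `month`, `song_year`,
#'   `ini`, `kept`, `reason`.
#' @export
compute_inis <- function(songs, ini_min = 4.5, ini_max = 30,
                         included_only = TRUE) {
  if (included_only) songs <- dplyr::filter(songs, .data$included)
  per_song <- purrr::pmap(
    list(songs$song_id, songs$singer, songs$month, songs$song_year,
         songs$notes),
    function(song_id, singer, month, song_year, notes) {
      ct <- sort(notes$center_time)
      if (length(ct) < 2) {
        return(tibble::tibble(song_id = character(), singer = character(),
                              month = integer(), song_year = integer(),
                              ini = numeric(), kept = logical(),
                              reason = character()))
      }
      ini <- diff(ct)
      tibble::tibble(
        song_id = song_id, singer = singer,
        month = as.integer(month), song_year = as.integer(song_year),
        ini = ini,
        kept = ini >= ini_min & ini <= ini_max,
        reason = dplyr::case_when(ini < ini_min ~ "lt_min",
                                  ini > ini_max ~ "gt_max",
                                  TRUE ~ NA_character_))
    })
  dplyr::bind_rows(per_song)
}

#' Per-song INI summary
#'
#' Median, 25th and 75th quartile and interquartile range of each
#' song's kept INIs (linear-interpolation quantiles, the R default).
#' Songs with no kept INIs are dropped.
#'
#' @param inis An INI tibble from [compute_inis()].
#' @return A tibble with `song_id`, `singer`, `month`, `song_year`,
#'   `median_ini`, `q25`, `q75`, `iqr`, `n_inis`.
#' @export
summarize_song <- function(inis) {
  inis |>
    dplyr::filter(.data$kept) |>
    dplyr::group_by(.data$song_id, .data$singer, .data$month,
                    .data$song_year) |>
    dplyr::summarise(
      median_ini = median(.data$ini),
      q25 = quantile(.data$ini, 0.25, names = FALSE),
      q75 = quantile(.data$ini, 0.75, names = FALSE),
      iqr = .data$q75 - .data$q25,
      n_inis = dplyr::n(),
      .groups = "drop")
}

#' Pooled period means of INI by song year
#'
#' Pools kept INIs across the songs of a period -- short-INI period
#' (September-December) or long-INI period (March-May) -- and reports
#' the mean, its standard error (INIs treated as independent; the
#' mixed-model layer, not this summary, handles within-song
#' dependence), and song/INI counts per song year. Song years without
#' data yield an `NA` ("no data") row.
#'
#' @param inis An INI tibble from [compute_inis()].
#' @param period `"short"` or `"long"`.
#' @param short_months,long_months Month sets defining the periods.
#' @param song_years Song years to report (defaults to those present).
#' @return A tibble with `song_year`, `period`, `mean`, `sem`,
#'   `n_songs`, `n_inis`.
#' @export
period_means <- function(inis, period = c("short", "long"),
                         short_months = 9:12, long_months = 3:5,
                         song_years = NULL) {
  period <- match.arg(period)
  months <- if (period == "short") short_months else long_months
  song_years <- song_years %||% sort(unique(inis$song_year))
  kept <- dplyr::filter(inis, .data$kept, .data$month %in% months)
  out <- kept |>
    dplyr::group_by(.data$song_year) |>
    dplyr::summarise(
      mean = mean(.data$ini),
      sem = sd(.data$ini) / sqrt(dplyr::n()),
      n_songs = dplyr::n_distinct(.data$song_id),
      n_inis = dplyr::n(),
      .groups = "drop")
  tibble::tibble(song_year = as.integer(song_years)) |>
    dplyr::left_join(out, by = "song_year") |>
    dplyr::mutate(period = period, .after = "song_year") |>
    tidyr::replace_na(list(n_songs = 0L, n_inis = 0L))
}

#' Select high-SNR notes for spectral analysis
#'
#' Pools the SNR of all notes from included songs, takes the 75th
#' percentile (linear-interpolation quantile) as the threshold, keeps
#' notes at or above it, and then keeps only days contributing at least
#' `min_notes_per_day` such notes.
#'
#' @param meas Note measurements from included songs, with `singer` (or
#'   `date`) and `snr` columns; flagged notes (`NA` SNR) are ignored.
#' @param prob Quantile defining the threshold.
#' @param min_notes_per_day Minimum qualifying notes per day.
#' @return A list with `threshold` (dB), `notes` (the qualifying
#'   subset) and `day_counts` (per-day qualifying-note counts with a
#'   `kept_day` flag).
#' @export
select_high_snr_notes <- function(meas, prob = 0.75, min_notes_per_day = 10) {
  meas <- dplyr::filter(meas, !is.na(.data$snr))
  if (nrow(meas) < 4) abort("need at least 4 measured notes")
  if (!"date" %in% names(meas)) {
    meas$date <- as.Date(meas$singer)
  }
  threshold <- quantile(meas$snr, prob, names = FALSE)
  high <- dplyr::filter(meas, .data$snr >= threshold)
  day_counts <- high |>
    dplyr::count(.data$date, name = "n_notes") |>
    dplyr::mutate(kept_day = .data$n_notes >= min_notes_per_day)
  keep_days <- day_counts$date[day_counts$kept_day]
  list(threshold = threshold,
       notes = dplyr::filter(high, .data$date %in% keep_days),
       day_counts = day_counts)
}

#' Effort and yield summary by month and song year
#'
#' The review-audit table: songs and kept INIs per month x song year
#' with row and column totals, plus reviewed days and hours when an
#' effort plan is supplied.
#'
#' @param songs A songs tibble from [build_songs()] (included songs are
#'   counted).
#' @param inis An INI tibble from [compute_inis()].
#' @param plan Optional effort plan from [subsample_effort()].
#' @return A list with `cells` (tibble `month`, `song_year`, `songs`,
#'   `inis`), `totals_by_year`, `totals_by_month`, `total_songs`,
#'   `total_inis`, and (given a plan) `days_reviewed`, `hours_reviewed`.
#' @export
effort_summary <- function(songs, inis, plan = NULL) {
  included <- dplyr::filter(songs, .data$included)
  song_cells <- dplyr::count(included, .data$month, .data$song_year,
                             name = "songs")
  ini_cells <- inis |>
    dplyr::filter(.data$kept) |>
    dplyr::count(.data$month, .data$song_year, name = "inis")
  cells <- dplyr::full_join(song_cells, ini_cells,
                            by = c("month", "song_year")) |>
    tidyr::replace_na(list(songs = 0L, inis = 0L)) |>
    dplyr::arrange(.data$song_year, .data$month)
  by_year <- cells |>
    dplyr::group_by(.data$song_year) |>
    dplyr::summarise(songs = sum(.data$songs), inis = sum(.data$inis),
                     .groups = "drop")
  by_month <- cells |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(songs = sum(.data$songs), inis = sum(.data$inis),
                     .groups = "drop")
  out <- list(cells = cells, totals_by_year = by_year,
              totals_by_month = by_month,
              total_songs = sum(cells$songs), total_inis = sum(cells$inis))
  if (!is.null(plan)) {
    out$days_reviewed <- dplyr::n_distinct(plan$date)
    out$hours_reviewed <- sum(plan$minutes) / 60
  }
  out
}
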