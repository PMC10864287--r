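# Review-effort subsampling and daily song selection.
#
# The review scheme: starting with the first full calendar day after
# each deployment leg begins, every other day is reviewed; within a
# reviewed day only the six recordings starting at hours 00, 04, 08,
# 12, 16 and 20 UTC, and only their first 30 minutes (so continuously
# recorded years are reviewed identically to duty-cycled ones).

#' Build a review effort plan from a deployment index
#'
#' @param index A tibble of recording metadata with a `start` column
#'   (`POSIXct`). Deployment legs are split wherever the recorded dates
#'   jump by more than `gap_days`; the first-full-day rule restarts at
#'   each leg.
#' @param hours Hours-of-day reviewed.
#' @param every_days Review every this-many-th day.
#' @param minutes Minutes reviewed per recording.
#' @param gap_days Date gap that starts a new deployment leg.
#' @return A tibble (`date`, `hour`, `minutes`) with one row per
#'   reviewed recording.
#' @export
subsample_effort <- function(index, hours = c(0, 4, 8, 12, 16, 20),
                             every_days = 2, minutes = 30, gap_days = 2) {
  if (nrow(index) == 0) {
    return(tibble::tibble(date = as.Date(character()), hour = numeric(),
                          minutes = numeric()))
  }
  dates <- sort(unique(lubridate::as_date(index$start)))
  leg <- cumsum(c(1, diff(dates) > gap_days))
  day_starts <- index |>
    dplyr::mutate(date = lubridate::as_date(.data$start),
                  hour = lubridate::hour(.data$start) +
                    lubridate::minute(.data$start) / 60)
  plans <- lapply(split(dates, leg), function(leg_dates) {
    first <- leg_dates[1]
    # the leg's first day counts as full only if recording starts at 00:00
    first_start <- min(day_starts$hour[day_starts$date == first])
    first_full <- if (first_start <= 1e-9) first else first + 1
    if (first_full > max(leg_dates)) return(as.Date(character()))
    reviewed <- seq(first_full, max(leg_dates), by = every_days)
    reviewed[reviewed %in% leg_dates]
  })
  reviewed_dates <- as.Date(unlist(plans), origin = "1970-01-01")
  avail <- day_starts |>
    dplyr::filter(.data$date %in% reviewed_dates,
                  floor(.data$hour) %in% hours,
                  .data$hour %% 1 < 1e-9) |>
    dplyr::distinct(.data$date, .data$hour)
  dplyr::mutate(avail, minutes = minutes) |>
    dplyr::arrange(.data$date, .data$hour)
}

#' Choose the day's song recording
#'
#' At most one recording with song per reviewed day is analysed.
#' "Clearest, most distinct song" is operationalised deterministically:
#' most annotated notes, tie-break by highest mean SNR, then earliest
#' hour.
#'
#' @param candidates A tibble with one row per candidate recording of a
#'   single day: `recording_id`, `n_notes`, optionally `mean_snr` and
#'   `hour`.
#' @return The chosen `recording_id`, or `NA` when there are no
#'   candidates.
#' @export
pick_daily_song <- function(candidates) {
  if (nrow(candidates) == 0) return(NA_character_)
  if (!"mean_snr" %in% names(candidates)) candidates$mean_snr <- 0
  if (!"hour" %in% names(candidates)) candidates$hour <- 0
  picked <- candidates |>
    dplyr::arrange(dplyr::desc(.data$n_notes), dplyr::desc(.data$mean_snr),
                   .data$hour)
  picked$recording_id[1]
}

#' Assign singer identities by recording date
#'
#' The review design admits at most one analysed song per day, and days
#' are separated by more than a song sequence lasts, so the recording
#' date is the singer proxy: singer id = ISO date. Two songs on the
#' same day violate the design and raise an error.
#'
#' @param songs A tibble with a `date` column (`Date`), one row per
#'   song.
#' @return `songs` with a `singer` character column added.
#' @export
assign_singer_ids <- function(songs) {
  if (anyDuplicated(songs$date)) {
    abort("invariant violation: more than one song on the same day")
  }
  dplyr::mutate(songs, singer = format(as.Date(.data$date)))
}

#' Attribute notes to a single singer by relative amplitude
#'
#' When two singers share a recording, notes are assigned to the louder
#' singer by inband power: the candidate split is at the largest gap in
#' note powers, and the louder group is kept if every one of its notes
#' is within `tol_db` of the group's running median and no note is
#' ambiguous (within `tol_db` of both groups' medians). Any two notes
#' overlapping in time, or any ambiguous note, mark the whole song
#' ambiguous and it is excluded.
#'
#' @param meas A measurement tibble (one recording) with `begin`,
#'   `end`, `inband_power`.
#' @param tol_db Amplitude tolerance in dB.
#' @return A list with `notes` (the retained measurements, or `NULL`),
#'   `excluded` (logical) and `reason` (`NA` or a string).
#' @export
attribute_singers <- function(meas, tol_db = 3) {
  meas <- dplyr::arrange(meas, .data$begin)
  if (nrow(meas) >= 2 &&
      any(meas$begin[-1] < meas$end[-nrow(meas)])) {
    return(list(notes = NULL, excluded = TRUE, reason = "overlapping_notes"))
  }
  p <- meas$inband_power
  if (diff(range(p)) <= tol_db) {
    return(list(notes = meas, excluded = FALSE, reason = NA_character_))
  }
  ord <- order(p, decreasing = TRUE)
  gaps <- -diff(p[ord])
  cut <- which.max(gaps)
  loud <- sort(ord[seq_len(cut)])
  quiet <- sort(ord[-seq_len(cut)])
  med_loud <- median(p[loud]); med_quiet <- median(p[quiet])
  near_loud <- abs(p - med_loud) <= tol_db
  near_quiet <- abs(p - med_quiet) <= tol_db
  if (any(near_loud & near_quiet)) {
    return(list(notes = NULL, excluded = TRUE, reason = "ambiguous_amplitude"))
  }
  if (!all(near_loud[loud])) {
    return(list(notes = NULL, excluded = TRUE, reason = "ambiguous_amplitude"))
  }
  list(notes = meas[loud, ], excluded = FALSE, reason = NA_character_)
}
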