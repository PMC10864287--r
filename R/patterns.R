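# Song and song-year pattern classification.
#
# The field's two NYB/GoM INI modes sit near 10 s (short) and 15 s
# (long). Songs are labelled by their median INI against a configurable
# threshold at the midpoint (12.5 s); song years are labelled by the
# seasonal arrangement of song labels. All numeric criteria here are
# package conventions (the source analyses classified by inspection)
# and every threshold is an argument.

#' Classify songs as short- or long-INI
#'
#' `SHORT` when the song's median INI is strictly below `threshold`,
#' else `LONG`. Songs with IQR above `iqr_threshold` are additionally
#' flagged as variable (transition-period behaviour).
#'
#' @param summaries A song-summary tibble from [summarize_song()].
#' @param threshold SHORT/LONG boundary, seconds.
#' @param iqr_threshold IQR above which a song is flagged variable.
#' @return `summaries` with `label` and `variable_flag` columns added.
#' @export
classify_song <- function(summaries, threshold = 12.5, iqr_threshold = 2) {
  dplyr::mutate(summaries,
                label = ifelse(.data$median_ini < threshold, "SHORT", "LONG"),
                variable_flag = .data$iqr > iqr_threshold)
}

predominant <- function(labels) {
  tab <- sort(table(labels), decreasing = TRUE)
  if (length(tab) == 0) return(NA_character_)
  names(tab)[1]
}

#' Classify a song year's pattern
#'
#' `SEASONAL_SHIFT` when September-December songs are predominantly
#' SHORT and March-April songs predominantly LONG; `CONSTANT_LONG`
#' when at least `predominance` of all labelled songs are LONG,
#' including in September-December (the song-year-four regime);
#' `CONSTANT_SHORT` symmetrically; otherwise (or with fewer than
#' `min_months` labelled months) `UNDETERMINED`.
#'
#' @param labelled A labelled song tibble from [classify_song()] for
#'   one song year (columns `month`, `label`).
#' @param min_months Minimum number of months with labelled songs.
#' @param predominance Fraction of LONG (or SHORT) songs required for a
#'   constant-pattern call.
#' @return A list with `type`, `evidence` (per-month predominant
#'   labels), `transition_months` and `cooccurrence_months`.
#' @export
classify_song_year <- function(labelled, min_months = 4,
                               predominance = 0.75) {
  evidence <- labelled |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(predominant = predominant(.data$label),
                     n_songs = dplyr::n(), .groups = "drop")
  co <- detect_cooccurrence(labelled)
  out <- list(evidence = evidence,
              cooccurrence_months = co$month[co$flagged])
  if (nrow(evidence) < min_months) {
    out$type <- "UNDETERMINED"
    return(out)
  }
  fall <- dplyr::filter(labelled, .data$month %in% 9:12)
  spring <- dplyr::filter(labelled, .data$month %in% 3:4)
  prop_long <- mean(labelled$label == "LONG")
  fall_pred <- predominant(fall$label)
  spring_pred <- predominant(spring$label)
  out$type <- if (!is.na(fall_pred) && !is.na(spring_pred) &&
                  fall_pred == "SHORT" && spring_pred == "LONG") {
    "SEASONAL_SHIFT"
  } else if (prop_long >= predominance &&
             (is.na(fall_pred) || fall_pred == "LONG")) {
    "CONSTANT_LONG"
  } else if ((1 - prop_long) >= predominance &&
             (is.na(fall_pred) || fall_pred == "SHORT")) {
    "CONSTANT_SHORT"
  } else {
    "UNDETERMINED"
  }
  out
}

#' Detect co-occurring INI patterns within months
#'
#' A month is flagged when both SHORT- and LONG-labelled songs occur in
#' it (at least two songs required) -- the signature used to argue for
#' overlapping subpopulations.
#'
#' @param labelled A labelled song tibble from [classify_song()]
#'   (columns `month`, `label`; optionally `song_year`).
#' @return A tibble with `month` (and `song_year` when present),
#'   `n_short`, `n_long`, `n_songs`, `flagged`.
#' @export
detect_cooccurrence <- function(labelled) {
  groups <- intersect(c("song_year", "month"), names(labelled))
  labelled |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(
      n_short = sum(.data$label == "SHORT"),
      n_long = sum(.data$label == "LONG"),
      n_songs = dplyr::n(),
      flagged = .data$n_songs >= 2 & .data$n_short > 0 & .data$n_long > 0,
      .groups = "drop")
}

#' Detect transition months
#'
#' Transition months carry variable, intermediate INIs between the
#' short (~10 s) and long (~15 s) modes. A month is a transition month
#' when the dispersion of its song medians (IQR across songs) exceeds
#' `dispersion_factor` times the stable-month dispersion, or when its
#' monthly median INI lies strictly between the two modes by more than
#' `margin` seconds on each side.
#'
#' @param summaries A song-summary tibble (one song year) from
#'   [summarize_song()].
#' @param modes Short and long INI modes, seconds.
#' @param margin Intermediacy margin, seconds.
#' @param dispersion_factor Multiple of the stable-month dispersion.
#' @param min_months Minimum months of data required.
#' @return Integer vector of transition months (possibly empty).
#' @export
detect_transitions <- function(summaries, modes = c(short = 10, long = 15),
                               margin = 1, dispersion_factor = 2,
                               min_months = 4) {
  monthly <- summaries |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(
      month_median = median(.data$median_ini),
      disp = if (dplyr::n() >= 2) {
        quantile(.data$median_ini, 0.75, names = FALSE) -
          quantile(.data$median_ini, 0.25, names = FALSE)
      } else NA_real_,
      .groups = "drop")
  if (nrow(monthly) < min_months) return(integer(0))
  intermediate <- monthly$month_median > modes[["short"]] + margin &
    monthly$month_median < modes[["long"]] - margin
  stable_disp <- monthly$disp[!intermediate & !is.na(monthly$disp)]
  ref_disp <- if (length(stable_disp)) median(stable_disp) else NA_real_
  dispersed <- !is.na(monthly$disp) & !is.na(ref_disp) &
    monthly$disp > dispersion_factor * ref_disp & monthly$disp > 0
  sort(monthly$month[intermediate | dispersed])
}
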