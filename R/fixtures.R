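#' Packaged New York Bight 2017-2020 review-yield table
#'
#' The transcription of the monitoring study's per-month, per-song-year
#' counts of analysed songs and measured (kept) INIs, together with the
#' per-song-year review effort (days and hours manually reviewed).
#' Totals: 251 songs, 24,477 INIs over 653 reviewed days (1959 h).
#'
#' @return For `nyb_song_counts()`: a tibble with `month`, `song_year`,
#'   `songs`, `inis` (`NA` where the buoy was out of the water). For
#'   `nyb_review_effort()`: a tibble with `song_year`, `days_reviewed`,
#'   `hours_reviewed`.
#' @export
nyb_song_counts <- function() {
  path <- system.file("extdata", "nyb_song_counts.tsv", package = "finsong",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = "iiii", progress = FALSE)
}

#' @rdname nyb_song_counts
#' @export
nyb_review_effort <- function() {
  path <- system.file("extdata", "nyb_review_effort.tsv", package = "finsong",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = "iii", progress = FALSE)
}

#' Literature reference INI patterns across the Atlantic
#'
#' A static reference fixture: published INI patterns by region,
#' recording period and source, for context when interpreting pattern
#' labels. Not used by any computation.
#'
#' @return A tibble.
#' @export
atlantic_ini_literature <- function() {
  path <- system.file("extdata", "atlantic_ini_literature.tsv",
                      package = "finsong", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
}
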