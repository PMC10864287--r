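# Raven-dialect selection tables: tab-separated, "." decimal, one row
# per time-frequency selection box. Mandatory columns are the Raven
# measurement headers below; all other columns ride along untouched.

raven_core_cols <- c(
  selection = "Selection",
  begin = "Begin Time (s)",
  end = "End Time (s)",
  low = "Low Freq (Hz)",
  high = "High Freq (Hz)"
)

#' Read a Raven-style selection table
#'
#' Parses a tab-separated selection table and returns a tibble with the
#' core columns renamed to `selection`, `begin`, `end`, `low`, `high`
#' (times in recording-relative seconds, frequencies in Hz). Any other
#' columns -- annotations such as `Singer`, `SongID`, or Raven
#' measurements -- are preserved verbatim, in their original order, so
#' a read/write round trip is lossless.
#'
#' @param path File path.
#' @return A tibble of selections.
#' @export
read_selection_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(),
                         progress = FALSE, show_col_types = FALSE)
  required <- raven_core_cols[c("begin", "end", "low", "high")]
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    abort(sprintf("selection table is missing mandatory column(s): %s",
                  paste0('"', missing, '"', collapse = ", ")))
  }
  if (!raven_core_cols[["selection"]] %in% names(tbl)) {
    tbl <- dplyr::mutate(tbl, Selection = dplyr::row_number(), .before = 1)
  }
  present <- raven_core_cols[raven_core_cols %in% names(tbl)]
  names(tbl)[match(present, names(tbl))] <- names(present)
  validate_selections(tbl)
  tbl
}

validate_selections <- function(tbl) {
  if (nrow(tbl) == 0) return(invisible(tbl))
  if (any(tbl$begin < 0) || any(tbl$end <= tbl$begin)) {
    abort("invalid selection: need 0 <= begin < end")
  }
  if (any(tbl$low < 0) || any(tbl$high <= tbl$low)) {
    abort("invalid selection: need 0 <= low < high")
  }
  invisible(tbl)
}

#' Write a Raven-style selection table
#'
#' The inverse of [read_selection_table()]: core columns are written
#' under their Raven headers, everything else verbatim.
#'
#' @param tbl A selections tibble (core columns `selection`, `begin`,
#'   `end`, `low`, `high`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_table <- function(tbl, path) {
  idx <- match(names(raven_core_cols), names(tbl))
  names(tbl)[idx[!is.na(idx)]] <- raven_core_cols[!is.na(idx)]
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Convert generator ground truth to a selections tibble
#'
#' Ground-truth tables from [make_deployment()] carry the same box
#' geometry as a Raven selection table plus the truth annotations
#' (`singer`, `song_id`, `true_ini`). This helper renames those to the
#' annotation headers used on disk (`Singer`, `SongID`, `TrueINI_s`)
#' and adds selection numbers.
#'
#' @param truth A truth tibble from [make_deployment()].
#' @return A selections tibble.
#' @export
truth_as_selections <- function(truth) {
  tbl <- dplyr::rename(truth, Singer = "singer", SongID = "song_id",
                       TrueINI_s = "true_ini")
  dplyr::mutate(tbl, selection = dplyr::row_number(), .before = 1)
}
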