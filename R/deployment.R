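#' Specification of a synthetic buoy deployment
#'
#' Describes a duty-cycled hydrophone deployment: the calendar range,
#' the recorder duty cycle (30 minutes on per 60-minute cycle in the
#' 2017-2019 New York Bight configuration), the sampling rate, ambient
#' noise, and how song days are scheduled across months.
#'
#' Song scheduling is either probabilistic (`monthly_song_prob`, a
#' Bernoulli trial per reviewed day) or deterministic
#' (`songs_per_month`: month 1-12 -> count, spread evenly over the
#' month's days). When neither is given, the per-month song counts of
#' the `pattern` preset's song year are used. The preset also fixes the
#' generator INI mean per month: `"seasonal"` gives short INIs (~10 s)
#' in September-December, long INIs (~15 s) in March-May and
#' interpolated means with inflated jitter in the transition months;
#' `"constant_long"` gives long INIs year-round with a small number of
#' short-INI intruder songs (1 in October, 2 in November), emulating the
#' song-year-four regime.
#'
#' @param date_range Two `Date`s (inclusive).
#' @param duty_cycle `c(minutes_on, cycle_minutes)`.
#' @param fs Sampling rate, Hz (2000 in the reference hardware).
#' @param pattern `"seasonal"` or `"constant_long"`.
#' @param song_year Song year (1-5) whose reference period means and song
#'   counts parameterise the preset.
#' @param monthly_song_prob Optional named/possibly partial numeric
#'   vector indexed by month (1-12) of daily song probabilities.
#' @param songs_per_month Optional integer vector of length 12 of exact
#'   song-day counts per month.
#' @param n_notes,breath_gap_every,breath_gap_range,note Song structure
#'   shared by all generated songs; see [song_spec()].
#' @param singer_levels Received-level offsets in dB applied to each
#'   singer's notes; one song per entry is mixed into a song day's
#'   recording. Default one singer at 0 dB.
#' @param noise An [noise_spec()].
#' @param seed Integer root seed. Each day derives a child seed, so
#'   extending the range never perturbs earlier days.
#' @return A list of class `fw_deployment_spec`.
#' @export
deployment_spec <- function(date_range,
                            duty_cycle = c(30, 60),
                            fs = 2000,
                            pattern = c("seasonal", "constant_long"),
                            song_year = 2,
                            monthly_song_prob = NULL,
                            songs_per_month = NULL,
                            n_notes = 31,
                            breath_gap_every = 10,
                            breath_gap_range = c(35, 90),
                            note = note_spec(),
                            singer_levels = 0,
                            noise = noise_spec(),
                            seed = 1L) {
  pattern <- match.arg(pattern)
  date_range <- as.Date(date_range)
  if (length(date_range) != 2 || is.na(diff(date_range)) || diff(date_range) < 0) {
    abort("`date_range` must be two ordered dates")
  }
  if (duty_cycle[1] <= 0 || duty_cycle[1] > duty_cycle[2]) {
    abort("duty cycle on-time must be positive and at most the cycle length")
  }
  if (!is.null(monthly_song_prob) &&
      any(monthly_song_prob < 0 | monthly_song_prob > 1)) {
    abort("`monthly_song_prob` values must lie in [0, 1]")
  }
  structure(
    list(date_range = date_range, duty_cycle = duty_cycle, fs = fs,
         pattern = pattern, song_year = song_year,
         monthly_song_prob = monthly_song_prob,
         songs_per_month = songs_per_month,
         n_notes = n_notes, breath_gap_every = breath_gap_every,
         breath_gap_range = breath_gap_range, note = note,
         singer_levels = singer_levels, noise = noise,
         seed = as.integer(seed)),
    class = "fw_deployment_spec"
  )
}

#' Duty-cycle recording schedule
#'
#' Recording start times for every duty-cycle-on window in a date range:
#' one recording at the top of each cycle, `minutes_on` long.
#'
#' @param date_range Two `Date`s (inclusive).
#' @param duty_cycle `c(minutes_on, cycle_minutes)`.
#' @return A tibble with `start` (UTC `POSIXct`) and `minutes`.
#' @export
duty_cycle_schedule <- function(date_range, duty_cycle = c(30, 60)) {
  date_range <- as.Date(date_range)
  days <- seq(date_range[1], date_range[2], by = "day")
  step <- duty_cycle[2] * 60
  starts <- as.POSIXct(rep(days, each = 24 * 60 * 60 / step), tz = "UTC") +
    rep(seq(0, 24 * 60 * 60 - step, by = step), length(days))
  tibble::tibble(start = starts, minutes = duty_cycle[1])
}

# Child seed for a given day index: a fixed affine map folded into the
# 31-bit range, so per-day streams are independent of range extensions.
day_seed <- function(root, day_index) {
  as.integer((as.numeric(root) * 7919 + day_index * 104729) %% 2147483647)
}

recording_id_for <- function(start) {
  format(start, "FW_%Y%m%dT%H%M%SZ", tz = "UTC")
}

#' Generate a synthetic deployment
#'
#' Builds the deployment's song schedule, synthesises one duty-cycled
#' recording per song day (coloured ambient noise with each singer's
#' song mixed in at its received-level offset), and assembles the
#' ground-truth selection table. The waveform of every song day is
#' passed to `sink(recording, truth_rows)` if supplied (streaming mode:
#' audio is dropped afterwards), written as a 16-bit PCM WAV under
#' `out_dir` if given, and kept in memory otherwise.
#'
#' Noise-only recordings for duty windows without song are generated
#' only when `include_empty = TRUE` (they carry no annotations and are
#' expensive at full deployment scale).
#'
#' @param spec An [deployment_spec()].
#' @param out_dir Optional directory for WAV output.
#' @param sink Optional `function(recording, truth)` called per song day.
#' @param include_empty Also generate noise-only recordings for every
#'   duty window (only sensible for short ranges).
#' @return A list with `index` (tibble of recordings: `recording_id`,
#'   `start`, `fs`, `minutes`, `path` when written), `truth` (the
#'   ground-truth selection table as a tibble with `recording_id`,
#'   `begin`, `end`, `low`, `high`, `singer`, `song_id`, `true_ini`),
#'   and `recordings` (list of in-memory recordings, possibly empty).
#' @export
make_deployment <- function(spec, out_dir = NULL, sink = NULL,
                            include_empty = FALSE) {
  stopifnot(inherits(spec, "fw_deployment_spec"))
  days <- seq(spec$date_range[1], spec$date_range[2], by = "day")
  if (length(days) == 0) abort("zero-length date range")
  n_on <- round(spec$duty_cycle[1] * 60 * spec$fs)
  review_hours <- c(0, 4, 8, 12, 16, 20)

  song_days <- schedule_song_days(spec, days)

  index <- list(); truth <- list(); recordings <- list()
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  for (i in seq_along(days)) {
    day <- days[i]
    sd_row <- song_days[song_days$date == day, ]
    has_song <- nrow(sd_row) == 1
    if (!has_song && !include_empty) next
    set.seed(day_seed(spec$seed, i))
    hours <- if (include_empty) {
      seq(0, by = spec$duty_cycle[2] / 60, length.out = 24 * 60 / spec$duty_cycle[2])
    } else {
      sample(review_hours, 1)
    }
    song_hour <- if (has_song) sample(review_hours, 1) else NA_real_
    if (has_song && !(song_hour %in% hours)) hours <- song_hour
    for (h in hours) {
      start <- as.POSIXct(day, tz = "UTC") + h * 3600
      x <- make_noise(n_on, spec$fs, spec$noise)
      rows <- NULL
      if (has_song && (!include_empty || identical(h, song_hour))) {
        mix <- mix_songs_into(x, spec, sd_row)
        x <- mix$x
        rows <- mix$truth
        rows$recording_id <- recording_id_for(start)
        rows$singer <- format(day)
        rows$song_id <- paste0("S", format(day, "%Y%m%d"))
        rows <- rows[, c("recording_id", "begin", "end", "low", "high",
                         "singer", "song_id", "true_ini")]
      }
      x <- pmin(pmax(x, -1), 32767 / 32768)
      rec <- recording(x, fs = spec$fs, start = start,
                       id = recording_id_for(start),
                       duty_cycle = spec$duty_cycle)
      path <- NA_character_
      if (!is.null(out_dir)) {
        path <- file.path(out_dir, paste0(rec$id, ".wav"))
        write_wav(rec, path)
      }
      index[[length(index) + 1]] <- tibble::tibble(
        recording_id = rec$id, start = start, fs = spec$fs,
        minutes = spec$duty_cycle[1], path = path)
      if (!is.null(rows)) truth[[length(truth) + 1]] <- rows
      if (!is.null(sink)) {
        sink(rec, rows)
      } else if (is.null(out_dir)) {
        recordings[[length(recordings) + 1]] <- rec
      }
    }
  }
  list(index = dplyr::bind_rows(index),
       truth = if (length(truth)) dplyr::bind_rows(truth) else empty_truth(),
       recordings = recordings)
}

empty_truth <- function() {
  tibble::tibble(recording_id = character(), begin = numeric(),
                 end = numeric(), low = numeric(), high = numeric(),
                 singer = character(), song_id = character(),
                 true_ini = numeric())
}

# Decide which calendar days carry a song and the song's generator
# parameters (monthly preset mean/jitter, intruder status).
schedule_song_days <- function(spec, days) {
  preset <- preset_monthly_ini(spec$pattern, spec$song_year)
  months_present <- sort(unique(lubridate::month(days)))
  out <- list()
  for (m in months_present) {
    in_month <- days[lubridate::month(days) == m]
    if (!is.null(spec$songs_per_month)) {
      n <- spec$songs_per_month[[m]]
    } else if (!is.null(spec$monthly_song_prob)) {
      p <- spec$monthly_song_prob[m]
      if (is.na(p)) p <- 0
      set.seed(day_seed(spec$seed, 10000 + m))
      n <- sum(runif(length(in_month)) < p)
    } else {
      counts <- song_count_reference()
      n <- counts$n_songs[counts$month == m & counts$song_year == spec$song_year]
      n <- if (length(n) == 1 && !is.na(n)) n else 0L
    }
    if (is.na(n) || n < 1) next
    n <- min(n, length(in_month))
    sel <- in_month[unique(round(seq(1, length(in_month), length.out = n)))]
    pm <- preset[preset$month == m, ]
    intr <- rep(FALSE, length(sel))
    if (pm$n_intruder > 0) intr[seq_len(min(pm$n_intruder, length(sel)))] <- TRUE
    out[[length(out) + 1]] <- tibble::tibble(
      date = sel,
      ini_mean = ifelse(intr, pm$intruder_mean, pm$ini_mean),
      ini_jitter_sd = ifelse(intr, 0.3, pm$ini_jitter_sd),
      intruder = intr)
  }
  if (!length(out)) {
    return(tibble::tibble(date = as.Date(character()), ini_mean = numeric(),
                          ini_jitter_sd = numeric(), intruder = logical()))
  }
  dplyr::bind_rows(out)
}

# Mix each singer's song into the noise waveform `x`. Singers beyond the
# first are offset in start time and received level.
mix_songs_into <- function(x, spec, sd_row) {
  n <- length(x); fs <- spec$fs
  truth <- list()
  for (si in seq_along(spec$singer_levels)) {
    lev <- spec$singer_levels[si]
    sspec <- song_spec(
      ini_mean = min(max(sd_row$ini_mean, 4.5), 30),
      ini_jitter_sd = sd_row$ini_jitter_sd,
      n_notes = spec$n_notes,
      breath_gap_every = spec$breath_gap_every,
      breath_gap_range = spec$breath_gap_range,
      note = spec$note)
    start <- 100 + (si - 1) * 7
    song <- make_song(sspec, start = start)
    wave <- make_note(sspec$note, fs) * 10^(lev / 20)
    nn <- length(wave)
    for (on in song$onsets) {
      i0 <- round(on * fs) + 1
      if (i0 + nn - 1 > n) break
      x[i0:(i0 + nn - 1)] <- x[i0:(i0 + nn - 1)] + wave
    }
    tr <- song$truth
    tr$singer_level <- lev
    truth[[si]] <- tr
  }
  # ground truth reports the primary (first, loudest-by-convention) singer
  list(x = x, truth = truth[[1]])
}
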