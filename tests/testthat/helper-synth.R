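# Shared fixture builders. Everything is generated in code; no binary
# fixtures are stored.

# A short recording with the canonical note embedded in silence (or
# noise) -- enough frames either side for noise windows.
canonical_note_recording <- function(pad_s = 8, noise = NULL, fs = 2000) {
  note <- make_note(canonical_note_spec(), fs)
  x <- c(rep(0, pad_s * fs), note, rep(0, pad_s * fs))
  if (!is.null(noise)) x <- x + make_noise(length(x), fs, noise)
  recording(x, fs = fs, id = "canon")
}

canonical_note_selection <- function(pad_s = 8) {
  tibble::tibble(selection = 1L, begin = pad_s, end = pad_s + 0.9,
                 low = 15, high = 25)
}

# A pure tone recording at a given frequency.
tone_recording <- function(freq, amp = 0.5, dur = 10, fs = 2000) {
  t <- (0:(dur * fs - 1)) / fs
  recording(amp * sin(2 * pi * freq * t), fs = fs, id = "tone")
}

# Simulate truth-level (no audio) song tables for model tests: INIs
# drawn around a monthly mean profile, with per-singer random effects.
simulate_ini_table <- function(monthly_mean, song_years,
                               songs_per_month = 3, inis_per_song = 20,
                               jitter_sd = 0.5, singer_sd = 0.2) {
  rows <- list()
  for (sy in song_years) {
    for (m in seq_along(monthly_mean)) {
      mu_m <- monthly_mean[[m]]
      if (is.na(mu_m)) next
      for (s in seq_len(songs_per_month)) {
        singer <- sprintf("sy%d-m%02d-d%02d", sy, m, s)
        mu_s <- mu_m * exp(rnorm(1, 0, singer_sd / mu_m))
        rows[[length(rows) + 1]] <- tibble::tibble(
          ini = pmax(4.5, rnorm(inis_per_song, mu_s, jitter_sd)),
          month = m, song_year = sy, singer = singer)
      }
    }
  }
  dplyr::bind_rows(rows)
}

# Measurement-table stand-in built directly from note center times (no
# audio), for pipeline-logic tests.
fake_measurements <- function(center_times, date, snr = 20,
                              recording_id = "rec") {
  n <- length(center_times)
  tibble::tibble(
    recording_id = recording_id,
    begin = center_times - 0.45, end = center_times + 0.45,
    low = 15, high = 25,
    center_time = center_times,
    inband_power = -20, peak_freq = 19.53125, center_freq = 19.53125,
    bw90 = 3.90625,
    noise_begin = center_times - 5.9, noise_end = center_times - 5,
    snr = rep_len(snr, n), snr_flag = NA_character_,
    noise_overlap = FALSE,
    singer = format(as.Date(date)))
}

# Song-summary rows for pattern-classification tests.
fake_summaries <- function(medians, months, song_year = 2, iqr = 0.4) {
  tibble::tibble(
    song_id = sprintf("S%03d", seq_along(medians)),
    singer = sprintf("S%03d", seq_along(medians)),
    month = months, song_year = song_year,
    median_ini = medians, q25 = medians - iqr / 2, q75 = medians + iqr / 2,
    iqr = iqr, n_inis = 25L)
}

# Truth-level (no audio) song summaries for a preset song year: draws
# each month's songs from the preset generator means and summarises
# kept INIs, for pattern-recovery checks.
preset_song_summaries <- function(pattern, song_year, songs_per_month = 4,
                                  n_notes = 25) {
  sched <- finsong:::preset_monthly_ini(pattern, song_year)
  months <- if (pattern == "seasonal") c(9:12, 1:4) else c(8:12, 1:3)
  sm <- list()
  for (m in months) {
    pm <- sched[sched$month == m, ]
    for (k in seq_len(songs_per_month)) {
      mu <- if (k <= pm$n_intruder) pm$intruder_mean else pm$ini_mean
      s <- make_song(song_spec(ini_mean = min(max(mu, 4.5), 30),
                               ini_jitter_sd = pm$ini_jitter_sd,
                               n_notes = n_notes))
      ini <- s$truth$true_ini
      ini <- ini[!is.na(ini) & ini >= 4.5 & ini <= 30]
      sm[[length(sm) + 1]] <- tibble::tibble(
        song_id = sprintf("%s-%d-%d", pattern, m, k),
        singer = sprintf("%s-%d-%d", pattern, m, k),
        month = m, song_year = song_year,
        median_ini = median(ini),
        q25 = quantile(ini, 0.25, names = FALSE),
        q75 = quantile(ini, 0.75, names = FALSE),
        iqr = quantile(ini, 0.75, names = FALSE) -
          quantile(ini, 0.25, names = FALSE),
        n_inis = length(ini))
    }
  }
  dplyr::bind_rows(sm)
}
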