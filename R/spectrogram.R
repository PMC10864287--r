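# Spectrogram and per-selection measurements.
#
# Conventions (matching Raven's robust measurements):
#  * Hann window, nfft = 1024, 90% overlap -> hop = floor(0.1 * 1024) =
#    102 samples; at fs = 2000 Hz the grid is 1.953125 Hz x 0.051 s.
#  * Frame k starts at sample k * hop (0-based) and is stamped with its
#    window-center time; a frame belongs to a selection when its center
#    lies in [begin, end].
#  * Frequencies are reported on the bin grid k * fs / nfft.
#  * The PSD is one-sided and scaled so the total energy over the grid
#    equals the time-domain energy sum(x^2) (Parseval, window- and
#    overlap-gain corrected).

#' Compute a measurement spectrogram
#'
#' @param x An [recording()] or numeric waveform.
#' @param fs Sampling rate (taken from the recording when omitted).
#' @param nfft FFT length (also the Hann window length).
#' @param overlap Fractional window overlap.
#' @param t0 Time of the first sample, seconds; frame times are offset
#'   by this (used internally for locally computed, globally aligned
#'   grids).
#' @return A list of class `fw_spectrogram` with `psd` (frames x bins),
#'   `frame_times` (window centers, s), `bin_freqs` (Hz) and `params`.
#' @export
spectrogram <- function(x, fs = NULL, nfft = 1024, overlap = 0.9, t0 = 0) {
  if (inherits(x, "fw_recording")) {
    fs <- x$fs
    x <- x$samples
  }
  if (is.null(fs)) abort("`fs` is required for a bare waveform")
  n <- length(x)
  if (n < nfft) abort("recording shorter than one analysis window")
  hop <- floor(nfft * (1 - overlap))
  w <- hann_window(nfft)
  wss <- sum(w^2)
  starts <- seq(1, n - nfft + 1, by = hop)
  frames <- matrix(x[outer(0:(nfft - 1), starts, "+")], nrow = nfft) * w
  X <- mvfft(frames)
  nb <- nfft / 2 + 1
  psd <- Mod(X[1:nb, , drop = FALSE])^2
  psd[2:(nb - 1), ] <- 2 * psd[2:(nb - 1), ]
  psd <- t(psd) * hop / (nfft * wss)
  structure(
    list(psd = psd,
         frame_times = t0 + (starts - 1 + nfft / 2) / fs,
         bin_freqs = (0:(nfft / 2)) * fs / nfft,
         params = list(window = "hann", nfft = nfft, overlap = overlap,
                       fs = fs, hop = hop)),
    class = "fw_spectrogram"
  )
}

#' @export
print.fw_spectrogram <- function(x, ...) {
  cat(sprintf("<fw_spectrogram> %d frames x %d bins (%.6g Hz, %.4g s resolution)\n",
              nrow(x$psd), ncol(x$psd),
              x$bin_freqs[2], x$params$hop / x$params$fs))
  invisible(x)
}

# Indices of the frames and bins intersecting a selection box.
box_indices <- function(grid, begin, end, low, high) {
  fr <- which(grid$frame_times >= begin & grid$frame_times <= end)
  bn <- which(grid$bin_freqs >= low & grid$bin_freqs <= high)
  if (!length(fr) || !length(bn)) {
    abort("selection box does not intersect the spectrogram grid")
  }
  list(frames = fr, bins = bn)
}

sel_box <- function(selection) {
  sel <- as.list(selection[1, c("begin", "end", "low", "high")])
  lapply(sel, as.numeric)
}

#' Inband power of a selection
#'
#' Total spectrogram energy inside the selection's time-frequency box,
#' in dB re unit full-scale energy: `10 * log10(sum(psd))` over the
#' intersecting frames and bins.
#'
#' @param grid An [spectrogram()].
#' @param selection A one-row selections tibble (columns `begin`, `end`,
#'   `low`, `high`).
#' @return Power in dB.
#' @export
inband_power <- function(grid, selection) {
  b <- sel_box(selection)
  ix <- box_indices(grid, b$begin, b$end, b$low, b$high)
  10 * log10(sum(grid$psd[ix$frames, ix$bins]))
}

box_spectrum <- function(grid, selection) {
  b <- sel_box(selection)
  ix <- box_indices(grid, b$begin, b$end, b$low, b$high)
  list(energy = colSums(grid$psd[ix$frames, ix$bins, drop = FALSE]),
       freqs = grid$bin_freqs[ix$bins])
}

#' Peak frequency of a selection
#'
#' The bin frequency maximising in-selection energy (summed over the
#' selection's frames) within the selection's frequency bounds; ties go
#' to the lowest bin.
#'
#' @inheritParams inband_power
#' @return Frequency in Hz (a multiple of `fs / nfft`).
#' @export
peak_frequency <- function(grid, selection) {
  sp <- box_spectrum(grid, selection)
  sp$freqs[which.max(sp$energy)]
}

cumulative_energy_freq <- function(sp, threshold) {
  cs <- cumsum(sp$energy) / sum(sp$energy)
  sp$freqs[which(cs >= threshold)[1]]
}

#' Center frequency of a selection
#'
#' The lowest bin frequency at which cumulative in-selection energy
#' (ascending over bins) reaches 50% of the total -- the discrete
#' energy-median frequency.
#'
#' @inheritParams inband_power
#' @return Frequency in Hz.
#' @export
center_frequency <- function(grid, selection) {
  cumulative_energy_freq(box_spectrum(grid, selection), 0.5)
}

#' 90% bandwidth of a selection
#'
#' `f95 - f5`, where `f5` and `f95` are the lowest bin frequencies at
#' which cumulative in-selection energy reaches 5% and 95%. The
#' discrete first-bin-reaching rule (no interpolation) keeps all
#' reported frequencies on the bin grid.
#'
#' @inheritParams inband_power
#' @return Bandwidth in Hz.
#' @export
bandwidth90 <- function(grid, selection) {
  sp <- box_spectrum(grid, selection)
  cumulative_energy_freq(sp, 0.95) - cumulative_energy_freq(sp, 0.05)
}

#' Center time of a selection
#'
#' The selection midpoint `(begin + end) / 2` in recording-relative
#' seconds. Inter-note intervals are differences of successive center
#' times.
#'
#' @param selection A one-row selections tibble.
#' @return Time in seconds.
#' @export
center_time <- function(selection) {
  b <- sel_box(selection)
  (b$begin + b$end) / 2
}

#' Signal-to-noise ratio of a note selection
#'
#' The noise window is auto-generated: same duration and frequency
#' bounds as the note, ending exactly 5 s before the note begins. With
#' `S` the linear inband power of the note box (signal plus noise) and
#' `N` that of the noise box, `SNR = 10 * log10((S - N) / N)` dB. When
#' `S <= N` the SNR is undefined: the note is flagged
#' (`flag = "nonpositive_snr"`) and should be excluded from
#' SNR-dependent statistics, as is a note whose noise window falls
#' before the start of the recording (`flag = "noise_window_oob"`).
#' A noise window that overlaps the previous note's selection is
#' measured as defined but flagged (`noise_overlap = TRUE`).
#'
#' @inheritParams inband_power
#' @param prev_begin,prev_end Time bounds of the previous note in the
#'   same recording, if any (used only for the overlap flag).
#' @return A list with `snr` (dB or `NA`), `noise_begin`, `noise_end`,
#'   `flag` (`NA` or a reason string) and `noise_overlap` (logical).
#' @export
note_snr <- function(grid, selection, prev_begin = NULL, prev_end = NULL) {
  b <- sel_box(selection)
  dur <- b$end - b$begin
  nb <- b$begin - 5 - dur
  ne <- b$begin - 5
  overlap <- !is.null(prev_end) && length(prev_end) == 1 &&
    !is.na(prev_end) && prev_end > nb &&
    !is.null(prev_begin) && prev_begin < ne
  if (nb < min(grid$frame_times) - 1e-9) {
    return(list(snr = NA_real_, noise_begin = nb, noise_end = ne,
                flag = "noise_window_oob", noise_overlap = overlap))
  }
  s_db <- inband_power(grid, selection)
  n_db <- inband_power(grid, tibble::tibble(begin = nb, end = ne,
                                            low = b$low, high = b$high))
  s_lin <- 10^(s_db / 10)
  n_lin <- 10^(n_db / 10)
  if (s_lin <= n_lin) {
    return(list(snr = NA_real_, noise_begin = nb, noise_end = ne,
                flag = "nonpositive_snr", noise_overlap = overlap))
  }
  list(snr = 10 * log10((s_lin - n_lin) / n_lin),
       noise_begin = nb, noise_end = ne, flag = NA_character_,
       noise_overlap = overlap)
}

# Local spectrogram for a time span, aligned to the recording's global
# frame grid (frame k starts at sample k * hop from the recording
# start), so measurements from local grids match full-recording grids.
local_grid <- function(rec, from, to, nfft = 1024, overlap = 0.9) {
  hop <- floor(nfft * (1 - overlap))
  n <- length(rec$samples)
  k0 <- max(0, floor((from * rec$fs - nfft) / hop))
  s0 <- k0 * hop + 1
  s1 <- min(n, ceiling(to * rec$fs) + nfft)
  spectrogram(rec$samples[s0:s1], fs = rec$fs, nfft = nfft,
              overlap = overlap, t0 = (s0 - 1) / rec$fs)
}

#' Measure every selection of a recording
#'
#' Composes the per-selection operations into one measurement table:
#' center time, inband power, peak frequency, center frequency, 90%
#' bandwidth, and SNR with its auto-generated noise window. Spectrogram
#' frames are computed locally around each note (aligned to the
#' recording's global frame grid), which makes measurement of long
#' duty-cycled recordings cheap.
#'
#' @param rec An [recording()].
#' @param selections A selections tibble (from [read_selection_table()]
#'   or [truth_as_selections()]); extra columns are carried through.
#' @param nfft,overlap Spectrogram parameters.
#' @return A tibble with one row per selection: the selection geometry,
#'   carried-through annotations, and measurement columns
#'   `center_time`, `inband_power`, `peak_freq`, `center_freq`, `bw90`,
#'   `noise_begin`, `noise_end`, `snr`, `snr_flag`, `noise_overlap`.
#' @export
measure_notes <- function(rec, selections, nfft = 1024, overlap = 0.9) {
  stopifnot(inherits(rec, "fw_recording"))
  meas_cols <- c("center_time", "inband_power", "peak_freq", "center_freq",
                 "bw90", "noise_begin", "noise_end", "snr", "snr_flag",
                 "noise_overlap")
  if (nrow(selections) == 0) {
    out <- selections
    out[meas_cols] <- list(numeric(), numeric(), numeric(), numeric(),
                           numeric(), numeric(), numeric(), numeric(),
                           character(), logical())
    return(out)
  }
  selections <- dplyr::arrange(selections, .data$begin)
  rows <- vector("list", nrow(selections))
  prev_begin <- NA_real_
  prev_end <- NA_real_
  for (i in seq_len(nrow(selections))) {
    sel <- selections[i, ]
    dur <- sel$end - sel$begin
    grid <- local_grid(rec, max(0, sel$begin - 5 - dur - 0.5), sel$end + 0.5,
                       nfft = nfft, overlap = overlap)
    sn <- note_snr(grid, sel, prev_begin = prev_begin, prev_end = prev_end)
    rows[[i]] <- tibble::tibble(
      center_time = center_time(sel),
      inband_power = inband_power(grid, sel),
      peak_freq = peak_frequency(grid, sel),
      center_freq = center_frequency(grid, sel),
      bw90 = bandwidth90(grid, sel),
      noise_begin = sn$noise_begin,
      noise_end = sn$noise_end,
      snr = sn$snr,
      snr_flag = sn$flag,
      noise_overlap = sn$noise_overlap)
    prev_begin <- sel$begin
    prev_end <- sel$end
  }
  out <- dplyr::bind_cols(selections, dplyr::bind_rows(rows))
  if (!"recording_id" %in% names(out)) out$recording_id <- rec$id
  out
}

#' Write a measurement table with Raven-compatible headers
#'
#' @param meas A measurement tibble from [measure_notes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurement_table <- function(meas, path) {
  lut <- c(inband_power = "Inband Power (dB)", peak_freq = "Peak Freq (Hz)",
           center_freq = "Center Freq (Hz)", bw90 = "BW 90% (Hz)",
           center_time = "Center Time (s)", snr = "SNR NIST Quick (dB)")
  idx <- match(names(lut), names(meas))
  names(meas)[idx[!is.na(idx)]] <- lut[!is.na(idx)]
  write_selection_table(meas, path)
}
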