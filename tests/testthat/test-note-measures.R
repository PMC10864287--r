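test_that("spectrogram grid matches the stated analysis parameters", {
  rec <- tone_recording(19.53125, dur = 5)
  g <- spectrogram(rec)
  expect_equal(g$bin_freqs[2] - g$bin_freqs[1], 1.953125)
  expect_equal(round(g$bin_freqs[2] - g$bin_freqs[1], 2), 1.95)
  hop_s <- g$params$hop / g$params$fs
  expect_equal(g$params$hop, 102)
  expect_equal(round(hop_s, 2), 0.05)
  expect_equal(diff(g$frame_times)[1], hop_s)
  expect_true(all(g$psd >= 0))
  expect_error(spectrogram(recording(rep(0, 500), fs = 2000)),
               "shorter than one analysis window")
})

test_that("an on-bin tone concentrates its energy around its bin", {
  rec <- tone_recording(19.53125, dur = 5)  # bin 10 exactly
  g <- spectrogram(rec)
  energy <- colSums(g$psd)
  expect_equal(which.max(energy), 11)  # 0-based bin 10
  # Hann windowing spreads an on-bin line over bins k-1..k+1
  # (amplitude 1/4, 1/2, 1/4); leakage beyond those is < 5%
  expect_gt(sum(energy[10:12]) / sum(energy), 0.95)
  expect_equal(energy[10] / energy[11], 0.25, tolerance = 0.01)
})

test_that("spectrogram conserves energy (Parseval within 1%)", {
  set.seed(7)
  # energy concentrated mid-recording so edge frames lose nothing
  x <- c(rep(0, 2048), make_noise(20000, 2000, noise_spec(-20, -4)),
         rep(0, 2048))
  g <- spectrogram(x, fs = 2000)
  expect_equal(sum(g$psd), sum(x^2), tolerance = 0.01)
})

test_that("inband power scales and localises correctly", {
  rec <- canonical_note_recording()
  sel <- canonical_note_selection()
  g <- spectrogram(rec)
  p1 <- inband_power(g, sel)
  rec2 <- recording(2 * rec$samples, fs = rec$fs)
  p2 <- inband_power(spectrogram(rec2), sel)
  expect_equal(p2 - p1, 20 * log10(2), tolerance = 1e-6)  # +6.02 dB

  # a silent band of a noiseless recording is essentially empty
  silent <- dplyr::mutate(sel, low = 200, high = 400)
  expect_lt(inband_power(g, silent), -80)

  # box capturing the whole note agrees with time-domain energy
  wide <- tibble::tibble(begin = 7.4, end = 9.5, low = 0, high = 1000)
  expect_equal(10^(inband_power(g, wide) / 10), sum(rec$samples^2),
               tolerance = 0.01)
  expect_error(inband_power(g, dplyr::mutate(sel, begin = 1e4, end = 1e4 + 1)),
               "does not intersect")
})

test_that("peak frequency lands on the bin grid, ties to the lower bin", {
  g20 <- spectrogram(tone_recording(20, dur = 5))
  sel <- tibble::tibble(begin = 1, end = 4, low = 10, high = 100)
  expect_equal(peak_frequency(g20, sel), 19.53125)  # bin 10
  g50 <- spectrogram(tone_recording(50, dur = 5))
  expect_equal(peak_frequency(g50, sel), 50.78125)  # bin 26
})

test_that("center frequency and bandwidth follow the cumulative-energy bin rule", {
  # on-bin tone: center = that bin; Hann leakage into the two adjacent
  # bins makes the discrete 90% bandwidth span them (2 bins wide)
  g <- spectrogram(tone_recording(19.53125, dur = 5))
  sel <- tibble::tibble(begin = 1, end = 4, low = 10, high = 100)
  expect_equal(center_frequency(g, sel), 19.53125)
  expect_equal(bandwidth90(g, sel), 2 * 1.953125)

  # synthetic uniform spectra exercise the discrete quantile rule
  fake_grid <- function(bins_on, nb = 30) {
    psd <- matrix(0, nrow = 4, ncol = nb)
    psd[, bins_on + 1] <- 1
    structure(list(psd = psd, frame_times = (1:4) / 10,
                   bin_freqs = (0:(nb - 1)) * 1.953125,
                   params = list(fs = 2000, nfft = 1024, hop = 102)),
              class = "fw_spectrogram")
  }
  box <- tibble::tibble(begin = 0, end = 1, low = 0, high = 60)
  # a true single-bin spectrum has zero 90% bandwidth
  expect_equal(bandwidth90(fake_grid(10), box), 0)
  expect_equal(center_frequency(fake_grid(10), box), 10 * 1.953125)
  # energy uniform over bins 9-12: bin 10 first reaches 50%
  expect_equal(center_frequency(fake_grid(9:12), box), 10 * 1.953125)
  # uniform over 10 bins (5..14): f5 = bin 5, f95 = bin 14 -> 9 bins wide
  expect_equal(bandwidth90(fake_grid(5:14), box), 9 * 1.953125)
})

test_that("center time is the selection midpoint", {
  expect_equal(center_time(tibble::tibble(begin = 2, end = 3,
                                          low = 0, high = 1)), 2.5)
  expect_equal(center_time(tibble::tibble(begin = 0, end = 0.9,
                                          low = 0, high = 1)), 0.45)
})

test_that("SNR follows 10*log10((S-N)/N) with its closed-form cases", {
  # closed-form check through the definition on constructed powers
  lin_to_db <- function(s_lin, n_lin) 10 * log10((s_lin - n_lin) / n_lin)
  expect_equal(lin_to_db(2, 1), 0)    # S = 2N: 0 dB
  expect_equal(lin_to_db(11, 1), 10 * log10(10))  # S = 11N: 10 dB boundary

  # measured: known note over known noise, against the analytic ratio
  set.seed(31)
  ns <- noise_spec(level = -30, spectral_slope = 0)  # flat noise, known PSD
  rec <- canonical_note_recording(noise = ns)
  sel <- canonical_note_selection()
  g <- finsong:::local_grid(rec, 0, 9.5)
  res <- note_snr(g, sel)
  expect_true(is.na(res$flag))
  # analytic: S-N ~ note energy in box; N ~ band fraction of noise power
  note <- make_note(canonical_note_spec(), 2000)
  sig_energy <- sum(note^2)
  band_frac <- (25 - 15) / 1000
  noise_energy <- 10^(-30 / 10) * 0.9 * 2000 * band_frac
  expect_equal(res$snr, 10 * log10(sig_energy / noise_energy), tolerance = 1)
  expect_equal(res$noise_end, sel$begin - 5)
  expect_equal(res$noise_begin, sel$begin - 5 - 0.9)
})

test_that("SNR is monotone in note amplitude and flags degenerate cases", {
  set.seed(13)
  noise <- make_noise(2000 * 20, 2000, noise_spec(-25, -5))
  snr_at <- function(amp) {
    spec <- note_spec(amplitude = amp)
    x <- noise
    x[20001:21800] <- x[20001:21800] + make_note(spec, 2000)
    rec <- recording(x, fs = 2000)
    sel <- tibble::tibble(begin = 10, end = 10.9, low = 15, high = 25)
    note_snr(spectrogram(rec), sel)$snr
  }
  snrs <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), snr_at, numeric(1))
  expect_true(all(diff(snrs) > 0))

  # noise-only "note": S <= N -> flagged, excluded from stats
  rec <- recording(make_noise(2000 * 20, 2000, noise_spec(-25, 0)), fs = 2000)
  g <- spectrogram(rec)
  res <- note_snr(g, tibble::tibble(begin = 10, end = 10.9,
                                    low = 500, high = 510))
  expect_true(is.na(res$snr) || res$snr < 3)
  # noise window before recording start -> flagged oob
  res2 <- note_snr(g, tibble::tibble(begin = 2, end = 2.9, low = 15, high = 25))
  expect_equal(res2$flag, "noise_window_oob")
  expect_true(is.na(res2$snr))
})

test_that("measure_notes composes deterministically and flags noise overlap", {
  rec <- canonical_note_recording()
  sel <- canonical_note_selection()
  m1 <- measure_notes(rec, sel)
  m2 <- measure_notes(rec, sel)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 1)
  expect_equal(m1$peak_freq, 19.53125)
  expect_equal(m1$center_freq, 19.53125)
  expect_equal(m1$bw90, 3.90625)
  expect_equal(m1$center_time, 8.45)

  empty <- measure_notes(rec, sel[0, ])
  expect_equal(nrow(empty), 0)
  expect_true(all(c("snr", "peak_freq", "center_time") %in% names(empty)))

  # notes 6 s apart put the second's noise window on top of the first
  # note; 4 s apart leave the noise window clear (it ends 5 s before)
  note <- make_note(canonical_note_spec(), 2000)
  place <- function(onsets_s) {
    x <- rep(0, 2000 * 25)
    for (on in onsets_s) x[(on * 2000 + 1):(on * 2000 + 1800)] <- note
    list(rec = recording(x, fs = 2000),
         sels = tibble::tibble(selection = seq_along(onsets_s),
                               begin = onsets_s, end = onsets_s + 0.9,
                               low = 15, high = 25))
  }
  near <- place(c(8, 14))
  m <- measure_notes(near$rec, near$sels)
  expect_false(m$noise_overlap[1])
  expect_true(m$noise_overlap[2])
  clear <- place(c(8, 12))
  m2 <- measure_notes(clear$rec, clear$sels)
  expect_false(any(m2$noise_overlap))
})

test_that("all reported frequencies are multiples of the bin width", {
  set.seed(17)
  spec <- deployment_spec(date_range = as.Date(c("2017-09-03", "2017-09-06")),
                          songs_per_month = c(rep(0L, 8), 1L, 0L, 0L, 0L),
                          n_notes = 8, seed = 5)
  dep <- make_deployment(spec)
  rec <- dep$recordings[[1]]
  m <- measure_notes(rec, truth_as_selections(dep$truth))
  df <- 2000 / 1024
  for (col in c("peak_freq", "center_freq", "bw90")) {
    expect_equal(m[[col]] / df, round(m[[col]] / df), tolerance = 1e-9)
  }
})
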