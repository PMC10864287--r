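test_that("song years run July 1 through June 30", {
  expect_equal(assign_song_year(as.Date("2017-06-30")), 1L)
  expect_equal(assign_song_year(as.Date("2017-07-01")), 2L)
  expect_equal(assign_song_year(as.Date("2019-12-15")), 4L)
  expect_equal(assign_song_year(as.Date("2020-12-01")), 5L)
  expect_error(assign_song_year(as.Date("2025-01-01")), "out of study range")
})

test_that("song filters apply duration then SNR with strict boundaries", {
  meas <- dplyr::bind_rows(
    fake_measurements(seq(0, 120, by = 10) + 100, "2017-09-03", snr = 12),
    fake_measurements(seq(0, 118, by = 9.84) + 100, "2017-09-05", snr = 30),
    fake_measurements(seq(0, 130, by = 10) + 100, "2017-09-07", snr = 9.9),
    fake_measurements(seq(0, 130, by = 10) + 100, "2017-09-09", snr = 10))
  songs <- build_songs(meas)
  expect_equal(nrow(songs), 4)
  s <- songs[match(c("2017-09-03", "2017-09-05", "2017-09-07", "2017-09-09"),
                   songs$singer), ]
  # 121 s span (120 between centers + note duration), mean SNR 12: in
  expect_true(s$included[1])
  # 118.9 s < 120: out for duration
  expect_false(s$included[2])
  expect_equal(s$exclusion_reason[2], "duration")
  # mean SNR 9.9 < 10: out for snr; exactly 10: in
  expect_false(s$included[3])
  expect_equal(s$exclusion_reason[3], "snr")
  expect_true(s$included[4])
})

test_that("INIs are center-time differences, range-filtered with reasons", {
  meas <- fake_measurements(c(0, 10, 20, 65, 75) + 50, "2017-10-03", snr = 20)
  songs <- build_songs(meas, min_duration = 60)
  inis <- compute_inis(songs)
  expect_equal(inis$ini, c(10, 10, 45, 10))
  expect_equal(inis$kept, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(inis$reason[3], "gt_max")

  short <- fake_measurements(c(2, 5) + 50, "2017-10-05", snr = 20)
  songs2 <- build_songs(short, min_duration = 1)
  inis2 <- compute_inis(songs2)
  expect_equal(inis2$ini, 3)
  expect_equal(inis2$reason, "lt_min")
  expect_equal(sum(inis2$kept), 0)
  # |kept| + |removed| = |raw| = notes - 1
  both <- dplyr::bind_rows(inis, inis2)
  expect_equal(nrow(both), sum(both$kept) + sum(!both$kept))
  expect_true(all(both$ini[both$kept] >= 4.5 & both$ini[both$kept] <= 30))
})

test_that("song summaries use linear-interpolation quantiles", {
  meas <- fake_measurements(cumsum(c(50, 9, 10, 11, 15)), "2017-11-01",
                            snr = 20)
  songs <- build_songs(meas, min_duration = 40)
  sm <- summarize_song(compute_inis(songs))
  expect_equal(sm$median_ini, 10.5)
  expect_equal(sm$q25, quantile(c(9, 10, 11, 15), 0.25, names = FALSE))
  expect_equal(sm$iqr, sm$q75 - sm$q25)

  const <- fake_measurements(seq(50, 170, by = 10), "2017-11-03", snr = 20)
  sm2 <- summarize_song(compute_inis(build_songs(const)))
  expect_equal(sm2$median_ini, 10)
  expect_equal(sm2$iqr, 0)
})

test_that("period means pool INIs with s.e.m. and report empty periods", {
  meas <- dplyr::bind_rows(
    fake_measurements(seq(0, 150, by = 10) + 50, "2017-09-03", snr = 20),
    fake_measurements(seq(0, 150, by = 10) + 50, "2017-10-03", snr = 20))
  inis <- compute_inis(build_songs(meas))
  pm <- period_means(inis, "short")
  expect_equal(pm$mean, 10)
  expect_equal(pm$sem, 0)
  expect_equal(pm$n_songs, 2L)
  expect_equal(pm$n_inis, 30L)
  # no long-period data: a "no data" row, not an error
  pl <- period_means(inis, "long")
  expect_true(is.na(pl$mean))
  expect_equal(pl$n_songs, 0L)

  # pooled mean equals the count-weighted mean of per-song means
  set.seed(9)
  meas2 <- dplyr::bind_rows(
    fake_measurements(cumsum(c(50, rnorm(12, 10, 0.5))), "2018-09-04", snr = 20),
    fake_measurements(cumsum(c(50, rnorm(20, 9.5, 0.5))), "2018-09-06", snr = 20))
  inis2 <- compute_inis(build_songs(meas2))
  pm2 <- period_means(inis2, "short")
  per_song <- inis2 |>
    dplyr::filter(kept) |>
    dplyr::group_by(song_id) |>
    dplyr::summarise(m = mean(ini), n = dplyr::n())
  expect_equal(pm2$mean, sum(per_song$m * per_song$n) / sum(per_song$n))
})

test_that("high-SNR note selection uses the pooled 75th percentile and day rule", {
  snrs <- 1:100
  meas <- fake_measurements(seq_len(100) * 20, "2017-09-03", snr = 0)
  meas$snr <- snrs
  sel <- select_high_snr_notes(meas)
  expect_equal(sel$threshold, quantile(1:100, 0.75, names = FALSE))
  expect_equal(sel$threshold, 75.25)
  expect_true(all(sel$notes$snr >= 75.25))
  expect_equal(nrow(sel$notes), 25)

  # all SNRs equal: everything passes the threshold
  meas_eq <- dplyr::mutate(meas, snr = 14)
  sel_eq <- select_high_snr_notes(meas_eq)
  expect_equal(nrow(sel_eq$notes), 100)

  # a day with fewer than 10 qualifying notes is dropped entirely
  day1 <- dplyr::mutate(fake_measurements(seq_len(36) * 20, "2017-09-05"),
                        snr = c(rep(40, 10), rep(20, 26)))
  day2 <- dplyr::mutate(fake_measurements(seq_len(12) * 20, "2017-09-07"),
                        snr = c(rep(40, 3), rep(20, 9)))
  sel2 <- select_high_snr_notes(dplyr::bind_rows(day1, day2))
  expect_equal(sel2$threshold, 40)
  expect_true(as.Date("2017-09-05") %in% sel2$notes$date)
  expect_false(as.Date("2017-09-07") %in% sel2$notes$date)
  expect_true(all(sel2$day_counts$kept_day ==
                    (sel2$day_counts$n_notes >= 10)))
})

test_that("effort summary totals are exact sums of the packaged yield table", {
  counts <- nyb_song_counts()
  expect_equal(sum(counts$songs, na.rm = TRUE), 251)
  expect_equal(sum(counts$inis, na.rm = TRUE), 24477)
  by_year <- counts |>
    dplyr::group_by(song_year) |>
    dplyr::summarise(songs = sum(songs, na.rm = TRUE),
                     inis = sum(inis, na.rm = TRUE))
  expect_equal(by_year$songs, c(42, 42, 64, 65, 38))
  expect_equal(by_year$inis, c(3289, 4237, 6983, 5064, 4904))
  eff <- nyb_review_effort()
  expect_equal(sum(eff$days_reviewed), 653)
  expect_equal(sum(eff$hours_reviewed), 1959)
})

test_that("effort summary on synthetic songs matches its cells", {
  meas <- dplyr::bind_rows(
    fake_measurements(seq(0, 150, by = 10) + 50, "2017-09-03", snr = 20),
    fake_measurements(seq(0, 150, by = 10) + 50, "2017-10-03", snr = 20),
    fake_measurements(seq(0, 90, by = 10) + 50, "2017-10-05", snr = 20))
  songs <- build_songs(meas)
  inis <- compute_inis(songs)
  eff <- effort_summary(songs, inis)
  expect_equal(eff$total_songs, sum(eff$cells$songs))
  expect_equal(eff$total_inis, sum(eff$cells$inis))
  expect_equal(eff$total_inis, sum(inis$kept))
  empty <- effort_summary(songs[0, ], inis[0, ])
  expect_equal(empty$total_songs, 0)
  expect_equal(empty$total_inis, 0)
})
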