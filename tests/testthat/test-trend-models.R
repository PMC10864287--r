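seasonal_profile <- function(short = 10, long = 15) {
  # short INIs Sep-Dec, long Mar-Jun, interpolated transitions
  c(short + (long - short) / 3, short + 2 * (long - short) / 3,  # Jan Feb
    long, long, long, long,                                      # Mar-Jun
    short + 2 * (long - short) / 3, short + (long - short) / 3,  # Jul Aug
    short, short, short, short)                                  # Sep-Dec
}

test_that("degenerate flat data gives a near-null month smooth and grand-mean predictions", {
  set.seed(101)
  dat <- simulate_ini_table(rep(12, 12), song_years = 2:4,
                            songs_per_month = 2, inis_per_song = 10,
                            jitter_sd = 0.4, singer_sd = 0)
  fit <- fit_ini_model(dat, "m1")
  sm <- dplyr::filter(tidy(fit), grepl("month", term))
  expect_lt(sm$edf, 2.5)
  pred <- predict_monthly(fit, 3)
  expect_true(all(abs(pred$fit - mean(dat$ini)) < 0.5))
})

test_that("monthly predictions are positive, cyclic and wrap at month 13", {
  set.seed(102)
  dat <- simulate_ini_table(seasonal_profile(), song_years = 2:4)
  fit <- fit_ini_model(dat, "m1")
  p1 <- predict_monthly(fit, 2, months = 1)
  p13 <- predict_monthly(fit, 2, months = 13)
  expect_equal(p1$fit, p13$fit, tolerance = 1e-10)
  pred <- predict_monthly(fit, 2)
  expect_true(all(pred$lower > 0))
  expect_true(all(pred$upper > pred$fit & pred$fit > pred$lower))
  # seasonal structure recovered: fall short, spring long
  expect_lt(mean(pred$fit[pred$month %in% 9:12]),
            mean(pred$fit[pred$month %in% 3:5]))
  expect_error(predict_monthly(fit, 9), "unknown song year")
})

test_that("fitting is invariant to row order", {
  set.seed(103)
  dat <- simulate_ini_table(seasonal_profile(), song_years = 2:3,
                            songs_per_month = 2, inis_per_song = 10)
  fit1 <- fit_ini_model(dat, "m2")
  fit2 <- fit_ini_model(dat[sample(nrow(dat)), ], "m2")
  expect_equal(fit1$aic, fit2$aic, tolerance = 1e-6)
  expect_equal(stats::coef(fit1$fit), stats::coef(fit2$fit),
               tolerance = 1e-6)
  expect_identical(fit1$data_hash, fit2$data_hash)
})

test_that("input validation catches bad designs", {
  set.seed(104)
  dat <- simulate_ini_table(seasonal_profile(), song_years = 2:3,
                            songs_per_month = 1, inis_per_song = 5)
  expect_error(fit_ini_model(dplyr::mutate(dat, ini = ini - 20), "m1"),
               "positive")
  expect_error(fit_ini_model(dplyr::filter(dat, song_year == 2), "m1"),
               "2 song years")
  one_month <- dplyr::filter(dat, month == 3)
  expect_error(fit_ini_model(one_month, "m1"), "month")
  expect_error(fit_ini_model(dat[, c("ini", "month")], "m1"), "missing column")
})

test_that("AIC model selection prefers the generating structure", {
  # shared seasonal pattern across years -> m1; one aberrant year -> m2
  n_seeds <- 8
  m1_wins <- 0
  m2_wins <- 0
  sy4_sig <- 0
  for (s in seq_len(n_seeds)) {
    set.seed(200 + s)
    shared <- simulate_ini_table(seasonal_profile(), song_years = 2:4,
                                 songs_per_month = 2, inis_per_song = 12)
    f1 <- fit_ini_model(shared, "m1")
    f2 <- fit_ini_model(shared, "m2")
    if (select_model(f1, f2)$model == "m1") m1_wins <- m1_wins + 1

    set.seed(300 + s)
    hetero <- dplyr::bind_rows(
      simulate_ini_table(seasonal_profile(), song_years = 2:3,
                         songs_per_month = 2, inis_per_song = 12),
      simulate_ini_table(rep(15, 12), song_years = 4,
                         songs_per_month = 2, inis_per_song = 12))
    h1 <- fit_ini_model(hetero, "m1")
    h2 <- fit_ini_model(hetero, "m2")
    if (select_model(h1, h2)$model == "m2") m2_wins <- m2_wins + 1
    sy4 <- dplyr::filter(tidy(h2), term == "song_year_f4")
    if (sy4$p_value < 0.01) sy4_sig <- sy4_sig + 1
  }
  expect_gte(m1_wins, ceiling(0.75 * n_seeds))
  expect_gte(m2_wins, ceiling(0.75 * n_seeds))
  expect_gte(sy4_sig, ceiling(0.75 * n_seeds))
})

test_that("select_model takes the AIC minimum with a simplicity tie-break", {
  set.seed(105)
  dat <- simulate_ini_table(seasonal_profile(), song_years = 2:3,
                            songs_per_month = 2, inis_per_song = 10)
  f1 <- fit_ini_model(dat, "m1")
  f2 <- fit_ini_model(dat, "m2")
  best <- select_model(f1, f2)
  expect_equal(best$model, c("m1", "m2")[which.min(c(f1$aic, f2$aic))])
  expect_true(is.numeric(attr(best, "aic_margin")))
  # e.g. AICs reported as {-15636, -15710}: the lower (second) wins
  fa <- f1; fa$aic <- -15636
  fb <- f2; fb$aic <- -15710
  expect_equal(select_model(fa, fb)$model, fb$model)
  # equal AICs: fewer coefficients (m1) wins
  fc <- f2; fc$aic <- fa$aic
  expect_equal(select_model(fa, fc)$model, "m1")
  expect_equal(select_model(f1)$model, "m1")
  other <- simulate_ini_table(seasonal_profile(), song_years = 2:3,
                              songs_per_month = 1, inis_per_song = 8)
  f_other <- fit_ini_model(other, "m1")
  expect_error(select_model(f1, f_other), "different data")
})

test_that("spectral models detect injected seasonality but not constant spectra", {
  n_seeds <- 6
  null_ns <- 0
  inj_sig <- 0
  for (s in seq_len(n_seeds)) {
    set.seed(400 + s)
    days <- sample(seq(as.Date("2017-08-01"), as.Date("2019-04-30"), "day"), 60)
    notes <- tidyr::expand_grid(date = days, rep = 1:12) |>
      dplyr::mutate(month = lubridate::month(date),
                    song_year = assign_song_year(date),
                    center_freq = 19.53125 +
                      sample(c(-1, 0, 1), dplyr::n(), TRUE) * 1.953125)
    f0 <- fit_spectral_model(notes, "center_freq")
    p_month <- dplyr::filter(tidy(f0), grepl("month", term))$p_value
    if (p_month > 0.05) null_ns <- null_ns + 1

    inj <- dplyr::mutate(notes, center_freq = center_freq +
                           2 * sin(2 * pi * month / 12))
    f1 <- fit_spectral_model(inj, "center_freq")
    p_inj <- dplyr::filter(tidy(f1), grepl("month", term))$p_value
    if (p_inj < 0.05) inj_sig <- inj_sig + 1
  }
  expect_gte(null_ns, n_seeds - 1)
  expect_equal(inj_sig, n_seeds)
})

test_that("tidy and glance expose the reporting columns", {
  set.seed(106)
  dat <- simulate_ini_table(seasonal_profile(), song_years = 2:3,
                            songs_per_month = 2, inis_per_song = 10)
  fit <- fit_ini_model(dat, "m2")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std_error", "statistic", "p_value",
                    "edf", "ref_df") %in% names(td)))
  expect_true(any(td$type == "parametric") && any(td$type == "smooth"))
  gl <- glance(fit)
  expect_equal(gl$n, nrow(dat))
  expect_true(all(c("adj_r_squared", "AIC") %in% names(gl)))
})
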