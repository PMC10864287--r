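# Seasonal trend models.
#
# Two candidate generalized additive mixed models for INI, both gamma
# with a log link and a per-singer random intercept:
#   m1:  INI ~ s(month, cyclic, k <= 12) + s(song_year, k <= 5)
#   m2:  INI ~ song_year (categorical) + s(month, cyclic, k <= 12,
#                                          by = song_year)
# The month smooth is a cyclic cubic spline with period boundaries at
# month 0.5 and 12.5 (mid-December to mid-December), so predictions are
# continuous from month 12 into month 1. Fits use mgcv with maximum
# likelihood so AICs are comparable across the two fixed-effect
# structures; the final model is the AIC minimiser.

month_knots <- list(month = c(0.5, 12.5))

#' Fit a seasonal INI model
#'
#' @param data A tibble with columns `ini` (s, positive), `month`
#'   (1-12), `song_year` (integer) and `singer` (factor or character).
#'   Typically built by joining [compute_inis()] output.
#' @param model `"m1"` (month smooth plus song-year smooth) or `"m2"`
#'   (categorical song year with a separate month smooth per year).
#' @param k_month Basis dimension cap for the cyclic month smooth.
#' @param k_year Basis dimension cap for the song-year smooth (m1),
#'   reduced automatically to the number of distinct years.
#' @param method Smoothing-parameter estimation criterion; `"ML"` (the
#'   default) keeps AIC comparable between m1 and m2.
#' @return An object of class `fw_trend_fit`: a list with the mgcv
#'   `fit`, the `model` tag, `aic`, `r2` (adjusted), `n`, and the data.
#' @export
fit_ini_model <- function(data, model = c("m1", "m2"), k_month = 12,
                          k_year = 5, method = "ML") {
  model <- match.arg(model)
  need <- c("ini", "month", "song_year", "singer")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    abort(sprintf("`data` is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (any(data$ini <= 0)) abort("INIs must be positive for a gamma model")
  if (dplyr::n_distinct(data$song_year) < 2) {
    abort("singular design: need at least 2 song years")
  }
  if (dplyr::n_distinct(data$month) < 2) {
    abort("singular design: need at least 2 months of data")
  }
  if (dplyr::n_distinct(data$singer) < 2) {
    abort("need at least 2 singers for the random effect")
  }
  df <- data.frame(ini = data$ini, month = as.numeric(data$month),
                   song_year = as.numeric(data$song_year),
                   song_year_f = factor(data$song_year),
                   singer = factor(data$singer))
  n_year <- dplyr::n_distinct(df$song_year)
  if (model == "m1") {
    ky <- min(k_year, n_year)
    form <- if (ky >= 3) {
      stats::as.formula(sprintf(
        "ini ~ s(month, bs = 'cc', k = %d) + s(song_year, k = %d) + s(singer, bs = 're')",
        k_month, ky))
    } else {
      # too few years for a spline: fall back to a linear year term
      stats::as.formula(sprintf(
        "ini ~ s(month, bs = 'cc', k = %d) + song_year + s(singer, bs = 're')",
        k_month))
    }
  } else {
    form <- stats::as.formula(sprintf(
      "ini ~ song_year_f + s(month, bs = 'cc', k = %d, by = song_year_f) + s(singer, bs = 're')",
      k_month))
  }
  fit <- mgcv::gam(form, data = df, family = stats::Gamma(link = "log"),
                   method = method, knots = month_knots)
  new_trend_fit(fit, model = model, data = df, response = "ini")
}

new_trend_fit <- function(fit, model, data, response) {
  s <- summary(fit)
  structure(
    list(fit = fit, model = model, response = response,
         aic = AIC(fit), r2 = s$r.sq, dev_expl = s$dev.expl,
         n = nrow(data),
         data_hash = {
           sorted <- data[order(data[[response]], data$month, data$song_year),
                          c(response, "month", "song_year")]
           rownames(sorted) <- NULL
           rlang::hash(sorted)
         },
         data = tibble::as_tibble(data)),
    class = "fw_trend_fit"
  )
}

#' @export
print.fw_trend_fit <- function(x, ...) {
  cat(sprintf("<fw_trend_fit> %s on %d observations of %s\n",
              x$model, x$n, x$response))
  cat(sprintf("  AIC %.1f, adjusted R^2 %.3f, deviance explained %.1f%%\n",
              x$aic, x$r2, 100 * x$dev_expl))
  invisible(x)
}

#' @rdname fit_ini_model
#' @param x,object An `fw_trend_fit`.
#' @param ... Unused.
#' @method tidy fw_trend_fit
#' @export
tidy.fw_trend_fit <- function(x, ...) {
  s <- summary(x$fit)
  pt <- s$p.table
  parametric <- tibble::tibble(
    term = rownames(pt), type = "parametric",
    estimate = pt[, "Estimate"], std_error = pt[, "Std. Error"],
    statistic = pt[, 3], p_value = pt[, 4],
    edf = NA_real_, ref_df = NA_real_)
  st <- s$s.table
  smooths <- tibble::tibble(
    term = rownames(st), type = "smooth",
    estimate = NA_real_, std_error = NA_real_,
    statistic = st[, "F"], p_value = st[, 4],
    edf = st[, "edf"], ref_df = st[, "Ref.df"])
  dplyr::bind_rows(parametric, smooths)
}

#' @rdname fit_ini_model
#' @method glance fw_trend_fit
#' @export
glance.fw_trend_fit <- function(x, ...) {
  tibble::tibble(model = x$model, n = x$n, adj_r_squared = x$r2,
                 deviance_explained = x$dev_expl, AIC = x$aic)
}

#' Select the best trend model by AIC
#'
#' @param ... `fw_trend_fit` objects (or a single list of them), all
#'   fitted to identical data.
#' @return The AIC-minimising fit (ties go to the fit with fewer
#'   coefficients), with the AIC margin to the runner-up attached as
#'   attribute `"aic_margin"`.
#' @export
select_model <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "fw_trend_fit")) {
    fits <- fits[[1]]
  }
  stopifnot(all(vapply(fits, inherits, logical(1), "fw_trend_fit")))
  if (length(fits) == 1) return(fits[[1]])
  hashes <- vapply(fits, function(f) f$data_hash, character(1))
  if (length(unique(hashes)) != 1) {
    abort("cannot compare models fitted to different data")
  }
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  npar <- vapply(fits, function(f) length(stats::coef(f$fit)), numeric(1))
  best <- order(aics, npar)[1]
  out <- fits[[best]]
  attr(out, "aic_margin") <- sort(aics)[2] - aics[best]
  out
}

wrap_month <- function(month) ((month - 0.5) %% 12) + 0.5

#' Monthly predictions from a fitted trend model
#'
#' Expected INI (or spectral value) by month for one song year, with a
#' frequentist 95% confidence band, on the response scale. The random
#' intercept is excluded (population-level prediction). Months wrap
#' cyclically: month 13 predicts identically to month 1.
#'
#' @param fit An `fw_trend_fit`.
#' @param song_year Song year to predict for (must have been observed).
#' @param months Months to predict at (default 1-12; values outside
#'   1-12 are wrapped).
#' @param level Confidence level.
#' @return A tibble with `month`, `song_year`, `fit`, `lower`, `upper`.
#' @export
predict_monthly <- function(fit, song_year, months = 1:12, level = 0.95) {
  stopifnot(inherits(fit, "fw_trend_fit"))
  df <- fit$data
  if (!song_year %in% df$song_year) {
    abort(sprintf("unknown song year: %s", song_year))
  }
  re_term <- grep("singer|date_f", sapply(fit$fit$smooth, `[[`, "label"),
                  value = TRUE)
  nd <- data.frame(month = wrap_month(months),
                   song_year = as.numeric(song_year),
                   song_year_f = factor(song_year,
                                        levels = levels(df$song_year_f)),
                   singer = factor(df$singer[1], levels = levels(df$singer)))
  if ("date_f" %in% names(df)) {
    nd$date_f <- factor(df$date_f[1], levels = levels(df$date_f))
  }
  pr <- predict(fit$fit, newdata = nd, type = "link", se.fit = TRUE,
                exclude = re_term, newdata.guaranteed = TRUE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  inv <- fit$fit$family$linkinv
  out <- tibble::tibble(
    month = months, song_year = song_year,
    fit = inv(as.numeric(pr$fit)),
    lower = inv(as.numeric(pr$fit) - z * as.numeric(pr$se.fit)),
    upper = inv(as.numeric(pr$fit) + z * as.numeric(pr$se.fit)))
  if (identical(fit$fit$family$link, "identity") && any(out$lower < 0)) {
    warn("identity-link predictions dip below zero; interpret with care")
  }
  out
}

#' Fit a spectral-characteristic trend model
#'
#' Generalized additive model for a per-note spectral measurement
#' (center frequency, peak frequency or 90% bandwidth) of high-SNR
#' notes: cyclic month smooth (k <= 10; late-spring months are often
#' absent), song-year smooth (k <= 5), gamma family with identity link
#' and a per-date random intercept for within-day dependence.
#'
#' @param notes High-SNR note measurements (see
#'   [select_high_snr_notes()]) with the response column, `month`,
#'   `song_year` and `date`.
#' @param response One of `"center_freq"`, `"peak_freq"`, `"bw90"`.
#' @param k_month,k_year Basis dimension caps.
#' @param method Smoothing-parameter criterion.
#' @return An `fw_trend_fit`.
#' @export
fit_spectral_model <- function(notes,
                               response = c("center_freq", "peak_freq", "bw90"),
                               k_month = 10, k_year = 5, method = "ML") {
  response <- match.arg(response)
  if (!response %in% names(notes)) {
    abort(sprintf("`notes` lacks the response column `%s`", response))
  }
  if (any(notes[[response]] <= 0)) {
    abort("spectral responses must be positive for a gamma model")
  }
  df <- data.frame(y = notes[[response]], month = as.numeric(notes$month),
                   song_year = as.numeric(notes$song_year),
                   song_year_f = factor(notes$song_year),
                   date_f = factor(notes$date),
                   singer = factor(notes$date))
  ky <- min(k_year, dplyr::n_distinct(df$song_year))
  year_term <- if (ky >= 3) sprintf("s(song_year, k = %d)", ky) else "song_year"
  form <- stats::as.formula(sprintf(
    "y ~ s(month, bs = 'cc', k = %d) + %s + s(date_f, bs = 're')",
    k_month, year_term))
  fit <- mgcv::gam(form, data = df,
                   family = stats::Gamma(link = "identity"),
                   method = method, knots = month_knots)
  tf <- new_trend_fit(fit, model = paste0("spectral_", response),
                      data = df, response = "y")
  tf$response <- response
  tf
}
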