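check_contiguous <- function(series) {
  ord <- order(series$year, series$month)
  series <- series[ord, , drop = FALSE]
  idx <- series$year * 12 + (series$month - 1)
  if (nrow(series) < 2L || any(diff(idx) != 1L))
    stop_facetdiv("climate series must be contiguous monthly records",
                  "contiguity_error")
  if (any(series$precip_mm < 0) || any(series$pet_mm < 0))
    stop_facetdiv("precipitation and PET must be non-negative",
                  "invalid_argument")
  series
}

single_plot <- function(series) {
  if (!is.null(series$plot_id) && length(unique(series$plot_id)) > 1L)
    stop_facetdiv("this operation expects a single plot's series",
                  "invalid_argument")
  series
}

# Wettest calendar month of the full-period precipitation climatology;
# ties broken by the earliest month.  Used to anchor the hydrological year.
wettest_month <- function(series) {
  clim <- tapply(series$precip_mm, series$month, mean)
  as.integer(names(clim)[which.max(clim)])
}

#' Monthly cumulative water deficit (CWD) series
#'
#' Running water balance `WD_m = min(0, WD_{m-1} + P_m - PET_m)`, reset to
#' zero at the start of each hydrological year.  The hydrological year is
#' anchored at the climatologically wettest calendar month of the series
#' (ties to the earliest month).  `mode = "monthly"` instead returns the
#' memoryless monthly deficit `min(0, P_m - PET_m)`.
#'
#' @param series single-plot climate data.frame with columns `year`,
#'   `month`, `precip_mm`, `pet_mm` (contiguous months).
#' @param mode `"cumulative"` (running deficit with annual reset, the
#'   default) or `"monthly"`.
#' @return the input rows (time-ordered) with added columns `cwd` (mm,
#'   `<= 0`) and `hydro_year` (calendar year in which the hydrological year
#'   began).
#' @export
cwd_series <- function(series, mode = c("cumulative", "monthly")) {
  mode <- match.arg(mode)
  series <- check_contiguous(single_plot(series))
  anchor <- wettest_month(series)
  hydro <- series$year - (series$month < anchor)
  balance <- series$precip_mm - series$pet_mm
  if (mode == "monthly") {
    cwd <- pmin(0, balance)
  } else {
    cwd <- numeric(nrow(series))
    wd <- 0
    prev <- hydro[1L] - 1L
    for (i in seq_len(nrow(series))) {
      if (hydro[i] != prev) { wd <- 0; prev <- hydro[i] }
      wd <- min(0, wd + balance[i])
      cwd[i] <- wd
    }
  }
  series$cwd <- cwd
  series$hydro_year <- hydro
  series
}

#' Maximum climatological water deficit (MCWD) over a window
#'
#' The most negative CWD value of each hydrological year, aggregated over
#' the years of a climatology window.  The default aggregation is the mean
#' of the yearly minima (a climatological mean MCWD); `aggregate = "min"`
#' gives the single most extreme year instead.  Only complete hydrological
#' years whose start falls inside the window are used.
#'
#' @inheritParams cwd_series
#' @param window inclusive calendar-year range `c(first, last)`.
#' @param aggregate `"mean"` (default) or `"min"` over the yearly minima.
#' @return MCWD in mm, always `<= 0`.
#' @export
mcwd <- function(series, window, mode = c("cumulative", "monthly"),
                 aggregate = c("mean", "min")) {
  aggregate <- match.arg(aggregate)
  cw <- cwd_series(series, match.arg(mode))
  check_window(cw, window)
  complete <- tapply(cw$month, cw$hydro_year, length) == 12L
  yearly_min <- tapply(cw$cwd, cw$hydro_year, min)
  years <- as.integer(names(yearly_min))
  use <- complete & years >= window[1L] & years <= window[2L]
  if (!any(use))
    stop_facetdiv("no complete hydrological years inside the window",
                  "range_error")
  if (aggregate == "mean") mean(yearly_min[use]) else min(yearly_min[use])
}

check_window <- function(series, window) {
  if (length(window) != 2L || window[1L] > window[2L])
    stop_facetdiv("window must be c(first_year, last_year)", "invalid_argument")
  if (window[1L] < min(series$year) || window[2L] > max(series$year))
    stop_facetdiv("window outside the series' coverage", "range_error")
  invisible(window)
}

#' Mean vapour pressure deficit over a window
#'
#' @inheritParams mcwd
#' @param series single-plot climate data.frame including a `vpd_kpa`
#'   column.
#' @return arithmetic mean monthly VPD (kPa) over the window's months.
#' @export
vpd_summary <- function(series, window) {
  series <- check_contiguous(single_plot(series))
  check_window(series, window)
  sel <- series$year >= window[1L] & series$year <= window[2L]
  mean(series$vpd_kpa[sel])
}

#' Standardized precipitation-evapotranspiration index (SPEI)
#'
#' The climatic balance `D = P - PET` is accumulated over rolling windows of
#' `window_months` months; for each calendar month a three-parameter
#' log-logistic distribution is fitted to the accumulated values by unbiased
#' probability-weighted moments, and each value is mapped through the fitted
#' CDF to a standard-normal quantile.  A month whose sample L-skewness is
#' negative (no valid log-logistic shape) is fitted on the reflected sample
#' and mapped back.  Months whose fit is degenerate (zero
#' interannual variance or an invalid shape parameter) return `NA` with a
#' warning.  Fitted probabilities are clamped to `[0.0005, 0.9995]`, so SPEI
#' values are bounded at about +/-3.29.
#'
#' @inheritParams cwd_series
#' @param window_months accumulation window in months (default 12).
#' @return the input rows (time-ordered) with an added `spei` column; the
#'   first `window_months - 1` values are `NA` by construction.
#' @export
spei <- function(series, window_months = 12L) {
  series <- check_contiguous(single_plot(series))
  if (nrow(series) < 30L * 12L)
    warn_facetdiv("fewer than 30 years of data; SPEI distribution fits may be unstable",
                  "short_series")
  d <- series$precip_mm - series$pet_mm
  acc <- stats::filter(d, rep(1, window_months), sides = 1L)
  acc <- as.numeric(acc)
  spei_vals <- rep(NA_real_, length(acc))
  degenerate <- character(0)
  for (m in sort(unique(series$month))) {
    idx <- which(series$month == m & !is.na(acc))
    x <- acc[idx]
    if (length(x) < 4L) next
    fit <- loglogistic_lmom(x)
    reflected <- FALSE
    if (is.null(fit)) {
      # negative L-skewness: fit the reflected sample and map back
      fit <- loglogistic_lmom(-x)
      reflected <- TRUE
    }
    if (is.null(fit)) {
      degenerate <- c(degenerate, month.abb[m])
      next
    }
    p <- if (reflected) 1 - loglogistic_cdf(-x, fit) else loglogistic_cdf(x, fit)
    p <- pmin(pmax(p, 5e-4), 1 - 5e-4)
    spei_vals[idx] <- stats::qnorm(p)
  }
  if (length(degenerate))
    warn_facetdiv(paste0("degenerate SPEI distribution fit for: ",
                         paste(degenerate, collapse = ", ")),
                  "degenerate_distribution")
  series$spei <- spei_vals
  series
}

# Three-parameter log-logistic fit by unbiased probability-weighted moments
# (b0, b1, b2).  Returns NULL when the sample is degenerate or the implied
# shape parameter does not admit a valid distribution (beta <= 1).
loglogistic_lmom <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(NULL)
  xs <- sort(x)
  j <- seq_len(n)
  b0 <- mean(xs)
  b1 <- sum((j - 1) / (n - 1) * xs) / n
  b2 <- sum((j - 1) * (j - 2) / ((n - 1) * (n - 2)) * xs) / n
  # complement-order PWMs w_s = E[X (1 - F)^s] from the ascending b_r
  w0 <- b0
  w1 <- b0 - b1
  w2 <- b0 - 2 * b1 + b2
  denom <- 6 * w1 - w0 - 6 * w2
  if (denom == 0) return(NULL)
  beta <- (2 * w1 - w0) / denom
  if (!is.finite(beta) || beta <= 1) return(NULL)
  g12 <- gamma(1 + 1 / beta) * gamma(1 - 1 / beta)
  alpha <- (w0 - 2 * w1) * beta / g12
  if (!is.finite(alpha) || alpha <= 0) return(NULL)
  gam <- w0 - alpha * g12
  list(alpha = alpha, beta = beta, gamma = gam)
}

loglogistic_cdf <- function(x, fit) {
  z <- x - fit$gamma
  p <- numeric(length(x))
  pos <- z > 0
  p[pos] <- 1 / (1 + (fit$alpha / z[pos])^fit$beta)
  p[!pos] <- 0
  p
}

#' Window climatologies of the climate drivers for many plots
#'
#' Computes MCWD, mean VPD and mean SPEI for each plot over each requested
#' window (by default the two 30-year census climatologies and the full
#' study period).
#'
#' @param climate climate data.frame for one or more plots (`plot_id`,
#'   `year`, `month`, `precip_mm`, `pet_mm`, `vpd_kpa`).
#' @param windows named list of inclusive year ranges.
#' @param mode CWD mode passed to [mcwd()].
#' @return data.frame with one row per plot and window: `plot_id`,
#'   `window`, `mcwd`, `vpd_mean`, `spei_mean`.
#' @export
climate_summary <- function(climate,
                            windows = list(T1 = c(1964, 1993),
                                           T2 = c(1984, 2013),
                                           Full = c(1964, 2013)),
                            mode = "cumulative") {
  plots <- unique(climate$plot_id)
  rows <- list()
  for (p in plots) {
    ser <- climate[climate$plot_id == p, , drop = FALSE]
    sp <- spei(ser)
    for (wn in names(windows)) {
      w <- windows[[wn]]
      sel <- sp$year >= w[1L] & sp$year <= w[2L]
      rows[[length(rows) + 1L]] <- data.frame(
        plot_id = p, window = wn,
        mcwd = mcwd(ser, w, mode = mode),
        vpd_mean = vpd_summary(ser, w),
        spei_mean = mean(sp$spei[sel], na.rm = TRUE))
    }
  }
  do.call(rbind, rows)
}

#' Absolute driver changes between the two census climatologies
#'
#' `delta_X_abs = X_T2 - X_T1` for MCWD, VPD and SPEI, carrying the
#' full-period MCWD and VPD alongside.  A drying trend (more negative MCWD
#' in T2) therefore yields `d_mcwd_abs < 0`.
#'
#' @param summaries output of [climate_summary()] containing windows `T1`,
#'   `T2` and `Full` for every plot.
#' @return data.frame with one row per plot: `plot_id`, `d_mcwd_abs`,
#'   `d_vpd_abs`, `d_spei_abs`, `mcwd_full`, `vpd_full`.
#' @export
driver_changes <- function(summaries) {
  need <- c("T1", "T2", "Full")
  rows <- lapply(unique(summaries$plot_id), function(p) {
    s <- summaries[summaries$plot_id == p, , drop = FALSE]
    if (!all(need %in% s$window))
      stop_facetdiv(sprintf("plot %s is missing a window summary", p),
                    "range_error")
    g <- function(w, col) s[s$window == w, col][1L]
    data.frame(plot_id = p,
               d_mcwd_abs = g("T2", "mcwd") - g("T1", "mcwd"),
               d_vpd_abs = g("T2", "vpd_mean") - g("T1", "vpd_mean"),
               d_spei_abs = g("T2", "spei_mean") - g("T1", "spei_mean"),
               mcwd_full = g("Full", "mcwd"),
               vpd_full = g("Full", "vpd_mean"))
  })
  do.call(rbind, rows)
}
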