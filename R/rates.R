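#' Annual rate of change between two censuses
#'
#' `(x2 - x1) / (t2 - t1)` with census dates in decimal years, so that
#' plots with different census intervals are comparable.
#'
#' @param x1,x2 diversity values at the first and second census.
#' @param t1,t2 census dates (decimal years), `t2 > t1`.
#' @return per-year rate of change.
#' @export
annual_rate <- function(x1, x2, t1, t2) {
  if (any(t2 - t1 <= 0))
    stop_facetdiv("census interval must be positive", "invalid_argument")
  (x2 - x1) / (t2 - t1)
}

#' Dry/wet classification by first-census MCWD
#'
#' Plots with a first-period MCWD at or below the threshold (default
#' -250 mm, the wet-forest to seasonal-forest transition) are classified
#' dry; the threshold itself is inclusive on the dry side.
#'
#' @param mcwd_t1 first-period MCWD in mm (`<= 0`).
#' @param threshold classification threshold in mm (default -250).
#' @return character vector of `"dry"` / `"wet"`.
#' @export
classify_wet_dry <- function(mcwd_t1, threshold = -250) {
  if (any(!is.finite(mcwd_t1)))
    stop_facetdiv("MCWD values must be finite", "invalid_argument")
  ifelse(mcwd_t1 <= threshold, "dry", "wet")
}

#' Per-plot annual rates of diversity change with dry/wet grouping
#'
#' Pairs each plot's first and last census diversity records, converts every
#' diversity column to an annual rate, and attaches the dry/wet group from
#' the plot's first-period MCWD.
#'
#' @param diversity data.frame with columns `plot_id`, `census_date` and one
#'   column per diversity metric (e.g. `fdis`, `simpson`, `mpd`); two rows
#'   per plot.
#' @param climate_summaries output of [climate_summary()] providing the `T1`
#'   MCWD per plot.
#' @param threshold dry/wet MCWD threshold in mm.
#' @return data.frame with one row per plot: `plot_id`, `interval`, `group`
#'   and a `d_<metric>_r` column per metric.
#' @export
rate_records <- function(diversity, climate_summaries, threshold = -250) {
  metrics <- setdiff(names(diversity), c("plot_id", "census_date"))
  rows <- lapply(unique(diversity$plot_id), function(p) {
    d <- diversity[diversity$plot_id == p, , drop = FALSE]
    d <- d[order(d$census_date), , drop = FALSE]
    if (nrow(d) < 2L)
      stop_facetdiv(sprintf("plot %s has fewer than two censuses", p),
                    "invalid_argument")
    first <- d[1L, ]
    last <- d[nrow(d), ]
    interval <- last$census_date - first$census_date
    if (interval < 10)
      warn_facetdiv(sprintf("plot %s census interval %.1f yr is below 10 yr", p,
                            interval), "short_interval")
    out <- data.frame(plot_id = p, interval = interval)
    for (m in metrics)
      out[[paste0("d_", m, "_r")]] <-
        annual_rate(first[[m]], last[[m]], first$census_date, last$census_date)
    out
  })
  rates <- do.call(rbind, rows)
  t1 <- climate_summaries[climate_summaries$window == "T1", , drop = FALSE]
  mcwd_t1 <- t1$mcwd[match(rates$plot_id, t1$plot_id)]
  rates$group <- classify_wet_dry(mcwd_t1, threshold)
  rates
}

#' Basal-area-change diagnostics for diversity rates
#'
#' Pearson correlation (and p-value) between each plot's change in total
#' basal area and its rate of change in each diversity facet — a check that
#' diversity trends are not an artefact of biomass trends.
#'
#' @param ba_change named or plot-ordered numeric vector of basal-area
#'   changes (m^2), one per plot.
#' @param rates data.frame of rate columns (`d_*_r`) from [rate_records()].
#' @return data.frame with one row per facet: `facet`, `r`, `p_value`.
#' @export
ba_change_diagnostics <- function(ba_change, rates) {
  if (length(ba_change) < 3L)
    stop_facetdiv("need at least 3 plots for correlation diagnostics",
                  "invalid_argument")
  facets <- grep("^d_.*_r$", names(rates), value = TRUE)
  rows <- lapply(facets, function(f) {
    y <- rates[[f]]
    if (stats::sd(ba_change) == 0 || stats::sd(y) == 0) {
      warn_facetdiv(sprintf("zero variance in %s diagnostics; recording NA", f),
                    "degenerate_input")
      return(data.frame(facet = f, r = NA_real_, p_value = NA_real_))
    }
    ct <- stats::cor.test(ba_change, y)
    data.frame(facet = f, r = unname(ct$estimate), p_value = ct$p.value)
  })
  do.call(rbind, rows)
}
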