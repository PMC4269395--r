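# Temporal statistics of the multinational-study series: annual counts,
# growth rates, and peak detection.

#' Annual counts of multinational studies
#'
#' Counts multinational studies by start year on a contiguous year axis from
#' the earliest to the latest observed year (gap years are zero-filled) and
#' computes the mean number of countries per study for each year. Studies
#' with a missing start year are excluded and their number reported via a
#' message.
#'
#' @param registry A [trial_registry()] of multinational studies.
#' @param quiet Suppress the excluded-count message.
#' @return Object of class `trend_series`: data frame with columns `year`,
#'   `n_studies`, `mean_countries` (`NA` for zero-count years).
#' @export
studies_per_year <- function(registry, quiet = FALSE) {
  stopifnot(inherits(registry, "trial_registry"))
  if (any(lengths(registry$countries) < 2L)) {
    stop("trend series requires studies filtered to multinational")
  }
  dated <- !is.na(registry$start_year)
  if (!quiet && sum(!dated) > 0) {
    message(sum(!dated), " undated studies excluded from trend series")
  }
  reg <- registry[dated, , drop = FALSE]
  if (nrow(reg) == 0L) {
    out <- data.frame(year = integer(0), n_studies = integer(0),
                      mean_countries = numeric(0))
    class(out) <- c("trend_series", "data.frame")
    return(out)
  }
  years <- seq(min(reg$start_year), max(reg$start_year))
  cnt <- table(factor(reg$start_year, levels = years))
  k <- lengths(reg$countries)
  mk <- tapply(k, factor(reg$start_year, levels = years), mean)
  out <- data.frame(year = years, n_studies = as.integer(cnt),
                    mean_countries = as.numeric(mk))
  class(out) <- c("trend_series", "data.frame")
  out
}

#' Year-over-year growth of a trend series
#'
#' g_t = (n_t - n_(t-1)) / n_(t-1). Growth is undefined (reported as `NA`,
#' not zero) for years preceded by a zero count.
#'
#' @param series A `trend_series` with at least two years.
#' @return Data frame with columns `year`, `growth`, one row per year after
#'   the first.
#' @export
yoy_growth <- function(series) {
  stopifnot(inherits(series, "trend_series"))
  if (nrow(series) < 2L) stop("growth requires a series of length >= 2")
  n <- series$n_studies
  prev <- utils::head(n, -1L)
  g <- (utils::tail(n, -1L) - prev) / prev
  g[prev == 0L] <- NA_real_
  data.frame(year = utils::tail(series$year, -1L), growth = g)
}

#' Annualized growth over a year window
#'
#' `mean_yoy` (default): the arithmetic mean of the defined year-over-year
#' growth fractions for years in (y0, y1]. `cagr`: the compound annual
#' growth rate (n_y1 / n_y0)^(1 / (y1 - y0)) - 1, which depends only on the
#' endpoints and requires a non-zero count at y0.
#'
#' @param series A `trend_series`.
#' @param y0,y1 Window endpoints, both present in the series, `y0 < y1`.
#' @param method `"mean_yoy"` or `"cagr"`.
#' @return List with elements `value`, `method`, `from`, `to`.
#' @export
annualized_growth <- function(series, y0, y1,
                              method = c("mean_yoy", "cagr")) {
  stopifnot(inherits(series, "trend_series"))
  method <- match.arg(method)
  if (!(y0 %in% series$year) || !(y1 %in% series$year)) {
    stop("window endpoints must be years present in the series")
  }
  if (y0 >= y1) stop("y0 must precede y1")
  if (method == "mean_yoy") {
    g <- yoy_growth(series)
    g <- g[g$year > y0 & g$year <= y1, , drop = FALSE]
    value <- mean(g$growth, na.rm = TRUE)
  } else {
    n0 <- series$n_studies[series$year == y0]
    n1 <- series$n_studies[series$year == y1]
    if (n0 == 0L) stop("CAGR undefined: zero count at window start")
    value <- (n1 / n0)^(1 / (y1 - y0)) - 1
  }
  list(value = value, method = method, from = y0, to = y1)
}

#' Peak year of a trend series
#'
#' @param series A non-empty `trend_series`.
#' @return List with elements `year` and `n_studies`; the earliest year wins
#'   ties.
#' @export
peak_year <- function(series) {
  stopifnot(inherits(series, "trend_series"))
  if (nrow(series) == 0L) stop("peak of an empty series is undefined")
  i <- which.max(series$n_studies)
  list(year = series$year[i], n_studies = series$n_studies[i])
}

#' Write a trend series and summary to disk
#'
#' Writes `trends.csv` (year, n_studies, mean_countries, yoy_growth) and
#' `trend_summary.json` (peak and annualized growth with its method tag).
#'
#' @param series A `trend_series`.
#' @param dir Output directory (created if missing).
#' @param growth_window Optional length-2 vector of years for annualized
#'   growth; defaults to the full series range.
#' @param method Growth method, see [annualized_growth()].
#' @return `dir`, invisibly.
#' @export
write_trend_series <- function(series, dir, growth_window = NULL,
                               method = c("mean_yoy", "cagr")) {
  stopifnot(inherits(series, "trend_series"))
  method <- match.arg(method)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- as.data.frame(series)
  df$yoy_growth <- NA_real_
  if (nrow(df) >= 2L) {
    g <- yoy_growth(series)
    df$yoy_growth[match(g$year, df$year)] <- g$growth
  }
  utils::write.csv(df, file.path(dir, "trends.csv"), row.names = FALSE)
  summary <- list(n_years = nrow(df),
                  n_studies_total = sum(df$n_studies))
  if (nrow(df) > 0L) summary$peak <- peak_year(series)
  if (nrow(df) >= 2L) {
    if (is.null(growth_window)) {
      growth_window <- range(series$year)
    }
    summary$annualized_growth <- annualized_growth(
      series, growth_window[1], growth_window[2], method = method)
  }
  jsonlite::write_json(summary, file.path(dir, "trend_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
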