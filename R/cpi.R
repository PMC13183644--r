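#' Generate a consumer price index series
#'
#' Builds an annual CPI series anchored at 100 in the base year, growing at a
#' fixed rate with optional multiplicative jitter on each yearly step. Used by
#' the synthetic cohort generator; real analyses should supply a published
#' CPI series via [read_cpi()].
#'
#' @param base_year Year whose index is fixed at 100.
#' @param years Integer vector of calendar years the series must cover
#'   (default 2015--2025). Must contain `base_year`.
#' @param growth Annual growth rate (e.g. 0.02 for 2\% inflation); must
#'   exceed -1.
#' @param seed Integer seed for the jitter; ignored when `jitter_sd = 0`.
#' @param jitter_sd Standard deviation of the mean-zero Gaussian perturbation
#'   added to the growth rate each year (default 0, a deterministic series).
#'
#' @return Named numeric vector of index values (names are years), strictly
#'   positive, with `series[as.character(base_year)] == 100`.
#' @examples
#' generate_cpi(2015, 2015:2025, growth = 0.02)
#' @export
generate_cpi <- function(base_year = 2015, years = 2015:2025, growth = 0.02,
                         seed = 1L, jitter_sd = 0) {
  stopifnot(growth > -1, jitter_sd >= 0)
  years <- sort(unique(as.integer(years)))
  if (!base_year %in% years) stop_drg("base_year not in years", class = "series_error")
  steps <- rep(growth, length(years) - 1L)
  if (jitter_sd > 0) {
    set.seed(as.integer(seed))
    steps <- steps + stats::rnorm(length(steps), 0, jitter_sd)
  }
  # build forward from the first year, then rescale so base_year = 100
  idx <- cumprod(c(1, 1 + steps))
  idx <- 100 * idx / idx[match(base_year, years)]
  names(idx) <- years
  idx
}

#' Read a CPI series from a two-column CSV
#'
#' @param path CSV file with columns `year` and `index`.
#' @return Named numeric vector as from [generate_cpi()].
#' @export
read_cpi <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("year", "index") %in% names(df)))
    stop_drg("CPI file must have columns 'year' and 'index'", class = "series_error")
  if (any(df$index <= 0)) stop_drg("CPI index values must be positive", class = "series_error")
  idx <- df$index
  names(idx) <- df$year
  idx
}

#' Deflate nominal amounts to base-year prices
#'
#' Standardizes nominal yuan amounts to the price level of `base_year` using
#' the ratio of CPI index values: `amount * cpi[base_year] / cpi[year]`.
#'
#' @param amount Numeric vector of nominal amounts (yuan), each >= 0.
#' @param year Calendar year(s) of the amounts (recycled against `amount`).
#' @param cpi Named numeric CPI series ([generate_cpi()] / [read_cpi()]).
#' @param base_year Base year of the standardization (default 2015).
#' @return Numeric vector of real (base-year) amounts.
#' @examples
#' cpi <- generate_cpi(2015, 2015:2020, growth = 0.02)
#' deflate(1000, 2020, cpi)
#' @export
deflate <- function(amount, year, cpi, base_year = 2015) {
  stopifnot(all(amount >= 0 | is.na(amount)))
  keys <- as.character(year)
  if (!as.character(base_year) %in% names(cpi))
    stop_drg("base year ", base_year, " missing from CPI series", class = "series_error")
  if (any(!keys %in% names(cpi)))
    stop_drg("year(s) ", paste(unique(keys[!keys %in% names(cpi)]), collapse = ", "),
             " missing from CPI series", class = "series_error")
  amount * cpi[[as.character(base_year)]] / unname(cpi[keys])
}

#' Natural-log transform with an optional additive offset
#'
#' `log(amount + offset)`. Total expenses are strictly positive and use
#' offset 0; out-of-pocket payments can be exactly zero (fully reimbursed
#' admissions), so the pipeline defaults to offset 1 yuan for them.
#'
#' @param amount Non-negative numeric vector (yuan).
#' @param offset Non-negative scalar added before taking the log.
#' @return `log(amount + offset)`.
#' @export
log_transform <- function(amount, offset = 0) {
  stopifnot(offset >= 0, all(amount >= 0 | is.na(amount)))
  if (any(amount + offset == 0, na.rm = TRUE))
    stop_drg("log undefined: amount + offset is zero", class = "domain_error")
  log(amount + offset)
}
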