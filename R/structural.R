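# Structural variation of itemized expense shares: VSV, DSV, CRSV.

#' Yearly item shares of total expenses
#'
#' For each discharge year, the share of each of the seven expense items in
#' total expenses. The default `"aggregate"` mode is the ratio of sums
#' (yearly item total over yearly grand total), which equals the ratio of
#' per-admission averages; `"mean_ratio"` instead averages each admission's
#' own item proportions.
#'
#' @param data Data frame with a year column and the seven item columns plus
#'   a total column. Column names may carry a common suffix (e.g. the
#'   `_real` columns of [code_records()]), resolved automatically.
#' @param year_col Name of the year column (default `"discharge_year"`).
#' @param mode `"aggregate"` (default) or `"mean_ratio"`.
#' @return Matrix of shares, rows = years (rownames), columns =
#'   [expense_items()]; every row sums to 1.
#' @export
annual_item_shares <- function(data, year_col = "discharge_year",
                               mode = c("aggregate", "mean_ratio")) {
  mode <- match.arg(mode)
  if (!year_col %in% names(data)) {
    if ("discharge_date" %in% names(data)) {
      data[[year_col]] <- as.integer(format(as.Date(data$discharge_date), "%Y"))
    } else stop_drg("no year column found", class = "domain_error")
  }
  suffix <- if (all(paste0(expense_items(), "_real") %in% names(data))) "_real" else ""
  item_cols <- paste0(expense_items(), suffix)
  total_col <- if (suffix == "_real") "total_real" else "total"
  stopifnot(all(c(item_cols, total_col) %in% names(data)))

  years <- sort(unique(data[[year_col]]))
  shares <- t(vapply(years, function(y) {
    d <- data[data[[year_col]] == y, , drop = FALSE]
    tot <- d[[total_col]]
    if (sum(tot) <= 0) stop_drg("year ", y, " has zero total expense", class = "domain_error")
    if (mode == "aggregate") {
      colSums(d[item_cols]) / sum(tot)
    } else {
      colMeans(d[item_cols] / tot)
    }
  }, numeric(7)))
  dimnames(shares) <- list(years, expense_items())
  shares
}

#' Structural Variation Value: change in item shares between two time points
#'
#' Elementwise `p_end - p_start`. A positive entry marks an item whose share
#' of total expenses grew over the period, a negative entry one that shrank.
#'
#' @param p_start,p_end Share vectors of equal length (period start / end).
#' @return Numeric vector of share changes.
#' @export
vsv <- function(p_start, p_end) {
  if (length(p_start) != length(p_end))
    stop_drg("share vectors differ in length", class = "domain_error")
  p_end - p_start
}

#' Degree of Structural Variation: total absolute share change
#'
#' The sum of absolute VSVs over the items, measuring the magnitude of
#' compositional churn in a period regardless of direction.
#'
#' @param vsv_vector Vector of structural variation values (share units).
#' @param as_percent Return percent (default) rather than a fraction.
#' @return Scalar DSV.
#' @examples
#' dsv(c(-0.092, 0.0547, 0.1663, -0.2015, -0.0023, 0.069, 0.0059))  # 59.17
#' @export
dsv <- function(vsv_vector, as_percent = TRUE) {
  out <- sum(abs(vsv_vector))
  if (as_percent) 100 * out else out
}

#' Contribution Rate of Structural Variation
#'
#' Each item's share of the total absolute compositional change:
#' `|VSV_i| / sum(|VSV|) * 100`.
#'
#' @param vsv_vector Vector of structural variation values.
#' @return Vector of percents summing to 100.
#' @export
crsv <- function(vsv_vector) {
  d <- sum(abs(vsv_vector))
  if (d == 0)
    stop_drg("all-zero VSV vector: contributions undefined", class = "domain_error")
  100 * abs(vsv_vector) / d
}

#' Structural-change table over a set of periods
#'
#' Computes VSV, DSV and CRSV for each period. By default the periods are
#' every consecutive year pair plus the full first-to-last span, the layout
#' of a published multi-year structural-change table. Consecutive VSVs
#' telescope: per item they sum exactly to the overall VSV.
#'
#' @param shares Share matrix from [annual_item_shares()] (rows = years).
#' @param periods Optional list of `c(start_year, end_year)` pairs.
#' @return Object of class `structural_change`: list with `vsv` (period x
#'   item matrix), `dsv` (named percent vector), `crsv` (period x item
#'   percent matrix) and `periods`.
#' @export
structural_change <- function(shares, periods = NULL) {
  years <- as.integer(rownames(shares))
  if (is.null(periods)) {
    periods <- lapply(seq_len(length(years) - 1L),
                      function(i) c(years[i], years[i + 1L]))
    if (length(years) > 2L) periods <- c(periods, list(range(years)))
  }
  labels <- vapply(periods, function(p) paste0(p[1], "-", p[2]), "")
  miss <- setdiff(unique(unlist(periods)), years)
  if (length(miss))
    stop_drg("year(s) missing from share series: ", paste(miss, collapse = ", "),
             class = "domain_error")
  V <- t(vapply(periods, function(p) {
    vsv(shares[as.character(p[1]), ], shares[as.character(p[2]), ])
  }, numeric(ncol(shares))))
  dimnames(V) <- list(labels, colnames(shares))
  D <- apply(V, 1, dsv)
  C <- t(apply(V, 1, crsv))
  structure(list(vsv = V, dsv = D, crsv = C, periods = periods),
            class = "structural_change")
}

#' @export
print.structural_change <- function(x, ...) {
  cat("Structural variation of expense shares\n\nVSV (share change) and DSV (%):\n")
  print(cbind(round_half_up(x$vsv, 4), `DSV%` = round_half_up(x$dsv, 2)))
  cat("\nCRSV (% of total absolute change):\n")
  print(round_half_up(x$crsv, 2))
  invisible(x)
}

#' Format a structural-change result at report precision
#'
#' VSV to 4 decimals, DSV and CRSV to 2, rounding half up as expense tables
#' conventionally print. Internal arithmetic stays unrounded.
#'
#' @param x A `structural_change` object.
#' @return List of two data frames, `vsv_dsv` and `crsv`.
#' @export
structural_change_report <- function(x) {
  stopifnot(inherits(x, "structural_change"))
  list(vsv_dsv = data.frame(period = rownames(x$vsv),
                            round_half_up(x$vsv, 4),
                            dsv_percent = round_half_up(x$dsv, 2),
                            check.names = FALSE, row.names = NULL),
       crsv = data.frame(period = rownames(x$crsv), round_half_up(x$crsv, 2),
                         check.names = FALSE, row.names = NULL))
}
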