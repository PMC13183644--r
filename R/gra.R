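# Gray relational analysis of itemized expenses against per-admission totals.
#
# The variant implemented here applies Deng's relational coefficient directly
# to yuan-denominated series: because the reference (mean total expense per
# admission) and the comparisons (mean itemized expenses) share units, the
# usual dimensionless preprocessing step can be dropped. A classic mode with
# initial-value normalization is available for comparison.

#' Yearly per-admission means of total and itemized expenses
#'
#' The reference sequence is the yearly mean per-admission total expense;
#' the comparison sequences are the yearly means of the seven items, all in
#' (CPI-adjusted) yuan.
#'
#' @inheritParams annual_item_shares
#' @return List with `reference` (named vector by year) and `comparisons`
#'   (7 x N matrix, rows = [expense_items()], columns = years).
#' @export
yearly_means <- function(data, year_col = "discharge_year") {
  if (!year_col %in% names(data)) {
    if ("discharge_date" %in% names(data)) {
      data[[year_col]] <- as.integer(format(as.Date(data$discharge_date), "%Y"))
    } else stop_drg("no year column found", class = "domain_error")
  }
  suffix <- if (all(paste0(expense_items(), "_real") %in% names(data))) "_real" else ""
  item_cols <- paste0(expense_items(), suffix)
  total_col <- if (suffix == "_real") "total_real" else "total"
  years <- sort(unique(data[[year_col]]))
  if (!length(years)) stop_drg("no years present", class = "domain_error")
  comp <- vapply(years, function(y) {
    d <- data[data[[year_col]] == y, , drop = FALSE]
    colMeans(d[item_cols])
  }, numeric(7))
  ref <- vapply(years, function(y) mean(data[[total_col]][data[[year_col]] == y]),
                numeric(1))
  dimnames(comp) <- list(expense_items(), years)
  names(ref) <- years
  list(reference = ref, comparisons = comp)
}

#' Absolute difference sequences and their global extremes
#'
#' `delta[i, k] = |X_i(k) - X_0(k)|` for comparison series i at time k, with
#' the minimum and maximum taken globally over all series and times (the
#' standard Deng convention).
#'
#' @param reference Numeric reference series X0 (length N).
#' @param comparisons Matrix of comparison series (rows = series, N columns).
#' @return List with `delta`, `delta_min`, `delta_max`.
#' @export
difference_sequences <- function(reference, comparisons) {
  comparisons <- as.matrix(comparisons)
  if (ncol(comparisons) != length(reference))
    stop_drg("series lengths differ", class = "domain_error")
  delta <- abs(sweep(comparisons, 2, reference))
  list(delta = delta, delta_min = min(delta), delta_max = max(delta))
}

#' Gray relational coefficients (Deng)
#'
#' `xi[i, k] = (delta_min + rho * delta_max) / (delta[i, k] + rho * delta_max)`
#' with distinguishing coefficient `rho` (default 0.5). The cell attaining
#' the global minimum difference gets the maximal coefficient; when
#' `delta_min = 0` that maximum is exactly 1. If every comparison series is
#' identical to the reference (`delta_max = 0`), all coefficients are 1 and
#' the result is flagged degenerate.
#'
#' @param delta Difference matrix from [difference_sequences()].
#' @param delta_min,delta_max Global extremes of `delta`.
#' @param rho Distinguishing coefficient in (0, 1].
#' @return Matrix of coefficients in (0, 1], with attribute `degenerate`.
#' @export
relational_coefficients <- function(delta, delta_min = min(delta),
                                    delta_max = max(delta), rho = 0.5) {
  stopifnot(rho > 0, rho <= 1)
  if (delta_max == 0) {
    xi <- delta * 0 + 1
    attr(xi, "degenerate") <- TRUE
    return(xi)
  }
  xi <- (delta_min + rho * delta_max) / (delta + rho * delta_max)
  attr(xi, "degenerate") <- FALSE
  xi
}

#' Gray relational degrees and ranking
#'
#' The relational degree of each comparison series is the mean of its
#' coefficients over the N time points; rank 1 goes to the largest degree.
#' Ties keep the input item order and are flagged.
#'
#' @param xi Coefficient matrix (rows = series).
#' @return List with `gamma` (named vector), `ranks` (named integer vector,
#'   a permutation of 1..nrow) and `ties` (logical).
#' @export
relational_degrees <- function(xi) {
  if (!nrow(xi) || !ncol(xi)) stop_drg("empty coefficient matrix", class = "domain_error")
  gamma <- rowMeans(xi)
  ord <- order(-gamma)           # ties broken by item order
  ranks <- integer(length(gamma))
  ranks[ord] <- seq_along(gamma)
  names(ranks) <- names(gamma)
  list(gamma = gamma, ranks = ranks, ties = anyDuplicated(gamma) > 0)
}

#' Gray relational analysis of itemized expenses against the total
#'
#' Full analysis: difference sequences against the reference, Deng
#' coefficients with distinguishing coefficient `rho`, relational degrees
#' and ranking. With `normalize = "none"` (default) the series enter in
#' their shared yuan units; `normalize = "initial"` first divides each
#' series by its initial value (classic GRA preprocessing).
#'
#' @param reference Reference series (yearly mean per-admission totals), or
#'   the list returned by [yearly_means()].
#' @param comparisons Comparison matrix (ignored when `reference` is a
#'   [yearly_means()] list).
#' @param rho Distinguishing coefficient (default 0.5).
#' @param normalize `"none"` or `"initial"`.
#' @return Object of class `gray_relational` with `xi`, `gamma`, `ranks`,
#'   `delta`, `delta_min`, `delta_max`, `rho`, `normalize`, `degenerate`.
#' @export
gray_relational <- function(reference, comparisons = NULL, rho = 0.5,
                            normalize = c("none", "initial")) {
  normalize <- match.arg(normalize)
  if (is.list(reference) && !is.null(reference$comparisons)) {
    comparisons <- reference$comparisons
    reference <- reference$reference
  }
  comparisons <- as.matrix(comparisons)
  if (normalize == "initial") {
    if (reference[1] == 0 || any(comparisons[, 1] == 0))
      stop_drg("initial-value normalization undefined for zero initial values",
               class = "domain_error")
    reference <- reference / reference[1]
    comparisons <- comparisons / comparisons[, 1]
  }
  ds <- difference_sequences(reference, comparisons)
  xi <- relational_coefficients(ds$delta, ds$delta_min, ds$delta_max, rho)
  deg <- relational_degrees(xi)
  structure(list(xi = xi, gamma = deg$gamma, ranks = deg$ranks, ties = deg$ties,
                 delta = ds$delta, delta_min = ds$delta_min,
                 delta_max = ds$delta_max, rho = rho, normalize = normalize,
                 degenerate = isTRUE(attr(xi, "degenerate"))),
            class = "gray_relational")
}

#' @export
print.gray_relational <- function(x, ...) {
  cat("Gray relational analysis (rho =", x$rho,
      if (x$normalize == "none") ", direct yuan series" else ", initial-value normalized",
      ")\n")
  out <- data.frame(item = names(x$gamma),
                    gamma = round_half_up(x$gamma, 4), rank = x$ranks,
                    row.names = NULL)
  print(out[order(out$rank), ], row.names = FALSE)
  if (x$degenerate) cat("note: all series identical to reference\n")
  invisible(x)
}

#' Format a gray relational result at report precision
#'
#' Coefficients and degrees to 4 decimals, half-up.
#'
#' @param x A `gray_relational` object.
#' @return Data frame: item, per-year coefficients, `gamma`, `rank`.
#' @export
gra_report <- function(x) {
  stopifnot(inherits(x, "gray_relational"))
  data.frame(item = rownames(x$xi), round_half_up(x$xi, 4),
             gamma = round_half_up(x$gamma, 4), rank = x$ranks,
             check.names = FALSE, row.names = NULL)
}
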