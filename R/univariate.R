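# Group descriptives and rank-based univariate screening.

#' Per-group summary: n, percent, median, quartiles
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7), the common statistical-package default.
#'
#' @param values Numeric vector (typically real-yuan expenses).
#' @param by Grouping vector (factor or codes), same length as `values`.
#' @return Data frame with one row per observed level: `level`, `n`,
#'   `percent` (of total N), `median`, `p25`, `p75`.
#' @examples
#' group_summary(c(1, 2, 3, 4, 5), rep("a", 5))
#' @export
group_summary <- function(values, by) {
  if (length(values) == 0L) stop_drg("empty input", class = "domain_error")
  stopifnot(length(values) == length(by))
  by <- factor(by)
  out <- do.call(rbind, lapply(levels(by), function(lv) {
    v <- values[by == lv]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(level = lv, n = length(v), percent = 100 * length(v) / length(values),
               median = q[2], p25 = q[1], p75 = q[3])
  }))
  rownames(out) <- NULL
  out
}

# Midranks plus the tie-correction term sum(t^3 - t) over tie groups.
rank_with_ties <- function(x) {
  r <- rank(x)                       # midranks
  t <- table(x)
  list(ranks = r, tie_term = sum(t^3 - t))
}

#' Mann-Whitney U test (normal approximation, tie-corrected)
#'
#' Two-sided test of a location difference between two samples. U is built
#' from midrank sums; the variance carries the standard tie correction; no
#' continuity correction is applied (large-sample convention). Z is negative
#' when the first sample's rank sum falls below its null expectation.
#'
#' @param x,y Numeric samples.
#' @return List with `statistic` (Z), `U`, `p_value` (two-sided normal),
#'   and `degenerate` (`TRUE` when all observations are identical, in which
#'   case Z = 0 and p = 1).
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop_drg("empty sample", class = "domain_error")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  rt <- rank_with_ties(c(x, y))
  R1 <- sum(rt$ranks[seq_len(n1)])
  U <- R1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((N + 1) - rt$tie_term / (N * (N - 1)))
  if (sigma2 <= 0)   # every observation identical
    return(list(statistic = 0, U = U, p_value = 1, degenerate = TRUE))
  z <- (U - mu) / sqrt(sigma2)
  list(statistic = z, U = U, p_value = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

#' Kruskal-Wallis H test (tie-corrected)
#'
#' Rank test for a location difference among three or more groups, with the
#' chi-square approximation on k - 1 degrees of freedom. Delegates to
#' [stats::kruskal.test()], which applies midranks and the tie-correction
#' divisor.
#'
#' @param groups List of numeric samples (length >= 3).
#' @return List with `statistic` (H), `df`, `p_value`, `degenerate`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 3L) stop_drg("need >= 3 groups", class = "domain_error")
  if (any(!lengths(groups))) stop_drg("empty group", class = "domain_error")
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L)
    return(list(statistic = 0, df = length(groups) - 1L, p_value = 1,
                degenerate = TRUE))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, degenerate = FALSE)
}

#' Univariate screening of coded factors against an expense outcome
#'
#' For each factor, runs a Mann-Whitney U test (2 observed levels) or
#' Kruskal-Wallis H test (3 or more) of the outcome across factor levels and
#' selects factors with p below `alpha`. Group descriptives are reported on
#' the scale of `display` (default: the outcome itself); since the tests are
#' rank-based they are invariant to any monotone transform of the outcome,
#' so screening on raw or log yuan is equivalent.
#'
#' @param data Data frame holding the factors and the outcome.
#' @param factors Character vector of factor column names (default: the
#'   fourteen coded analysis variables present in `data`).
#' @param outcome Name of the outcome column.
#' @param alpha Significance level of the screen (default 0.05).
#' @param display Optional column name whose values feed the group
#'   descriptives (e.g. real yuan while testing the same ranks).
#' @return Object of class `univariate_screen`: a list of per-factor results
#'   (`variable`, `group_stats`, `statistic_kind` ("Z" or "H"), `statistic`,
#'   `df`, `p_value`, `significant`) plus `selected`, the names of factors
#'   with p < alpha. Factors with a single observed level are skipped with a
#'   warning.
#' @export
univariate_screen <- function(data, factors = NULL, outcome = "y1_log_total",
                              alpha = 0.05, display = NULL) {
  stopifnot(alpha > 0, alpha <= 1, outcome %in% names(data))
  factors <- factors %||% intersect(coded_factor_names(), names(data))
  y <- data[[outcome]]
  shown <- if (is.null(display)) y else data[[display]]

  results <- list()
  for (f in factors) {
    g <- factor(data[[f]])
    if (nlevels(g) < 2L) {
      warning("factor ", f, " has a single observed level; skipped")
      next
    }
    stats_tab <- group_summary(shown, g)
    if (nlevels(g) == 2L) {
      spl <- split(y, g)
      tst <- mann_whitney(spl[[1]], spl[[2]])
      res <- list(statistic_kind = "Z", statistic = tst$statistic, df = NA_integer_,
                  p_value = tst$p_value)
    } else {
      tst <- kruskal_wallis(split(y, g))
      res <- list(statistic_kind = "H", statistic = tst$statistic, df = tst$df,
                  p_value = tst$p_value)
    }
    results[[f]] <- c(list(variable = f, group_stats = stats_tab), res,
                      list(significant = res$p_value < alpha))
  }
  structure(list(results = results,
                 selected = names(results)[vapply(results, `[[`, TRUE, "significant")],
                 outcome = outcome, alpha = alpha),
            class = "univariate_screen")
}

#' @export
print.univariate_screen <- function(x, ...) {
  cat("Univariate screen of", x$outcome, "( alpha =", x$alpha, ")\n")
  for (r in x$results)
    cat(sprintf("  %-20s %s = %8.3f  p = %.4g%s\n", r$variable,
                r$statistic_kind, r$statistic, r$p_value,
                if (r$significant) "  *" else ""))
  cat("selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Flatten a univariate screen into a report table
#'
#' One row per factor level, in the layout of a published univariate table
#' (level, n, percent, median and quartiles, test statistic and p on the
#' factor's first row).
#'
#' @param x A `univariate_screen` object.
#' @return Data frame.
#' @export
screen_table <- function(x) {
  stopifnot(inherits(x, "univariate_screen"))
  do.call(rbind, lapply(x$results, function(r) {
    gs <- r$group_stats
    gs$variable <- r$variable
    gs$statistic_kind <- r$statistic_kind
    gs$statistic <- c(r$statistic, rep(NA, nrow(gs) - 1L))
    gs$p_value <- c(r$p_value, rep(NA, nrow(gs) - 1L))
    gs[, c("variable", "level", "n", "percent", "median", "p25", "p75",
           "statistic_kind", "statistic", "p_value")]
  }))
}
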