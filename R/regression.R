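# Dummy-coded multiple linear regression of log expenses.

#' Build a dummy-coded design matrix for screened factors
#'
#' Treatment (reference-level) coding: an intercept column plus one 0/1
#' column per non-reference level of each factor, labelled `factor=level`.
#' Default references are each factor's first code (pre-DRG phase, uninsured,
#' first visit, male, youngest age band, Han, single, emergency route,
#' shortest stay, fewest other diagnoses, no surgery, transfer discharge).
#'
#' @param data Data frame (typically the coded table from [code_records()]).
#' @param factors Character vector of factor columns to include, in order.
#' @param references Optional named list/vector giving the reference level
#'   per factor; defaults to the smallest observed code.
#' @return List with `X` (numeric matrix, first column `(Intercept)`),
#'   `labels`, and `factors`/`references` as used. Errors if a requested
#'   reference level is unobserved or the matrix is rank-deficient.
#' @export
build_design <- function(data, factors, references = NULL) {
  stopifnot(all(factors %in% names(data)))
  cols <- list(`(Intercept)` = rep(1, nrow(data)))
  refs <- list()
  for (f in factors) {
    g <- factor(data[[f]])
    if (nlevels(g) < 2L)
      stop_drg("factor ", f, " has fewer than 2 observed levels", class = "design_error")
    ref <- as.character(references[[f]] %||% levels(g)[1])
    if (!ref %in% levels(g))
      stop_drg("reference level ", ref, " unobserved for ", f, class = "design_error")
    refs[[f]] <- ref
    for (lv in setdiff(levels(g), ref))
      cols[[paste0(f, "=", lv)]] <- as.numeric(g == lv)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (qr(X)$rank < ncol(X)) {
    q <- qr(X)
    dropped <- colnames(X)[q$pivot[-seq_len(q$rank)]]
    stop_drg("design matrix is rank deficient; collinear column(s): ",
             paste(dropped, collapse = ", "), class = "collinearity_error")
  }
  list(X = X, labels = colnames(X), factors = factors, references = refs)
}

#' Fit ordinary least squares on a prebuilt design matrix
#'
#' Classical OLS: least-squares coefficients by QR, homoskedastic standard
#' errors, t tests, 95\% confidence intervals from the t distribution on the
#' residual degrees of freedom, overall F against the intercept-only model,
#' and adjusted R-squared.
#'
#' @param design A design list from [build_design()], or a numeric matrix
#'   whose first column is the intercept.
#' @param y Numeric response vector (log real yuan in this pipeline).
#' @param conf_level Confidence level for the intervals (default 0.95).
#' @return Object of class `expense_ols` with a per-term coefficient table
#'   (`coef`, `std_err`, `t`, `p`, `ci_low`, `ci_high`), `F_statistic`,
#'   `r_squared`, `adj_r_squared`, `sigma`, `n`, `df_residual`, `fitted`,
#'   `residuals`.
#' @seealso [fit_expense_model()] for the coded-table convenience wrapper.
#' @export
fit_ols <- function(design, y, conf_level = 0.95) {
  X <- if (is.list(design)) design$X else design
  stopifnot(is.numeric(y), nrow(X) == length(y))
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop_drg("design matrix is rank deficient", class = "collinearity_error")
  beta <- qr.coef(qx, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  n <- length(y); p <- ncol(X); df_res <- n - p
  rss <- sum(resid^2)
  sigma2 <- rss / df_res
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtX_inv) * sigma2)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df_res)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df_res)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / df_res
  Fstat <- if (p > 1) (tss - rss) / (p - 1) / sigma2 else NA_real_

  tab <- data.frame(term = colnames(X), coef = unname(beta), std_err = se,
                    t = tval, p = pval,
                    ci_low = beta - tcrit * se, ci_high = beta + tcrit * se,
                    row.names = NULL)
  structure(list(coefficients = stats::setNames(unname(beta), colnames(X)),
                 table = tab, F_statistic = Fstat,
                 df_model = p - 1L, df_residual = df_res, n = n,
                 r_squared = r2, adj_r_squared = adj_r2, sigma = sqrt(sigma2),
                 fitted = fitted, residuals = resid,
                 design_info = if (is.list(design)) design[c("factors", "references")],
                 conf_level = conf_level),
            class = "expense_ols")
}

#' Fit the expense model directly from a coded table
#'
#' Convenience wrapper: [build_design()] on the given (typically screened)
#' factors, then [fit_ols()] on the chosen log-expense outcome.
#'
#' @param data Coded table from [code_records()].
#' @param factors Factor columns to enter (e.g. the `selected` set of a
#'   [univariate_screen()]).
#' @param outcome Outcome column (default `"y1_log_total"`).
#' @param references Passed to [build_design()].
#' @param conf_level Passed to [fit_ols()].
#' @return An `expense_ols` fit.
#' @export
fit_expense_model <- function(data, factors, outcome = "y1_log_total",
                              references = NULL, conf_level = 0.95) {
  fit <- fit_ols(build_design(data, factors, references), data[[outcome]],
                 conf_level)
  fit$outcome <- outcome
  fit
}

#' @export
print.expense_ols <- function(x, digits = 3, ...) {
  cat("Dummy-coded OLS", if (!is.null(x$outcome)) paste("of", x$outcome), "\n")
  cat(sprintf("n = %d, F = %.2f on %d and %d df, adj R2 = %.4f\n",
              x$n, x$F_statistic, x$df_model, x$df_residual, x$adj_r_squared))
  print(format(x$table, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.expense_ols <- function(object, ...) object

#' @export
coef.expense_ols <- function(object, ...) object$coefficients

#' @export
residuals.expense_ols <- function(object, ...) object$residuals

#' @export
fitted.expense_ols <- function(object, ...) object$fitted

#' @export
confint.expense_ols <- function(object, parm, level = 0.95, ...) {
  ci <- cbind(object$table$ci_low, object$table$ci_high)
  rownames(ci) <- object$table$term
  colnames(ci) <- paste0(100 * c((1 - object$conf_level) / 2,
                                 1 - (1 - object$conf_level) / 2), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.expense_ols <- function(object, newdesign = NULL, ...) {
  if (is.null(newdesign)) return(object$fitted)
  X <- if (is.list(newdesign)) newdesign$X else newdesign
  drop(X %*% object$coefficients)
}
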