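# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' `round()` in R rounds half to even; published expense tables round half
#' up, so report formatting uses this convention.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_drg <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "drgcost_error")))
}

assert_prob_vector <- function(p, name, tol = 1e-8) {
  if (any(!is.finite(p)) || any(p < -tol) || abs(sum(p) - 1) > 1e-6)
    stop_drg(name, " must be non-negative and sum to 1", class = "config_error")
  invisible(p / sum(p))
}

is_count <- function(x) length(x) == 1L && is.finite(x) && x == floor(x)
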