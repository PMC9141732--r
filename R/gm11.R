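# GM(1,1) grey forecasting: least squares on the whitened equation of the
# once-accumulated series, then the exact solution of the grey difference
# equation, de-accumulated.

#' Fit a GM(1,1) grey model
#'
#' First-order single-variable grey model: accumulate the series (1-AGO),
#' regress the original values on the consecutive means of the accumulated
#' series (`x0(k) = -a z(k) + b`, `z(k)` the even mean of `x1`) to estimate
#' the development coefficient `a` and grey input `b`. Forecasts use the
#' exact solution of that difference equation, whose accumulated series grows
#' by the ratio `sigma = (1 - a/2)/(1 + a/2)` (the small-`a` limit of
#' `exp(-a)`); this keeps the response consistent with the estimating
#' equation, so purely geometric and constant series are reproduced without
#' discretization bias. The fitted value at index 1 equals the first
#' observation by construction.
#'
#' @param x positive numeric series, length >= 4.
#' @return a `gm11` object: list with `a`, `b`, `x0` (input), `fitted`.
#' @export
gm11_fit <- function(x) {
  if (length(x) < 4) stop("GM(1,1) needs at least 4 observations")
  if (any(!is.finite(x)) || any(x <= 0)) stop("GM(1,1) needs positive values")
  x1 <- cumsum(x)
  n <- length(x)
  z <- (x1[-n] + x1[-1]) / 2
  B <- cbind(-z, 1)
  ab <- solve(crossprod(B), crossprod(B, x[-1]))
  a <- ab[1]; b <- ab[2]
  if (abs(1 + a / 2) < 1e-12) stop("degenerate development coefficient (a = -2)")
  model <- structure(list(a = a, b = b, x0 = x, n = n), class = "gm11")
  model$fitted <- gm11_forecast(model, horizon = 0, include_fit = TRUE)
  model
}

#' Forecast from a GM(1,1) model
#'
#' @param model a `gm11` object.
#' @param horizon number of steps beyond the fitted series (>= 1 for a
#'   forecast; 0 with `include_fit = TRUE` returns the in-sample fit).
#' @param include_fit prepend the n in-sample fitted values.
#' @return numeric vector of de-accumulated values.
#' @export
gm11_forecast <- function(model, horizon = 1, include_fit = FALSE) {
  if (horizon < 0) stop("horizon must be >= 0")
  a <- model$a; b <- model$b; x0 <- model$x0; n <- model$n
  idx <- seq_len(n + horizon)
  if (abs(a) < 1e-12) {
    # flat model: accumulated series grows linearly by b
    x1hat <- x0[1] + b * (idx - 1)
  } else {
    sigma <- (1 - a / 2) / (1 + a / 2)
    x1hat <- (x0[1] - b / a) * sigma^(idx - 1) + b / a
  }
  x0hat <- c(x0[1], diff(x1hat))
  if (include_fit) x0hat[seq_len(n + horizon)] else x0hat[n + seq_len(horizon)]
}

#' @export
print.gm11 <- function(x, ...) {
  cat(sprintf("GM(1,1): a = %.6g, b = %.6g, n = %d\n", x$a, x$b, x$n))
  invisible(x)
}
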