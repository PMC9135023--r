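## Small numerical helpers shared across modules.

## Trapezoidal quadrature of y(x) on a (possibly non-uniform) grid.
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

## Trapezoidal weights w such that sum(w * y) == .trapz(x, y).
.trapz_weights <- function(x) {
  n <- length(x)
  dx <- diff(x)
  w <- numeric(n)
  w[-n] <- w[-n] + dx / 2
  w[-1L] <- w[-1L] + dx / 2
  w
}

.pos <- function(x) pmax(x, 0)

## Positive-part integral of a rate series on grid x.
.pos_work <- function(x, rate) .trapz(x, .pos(rate))

## Cumulative trapezoid (same length as x, starting at 0).
.cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-1L] + y[-n]) / 2))
}

## Linear interpolation of each column of a matrix onto a new grid.
.interp_cols <- function(t_old, M, t_new) {
  apply(M, 2L, function(col) stats::approx(t_old, col, xout = t_new, rule = 2)$y)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
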