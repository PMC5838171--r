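# Discounted cash-flow economics: net present value and equivalent annual
# annuity of per-site profit streams.

#' Net present value of a profit stream
#'
#' Discounts a stream of annual profits at rate `delta` and sums:
#' `NPV = sum_t pi_t / (1 + delta)^t`. By default the stream covers years
#' `t = 0..T` inclusive (`T + 1` cash flows for a `T`-year horizon, the first
#' undiscounted); set `include_t0 = FALSE` for the `t = 1..T` convention.
#'
#' @param profits Numeric vector of annual profits, in order of year.
#' @param delta Discount rate as a fraction per year (default 0.05).
#' @param include_t0 If `TRUE` (default) the first element is the year-0 cash
#'   flow and is undiscounted; if `FALSE` discounting starts at year 1.
#' @return The net present value, a single number in the units of `profits`.
#' @export
#' @examples
#' npv(rep(100, 11))              # 11 cash flows, t = 0..10, delta = 5%
#' npv(rep(100, 11), delta = 0)   # undiscounted: 1100
npv <- function(profits, delta = 0.05, include_t0 = TRUE) {
  if (!is.numeric(profits) || length(profits) < 1 || anyNA(profits)) {
    abort("`profits` must be a non-empty numeric vector with no missing values")
  }
  if (delta < 0) abort("discount rate `delta` must be non-negative")
  t <- seq_along(profits) - if (include_t0) 1L else 0L
  sum(profits / (1 + delta)^t)
}

#' Equivalent annual annuity of a net present value
#'
#' The level yearly payment over a `horizon`-year period with the same present
#' value: `annuity = delta * NPV / (1 - (1 + delta)^-T)`. As `delta -> 0` this
#' tends to `NPV / T`, which is returned exactly at `delta = 0`.
#'
#' @param npv_value Net present value (any currency unit).
#' @param delta Discount rate, fraction per year (default 0.05).
#' @param horizon Horizon `T` in years, a positive integer (default 10).
#' @return The annuity, in units of `npv_value` per year.
#' @export
#' @examples
#' annuity(1000)                    # delta = 5%, T = 10
#' annuity(1000, delta = 0)         # limit NPV / T = 100
annuity <- function(npv_value, delta = 0.05, horizon = 10) {
  if (horizon <= 0 || horizon != round(horizon)) {
    abort("`horizon` must be a positive integer number of years")
  }
  if (delta < 0) abort("discount rate `delta` must be non-negative")
  if (delta == 0) return(npv_value / horizon)
  # -expm1(-T log1p(delta)) = 1 - (1+delta)^-T, stable for tiny delta
  delta * npv_value / (-expm1(-horizon * log1p(delta)))
}

#' Annuity of a profit stream
#'
#' Convenience composition of [npv()] and [annuity()]: the equivalent annual
#' annuity of the discounted profit stream. Negative annuities mark a
#' (site, option) pair economically undevelopable downstream.
#'
#' @inheritParams npv
#' @param horizon Amortization horizon in years; defaults to the stream's own
#'   `T` (its length minus one when `include_t0` is `TRUE`, else its length).
#' @return The equivalent annual annuity.
#' @export
profit_annuity <- function(profits, delta = 0.05, include_t0 = TRUE,
                           horizon = NULL) {
  horizon <- horizon %||%
    (length(profits) - if (include_t0) 1L else 0L)
  annuity(npv(profits, delta, include_t0), delta, horizon)
}
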