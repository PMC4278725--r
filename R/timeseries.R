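#' Sampled concentration/signal curve
#'
#' The universal currency of the pipeline: a (time, value) curve with a unit
#' tag. Time is in seconds and must be strictly increasing; sampling may be
#' uniform (0.2 s pre-bolus grid, 3.2 s main-bolus grid) or not.
#'
#' @param t numeric vector of sample times in seconds, strictly increasing.
#' @param y numeric vector of values, same length as `t`.
#' @param units unit label, `"a.u."` for raw signal intensity or `"mmol/L"`
#'   for gadolinium concentration.
#' @return An object of class `"dce_ts"`: a list with elements `t`, `y`,
#'   `units`.
#' @examples
#' ts <- time_series(seq(0, 10, 0.5), sin(seq(0, 10, 0.5)), "a.u.")
#' ts
#' @export
time_series <- function(t, y, units = c("a.u.", "mmol/L")) {
  units <- match.arg(units)
  if (!is.numeric(t) || !is.numeric(y))
    stop("'t' and 'y' must be numeric")
  if (length(t) != length(y))
    stop("'t' and 'y' must have the same length (got ", length(t),
         " and ", length(y), ")")
  if (length(t) < 2L)
    stop("a time series needs at least 2 samples")
  if (anyNA(t) || any(!is.finite(t)))
    stop("non-finite values in 't'")
  if (any(diff(t) <= 0))
    stop("'t' must be strictly increasing")
  structure(list(t = as.numeric(t), y = as.numeric(y), units = units),
            class = "dce_ts")
}

#' @export
print.dce_ts <- function(x, ...) {
  dt <- diff(x$t)
  grid <- if (max(dt) - min(dt) < 1e-9 * max(dt)) {
    sprintf("uniform %.4g s grid", dt[1])
  } else "non-uniform grid"
  cat(sprintf("<dce_ts> %d samples, t in [%g, %g] s (%s), values in %s\n",
              length(x$t), x$t[1], x$t[length(x$t)], grid, x$units))
  invisible(x)
}

#' @export
length.dce_ts <- function(x) length(x$t)

is_dce_ts <- function(x) inherits(x, "dce_ts")

#' Test whether a series is uniformly sampled
#'
#' @param series a [time_series()] object.
#' @param tol relative tolerance on the step variation.
#' @return `TRUE` if all steps agree to within `tol` relative.
#' @export
is_uniform <- function(series, tol = 1e-6) {
  stopifnot(is_dce_ts(series))
  dt <- diff(series$t)
  (max(dt) - min(dt)) <= tol * max(dt)
}

#' Resample a curve onto a new time grid by linear interpolation
#'
#' Values at original sample points are preserved exactly. Target times
#' outside the sampled range are an error unless `extrapolate_zero = TRUE`,
#' in which case times before the first sample evaluate to zero (the
#' pre-arrival convention for concentration curves).
#'
#' @param series a [time_series()] object.
#' @param new_times numeric vector of target times in seconds.
#' @param extrapolate_zero allow times before `min(t)` and return 0 there.
#' @return A [time_series()] on `new_times` with the same units.
#' @export
resample <- function(series, new_times, extrapolate_zero = FALSE) {
  stopifnot(is_dce_ts(series))
  if (length(new_times) == 0L)
    stop("empty target grid")
  if (anyNA(new_times) || any(!is.finite(new_times)))
    stop("non-finite values in 'new_times'")
  lo <- series$t[1]; hi <- series$t[length(series$t)]
  if (any(new_times > hi))
    stop("target times beyond the end of the series (max ", hi, " s)")
  if (any(new_times < lo) && !extrapolate_zero)
    stop("target times before the start of the series (min ", lo,
         " s); set extrapolate_zero = TRUE to treat pre-bolus times as 0")
  y <- interp_zero(series$t, series$y, new_times)
  time_series(new_times, y, series$units)
}

# Linear interpolation with C(t) = 0 before the first sample and constant
# extension past the last; internal workhorse shared by the reconstruction
# and kinetic modules (shifted-input evaluation).
interp_zero <- function(t, y, xout) {
  out <- stats::approx(t, y, xout = pmin(pmax(xout, t[1]), t[length(t)]),
                       method = "linear", rule = 2)$y
  out[xout < t[1]] <- 0
  out
}

# Trapezoidal integral of the full series.
ts_integral <- function(series) {
  pracma::trapz(series$t, series$y)
}

check_finite_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number")
  if (positive && x <= 0)
    stop("'", name, "' must be > 0")
  invisible(x)
}
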