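#' MR acquisition parameters
#'
#' Parameters of the two dynamic sequences used in the protocol: a 3D spoiled
#' gradient echo (SPGR/FLASH) for the main-bolus series and a
#' saturation-recovery 2D-TurboFLASH for the high-temporal-resolution
#' pre-bolus series.
#'
#' @param sequence_kind `"spgr"` or `"sat_recovery"`.
#' @param TR repetition time in seconds.
#' @param TE echo time in seconds (carried for reference; the T2*/TE decay
#'   factor is treated as constant and cancels in the baseline-normalised
#'   inversion).
#' @param flip_angle flip angle in degrees, in (0, 90].
#' @param TS saturation-recovery time in seconds (required for
#'   `"sat_recovery"`).
#' @return An object of class `"acquisition_params"`.
#' @examples
#' acq_main <- acquisition_params("spgr", TR = 0.00296, TE = 0.00095,
#'                                flip_angle = 12)
#' acq_pre  <- acquisition_params("sat_recovery", TR = 0.0023, TE = 0.00091,
#'                                flip_angle = 12, TS = 0.12)
#' @export
acquisition_params <- function(sequence_kind = c("spgr", "sat_recovery"),
                               TR, TE = NA_real_, flip_angle, TS = NA_real_) {
  sequence_kind <- match.arg(sequence_kind)
  check_finite_scalar(TR, "TR", positive = TRUE)
  check_finite_scalar(flip_angle, "flip_angle")
  if (flip_angle <= 0 || flip_angle > 90)
    stop("'flip_angle' must be in (0, 90] degrees")
  if (sequence_kind == "sat_recovery") {
    check_finite_scalar(TS, "TS", positive = TRUE)
  }
  structure(list(sequence_kind = sequence_kind, TR = TR, TE = TE,
                 flip_angle = flip_angle, TS = TS),
            class = "acquisition_params")
}

#' Relaxation parameters of tissue/blood and contrast agent
#'
#' @param T10 pre-contrast longitudinal relaxation time in seconds
#'   (1.2 s for blood at 1.5 T by default).
#' @param r1 longitudinal relaxivity of the contrast agent in L/(mmol s);
#'   default 6.3, the 1.5 T plasma value commonly used for gadobenate
#'   dimeglumine; configurable because reported values span roughly 3-8
#'   depending on medium and field.
#' @return An object of class `"relaxation_params"`.
#' @export
relaxation_params <- function(T10 = 1.2, r1 = 6.3) {
  check_finite_scalar(T10, "T10", positive = TRUE)
  check_finite_scalar(r1, "r1", positive = TRUE)
  structure(list(T10 = T10, r1 = r1), class = "relaxation_params")
}

# T1 shortening by gadolinium: 1/T1 = 1/T10 + r1 * conc.
t1_of_conc <- function(conc, relax) {
  1 / (1 / relax$T10 + relax$r1 * conc)
}

#' Forward SPGR (FLASH) steady-state signal
#'
#' S = M0 sin(a) (1 - E1) / (1 - E1 cos(a)) with E1 = exp(-TR/T1) and
#' 1/T1 = 1/T10 + r1 c. Monotone non-decreasing in concentration; its slope
#' shrinks as E1 -> 0, which is the saturation mechanism that clips the
#' main-bolus first-pass peak.
#'
#' @param conc gadolinium concentration(s), mmol/L, >= 0.
#' @param M0 equilibrium signal scale, arbitrary units.
#' @param acq an [acquisition_params()] with `sequence_kind = "spgr"`.
#' @param relax a [relaxation_params()].
#' @return Signal intensity, same length as `conc`.
#' @export
spgr_signal <- function(conc, M0, acq, relax) {
  check_signal_inputs(conc, M0, acq, relax, kind = "spgr")
  a <- acq$flip_angle * pi / 180
  E1 <- exp(-acq$TR / t1_of_conc(conc, relax))
  M0 * sin(a) * (1 - E1) / (1 - E1 * cos(a))
}

#' Forward saturation-recovery TurboFLASH signal
#'
#' S = M0 (1 - exp(-TS/T1)): the longitudinal magnetisation recovered during
#' the saturation delay TS, read out at the centre of k-space. The readout
#' train is modelled as ideal (no imaging-pulse correction), a stated
#' modelling simplification.
#'
#' @inheritParams spgr_signal
#' @param acq an [acquisition_params()] with `sequence_kind = "sat_recovery"`.
#' @return Signal intensity in `[0, M0]`, same length as `conc`.
#' @export
sat_recovery_signal <- function(conc, M0, acq, relax) {
  check_signal_inputs(conc, M0, acq, relax, kind = "sat_recovery")
  M0 * (1 - exp(-acq$TS / t1_of_conc(conc, relax)))
}

check_signal_inputs <- function(conc, M0, acq, relax, kind) {
  if (!inherits(acq, "acquisition_params")) stop("'acq' must be acquisition_params")
  if (!inherits(relax, "relaxation_params")) stop("'relax' must be relaxation_params")
  if (acq$sequence_kind != kind)
    stop("'acq' has sequence_kind '", acq$sequence_kind,
         "', expected '", kind, "'")
  if (anyNA(conc) || any(!is.finite(conc)))
    stop("non-finite values in 'conc'")
  if (any(conc < 0))
    stop("'conc' must be >= 0")
  check_finite_scalar(M0, "M0")
  invisible(TRUE)
}

forward_signal <- function(conc, M0, acq, relax) {
  switch(acq$sequence_kind,
         spgr = spgr_signal(conc, M0, acq, relax),
         sat_recovery = sat_recovery_signal(conc, M0, acq, relax))
}

#' Invert a signal-intensity curve to gadolinium concentration
#'
#' Calibrates the signal scale M0 from the mean of the first `n_baseline`
#' pre-contrast samples and the forward model at zero concentration, then
#' inverts every sample to the unique non-negative concentration reproducing
#' its signal by bracketed monotone root finding on `[0, conc_max]`. One code
#' path serves both sequence kinds.
#'
#' Samples whose signal falls below the zero-concentration baseline (noise)
#' would invert to negative concentration: they are clamped to 0 and counted
#' in `n_clamped`. Samples above the asymptotic maximum of the forward model
#' (saturation) are set to `conc_max` and counted in `n_saturated`.
#'
#' @param series a [time_series()] of signal intensity (`"a.u."`).
#' @param n_baseline number of pre-contrast samples used for M0 calibration
#'   (>= 1; 3 matches the main-bolus protocol's pre-contrast acquisitions).
#' @param acq an [acquisition_params()].
#' @param relax a [relaxation_params()].
#' @param conc_max upper bracket of the inversion, mmol/L.
#' @return A list of class `"dce_conversion"`: `series` (concentration
#'   [time_series()], mmol/L), `M0`, `n_clamped`, `n_saturated`.
#' @examples
#' acq <- acquisition_params("spgr", TR = 0.00296, flip_angle = 12)
#' rel <- relaxation_params(T10 = 1.2, r1 = 6.3)
#' tt <- seq(0, 10, 0.5)
#' conc <- c(rep(0, 6), 2 * exp(-((tt[-(1:6)] - 5) / 2)^2))
#' si <- time_series(tt, spgr_signal(conc, 1000, acq, rel), "a.u.")
#' conv <- signal_to_concentration(si, n_baseline = 3, acq, rel)
#' max(abs(conv$series$y - conc))
#' @export
signal_to_concentration <- function(series, n_baseline, acq, relax,
                                    conc_max = 50) {
  stopifnot(is_dce_ts(series))
  if (!is.numeric(n_baseline) || n_baseline < 1 ||
      n_baseline > length(series$t))
    stop("'n_baseline' must be in [1, number of samples]")
  n_baseline <- as.integer(n_baseline)
  if (anyNA(series$y) || any(!is.finite(series$y)))
    stop("non-finite values in signal 'y'")
  base_mean <- mean(series$y[seq_len(n_baseline)])
  if (base_mean <= 0)
    stop("baseline mean must be > 0 (got ", format(base_mean), ")")
  s0_unit <- forward_signal(0, 1, acq, relax)
  M0 <- base_mean / s0_unit
  s_zero <- forward_signal(0, M0, acq, relax)
  s_max <- forward_signal(conc_max, M0, acq, relax)

  conc <- numeric(length(series$y))
  n_clamped <- 0L
  n_saturated <- 0L
  for (i in seq_along(series$y)) {
    s <- series$y[i]
    if (s <= s_zero) {
      conc[i] <- 0
      if (s < s_zero) n_clamped <- n_clamped + 1L
    } else if (s >= s_max) {
      conc[i] <- conc_max
      n_saturated <- n_saturated + 1L
      warning("sample ", i, " at t = ", series$t[i],
              " s exceeds the forward-model maximum; concentration set to ",
              conc_max, " mmol/L (saturation)", call. = FALSE)
    } else {
      root <- stats::uniroot(
        function(cc) forward_signal(cc, M0, acq, relax) - s,
        lower = 0, upper = conc_max, tol = 1e-12,
        f.lower = s_zero - s, f.upper = s_max - s)$root
      # Newton polish: the forward model is smooth and strictly monotone,
      # two steps take the signal residual to machine precision
      for (it in 1:2) {
        h <- 1e-6 * (1 + root)
        der <- (forward_signal(root + h, M0, acq, relax) -
                  forward_signal(max(0, root - h), M0, acq, relax)) /
          (root + h - max(0, root - h))
        root <- root - (forward_signal(root, M0, acq, relax) - s) / der
        root <- min(max(root, 0), conc_max)
      }
      conc[i] <- root
    }
  }
  structure(list(series = time_series(series$t, conc, "mmol/L"),
                 M0 = M0, n_clamped = n_clamped, n_saturated = n_saturated),
            class = "dce_conversion")
}

#' @export
print.dce_conversion <- function(x, ...) {
  cat(sprintf(
    "<dce_conversion> M0 = %.4g; %d clamped to 0; %d saturated\n",
    x$M0, x$n_clamped, x$n_saturated))
  print(x$series)
  invisible(x)
}

#' Convert whole-blood to plasma concentration
#'
#' Gadolinium distributes in plasma only, so the blood concentration measured
#' in a vessel ROI is divided by (1 - hematocrit).
#'
#' @param series a concentration [time_series()] (mmol/L).
#' @param hematocrit red-cell volume fraction in `[0, 1)`.
#' @return A [time_series()] of plasma concentration.
#' @export
blood_to_plasma <- function(series, hematocrit) {
  stopifnot(is_dce_ts(series))
  check_finite_scalar(hematocrit, "hematocrit")
  if (hematocrit < 0 || hematocrit >= 1)
    stop("'hematocrit' must be in [0, 1)")
  time_series(series$t, series$y / (1 - hematocrit), series$units)
}
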