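#' Ground-truth description of a synthetic subject
#'
#' Defines everything needed to forward-simulate one subject's two-protocol
#' DCE-MRI examination: liver kinetics, the aortic bolus morphology (gamma-
#' variate first pass plus a dispersed recirculation bump), the splanchnic
#' delay/dispersion producing the portal-vein input, physiology scalars, and
#' the acquisition imperfections (signal noise, pre-bolus inflow
#' oscillations).
#'
#' Defaults emulate a typical liver-disease subject: portal-dominant flow
#' (k1p 0.07 /s, k1a 0.009 /s, k2 0.053 /s, i.e. Fp ~ 420, Fa ~ 54
#' mL/min/100 mL, MTT ~ 19 s), an aortic first pass peaking ~ 8 mmol/L in
#' plasma at the full dose with ~ 9 s FWHM, hematocrit 0.42, blood T10
#' 1.2 s, liver T10 0.586 s, 2% signal noise and 5% inflow modulation at a
#' 1 s cardiac period.
#'
#' @param kinetic a [kinetic_params()].
#' @param aif_amplitude first-pass impulse amplitude, mmol/L of whole blood
#'   per mL of injected agent.
#' @param aif_arrival bolus arrival time after acquisition start, s.
#' @param aif_shape,aif_scale gamma-variate shape (dimensionless) and time
#'   scale (s); the first-pass peak sits at arrival + shape * scale.
#' @param recirc_fraction recirculation amplitude as a fraction of the
#'   first-pass impulse (must be < 0.4 so the first pass dominates).
#' @param recirc_delay,recirc_dispersion recirculation delay and exponential
#'   dispersion time constant, s.
#' @param portal_delay,portal_dispersion splanchnic transit delay and
#'   exponential dispersion time constant of the portal input, s.
#' @param hematocrit red-cell fraction, in (0, 0.6).
#' @param T10_blood,T10_liver pre-contrast T1 of blood and liver, s.
#' @param r1 contrast relaxivity, L/(mmol s).
#' @param noise_sd Gaussian signal noise as a fraction of the baseline
#'   signal.
#' @param inflow_amplitude,inflow_period pre-bolus inflow oscillation:
#'   multiplicative amplitude fraction and period, s.
#' @param seed integer seed for the subject's noise stream.
#' @return An object of class `"subject_truth"`.
#' @export
subject_truth <- function(kinetic = kinetic_params(0.009, 0.07, 0.053,
                                                   tau_a = 2, tau_p = 4),
                          aif_amplitude = 0.67, aif_arrival = 8,
                          aif_shape = 3.5, aif_scale = 2.0,
                          recirc_fraction = 0.25, recirc_delay = 14,
                          recirc_dispersion = 8,
                          portal_delay = 5, portal_dispersion = 10,
                          hematocrit = 0.42,
                          T10_blood = 1.2, T10_liver = 0.586, r1 = 6.3,
                          noise_sd = 0.02,
                          inflow_amplitude = 0.05, inflow_period = 1.0,
                          seed = 1L) {
  stopifnot(inherits(kinetic, "kinetic_params"))
  for (nm in c("aif_amplitude", "aif_arrival", "aif_shape", "aif_scale",
               "recirc_fraction", "recirc_delay", "recirc_dispersion",
               "portal_delay", "portal_dispersion", "hematocrit",
               "T10_blood", "T10_liver", "r1", "noise_sd",
               "inflow_amplitude", "inflow_period"))
    check_finite_scalar(get(nm), nm)
  if (aif_amplitude < 0 || aif_shape <= 0 || aif_scale <= 0)
    stop("non-physical gamma-variate parameters")
  if (recirc_fraction < 0 || recirc_fraction >= 0.4)
    stop("'recirc_fraction' must be in [0, 0.4): the first pass must dominate")
  if (hematocrit <= 0 || hematocrit >= 0.6)
    stop("'hematocrit' must be in (0, 0.6)")
  if (noise_sd < 0 || inflow_amplitude < 0)
    stop("'noise_sd' and 'inflow_amplitude' must be >= 0")
  structure(list(kinetic = kinetic,
                 aif = list(amplitude = aif_amplitude, arrival = aif_arrival,
                            shape = aif_shape, scale = aif_scale,
                            recirc_fraction = recirc_fraction,
                            recirc_delay = recirc_delay,
                            recirc_dispersion = recirc_dispersion),
                 portal = list(delay = portal_delay,
                               dispersion = portal_dispersion),
                 hematocrit = hematocrit, T10_blood = T10_blood,
                 T10_liver = T10_liver, r1 = r1, noise_sd = noise_sd,
                 inflow = list(amplitude = inflow_amplitude,
                               period = inflow_period),
                 seed = as.integer(seed)),
            class = "subject_truth")
}

# causal discrete convolution on a uniform grid, dt-weighted; FFT-based
conv_causal <- function(y, kern, dt) {
  stats::convolve(y, rev(kern), type = "open")[seq_along(y)] * dt
}

# normalised exponential dispersion kernel exp(-t/tau)/tau on the grid step
# dt; weights renormalised so the discrete kernel has unit time-integral
# (mass conservation).
exp_dispersion_kernel <- function(tau, dt, t_max) {
  tk <- seq(0, min(14 * tau, t_max), by = dt)
  k <- exp(-tk / tau)
  k / (sum(k) * dt)
}

#' Aortic impulse response: gamma-variate first pass plus recirculation
#'
#' Evaluates the whole-blood aortic concentration response per mL of
#' injected contrast: a gamma-variate first pass
#' `A ((t - t0)/(a s))^a exp(a - (t - t0)/s)` (peak `A` at `t0 + a s`)
#' plus, when `recirc_fraction > 0`, a recirculation bump built by
#' dispersing the first pass with a normalised exponential kernel and
#' delaying it.
#'
#' @param t_grid uniform time grid, s.
#' @param aif the `aif` list of a [subject_truth()].
#' @return A [time_series()] (mmol/L per mL injected).
#' @export
impulse_aif <- function(t_grid, aif) {
  stopifnot(is.numeric(t_grid), length(t_grid) >= 2L)
  if (aif$amplitude < 0 || aif$shape <= 0 || aif$scale <= 0 ||
      aif$recirc_fraction < 0 || aif$recirc_fraction >= 0.4 ||
      aif$recirc_delay < 0 || aif$recirc_dispersion <= 0)
    stop("non-physical impulse-response parameters")
  dt <- t_grid[2] - t_grid[1]
  x <- t_grid - aif$arrival
  g <- ifelse(x > 0,
              aif$amplitude * (x / (aif$shape * aif$scale))^aif$shape *
                exp(aif$shape - x / aif$scale),
              0)
  if (aif$recirc_fraction > 0) {
    kern <- exp_dispersion_kernel(aif$recirc_dispersion, dt,
                                  max(t_grid) - min(t_grid))
    disp <- pmax(0, conv_causal(g, kern, dt))
    recirc <- aif$recirc_fraction *
      interp_zero(t_grid, disp, t_grid - aif$recirc_delay)
    g <- g + recirc
  }
  time_series(t_grid, g, "mmol/L")
}

#' Build the true arterial and portal whole-blood input curves
#'
#' Convolves the subject's aortic impulse response with the rectangular
#' injection profile of the chosen bolus (height = injection rate in mL/s,
#' width = injection duration), then derives the portal-vein curve by
#' dispersing the aortic curve with a normalised exponential kernel
#' (splanchnic transit) and delaying it. With the dispersion time constant
#' below the grid step the kernel degenerates to a delta and the portal
#' curve is a pure delayed copy.
#'
#' @param truth a [subject_truth()].
#' @param protocol an [injection_protocol()].
#' @param bolus `"main"` or `"pre"`: which injection to simulate.
#' @param t_max end of the master grid, s.
#' @param dt master grid step, s (default 0.05).
#' @return List with [time_series()] elements `aorta` and `portal`
#'   (whole-blood mmol/L) on the master grid.
#' @export
make_inputs <- function(truth, protocol, bolus = c("main", "pre"),
                        t_max = 212, dt = 0.05) {
  stopifnot(inherits(truth, "subject_truth"),
            inherits(protocol, "injection_protocol"))
  bolus <- match.arg(bolus)
  t <- seq(0, t_max, by = dt)
  h <- impulse_aif(t, truth$aif)
  rate <- if (bolus == "main") protocol$main_rate else protocol$pre_rate
  dur <- if (bolus == "main") protocol$T_m else protocol$T_p
  rect <- rep(rate, max(1L, round(dur / dt)))
  # correct for rounding of the injection duration so the delivered volume
  # is exact
  rect <- rect * (dur / (length(rect) * dt))
  aorta <- pmax(0, conv_causal(h$y, rect, dt))

  if (truth$portal$dispersion < dt / 2) {
    pv <- interp_zero(t, aorta, t - truth$portal$delay)
  } else {
    kern <- exp_dispersion_kernel(truth$portal$dispersion, dt, t_max)
    pv <- pmax(0, conv_causal(aorta, kern, dt))
    pv <- interp_zero(t, pv, t - truth$portal$delay)
  }
  list(aorta = time_series(t, aorta, "mmol/L"),
       portal = time_series(t, pv, "mmol/L"))
}

# boxcar-average y (on uniform grid t, step dt) over a window of 'width'
# seconds centred at each element of 'centres'; emulates the signal mixing
# of a 3D acquisition whose k-space is filled over the frame duration
frame_average <- function(t, y, centres, width) {
  vapply(centres, function(tc) {
    w <- t >= tc - width / 2 & t <= tc + width / 2
    mean(y[w])
  }, numeric(1))
}

#' Acquisition parameter defaults of the two dynamic sequences
#'
#' The saturation-recovery 2D-TurboFLASH pre-bolus sequence (TR 2.3 ms,
#' TE 0.91 ms, flip 12 deg, recovery time 120 ms, 0.2 s frames over 60 s)
#' and the 3D-FLASH main-bolus sequence (TR 2.96 ms, TE 0.95 ms, flip
#' 12 deg, 3.2 s frames, 3 pre-contrast + 64 volumes).
#'
#' @return List with elements `pre` and `main` ([acquisition_params()]).
#' @export
acquisition_defaults <- function() {
  list(pre = acquisition_params("sat_recovery", TR = 0.0023, TE = 0.00091,
                                flip_angle = 12, TS = 0.12),
       main = acquisition_params("spgr", TR = 0.00296, TE = 0.00095,
                                 flip_angle = 12))
}

#' Simulate one subject's complete two-protocol examination
#'
#' Builds the true input and liver curves from the ground truth, then
#' renders the four signal-intensity series the pipeline consumes:
#'
#' * `prebolus_si`: aorta during the pre-bolus, saturation-recovery model,
#'   0.2 s grid over 60 s, multiplied by the inflow oscillation
#'   `1 + A sin(2 pi t / period)` and corrupted by Gaussian noise.
#' * `mainbolus_aorta_si`, `portal_si`, `liver_si`: SPGR model on the 3.2 s
#'   main-bolus grid (3 pre-contrast + 64 volumes). The aortic frames are
#'   boxcar averages of the continuous signal over the frame duration
#'   (k-space filling time), which, combined with SPGR saturation, is what
#'   clips the main-bolus first-pass peak. The portal and liver curves vary
#'   slowly on the frame scale, so they are sampled instantaneously — a
#'   stated simplification that keeps the tissue forward model consistent
#'   with the kinetic model's instantaneous sampling.
#'
#' The liver curve comes from [simulate_liver()] driven by the true plasma
#' inputs and the subject's kinetic parameters. Noise is reproducible: the
#' subject's seed fully determines the output.
#'
#' @param truth a [subject_truth()].
#' @param protocol an [injection_protocol()].
#' @param M0 equilibrium signal scale given to the forward models.
#' @param frame_average apply the acquisition-window boxcar to the
#'   main-bolus aortic signal (disable to emulate an idealised instantaneous
#'   readout without temporal-footprint degradation).
#' @param frame_main main-bolus frame duration, s.
#' @param n_pre_contrast main-bolus pre-contrast frames.
#' @param n_volumes main-bolus post-contrast frames.
#' @param dt_pre pre-bolus frame duration, s.
#' @param t_pre_end pre-bolus acquisition length, s.
#' @return An object of class `"synthetic_subject"`: `truth`, `protocol`,
#'   the four SI [time_series()], and `true` — a list of noise-free truth
#'   curves (`prebolus_aorta_blood`, `aif_plasma`, `portal_plasma`,
#'   `liver_conc`) for parameter-recovery tests.
#' @export
generate_subject <- function(truth, protocol, M0 = 1000,
                             frame_average = TRUE,
                             frame_main = 3.2, n_pre_contrast = 3L,
                             n_volumes = 64L, dt_pre = 0.2,
                             t_pre_end = 60) {
  stopifnot(inherits(truth, "subject_truth"),
            inherits(protocol, "injection_protocol"))
  acq <- acquisition_defaults()
  relax_blood <- relaxation_params(T10 = truth$T10_blood, r1 = truth$r1)
  relax_liver <- relaxation_params(T10 = truth$T10_liver, r1 = truth$r1)

  t_main <- seq(0, by = frame_main,
                length.out = n_pre_contrast + n_volumes)
  t_max <- max(t_main) + frame_main
  t_pre <- seq(0, t_pre_end, by = dt_pre)

  main <- make_inputs(truth, protocol, "main", t_max = t_max)
  pre <- make_inputs(truth, protocol, "pre", t_max = t_pre_end + 2)

  hct <- truth$hematocrit
  aif_plasma <- time_series(main$aorta$t, main$aorta$y / (1 - hct), "mmol/L")
  pv_plasma <- time_series(main$portal$t, main$portal$y / (1 - hct), "mmol/L")
  liver_conc <- simulate_liver(aif_plasma, pv_plasma, truth$kinetic,
                               main$aorta$t, dt_max = 0.2)

  set.seed(truth$seed)

  # pre-bolus aorta: saturation-recovery readout + inflow + noise
  conc_pre <- interp_zero(pre$aorta$t, pre$aorta$y, t_pre)
  si_pre <- sat_recovery_signal(conc_pre, M0, acq$pre, relax_blood)
  si_pre <- si_pre * (1 + truth$inflow$amplitude *
                        sin(2 * pi * t_pre / truth$inflow$period))
  base_pre <- sat_recovery_signal(0, M0, acq$pre, relax_blood)
  si_pre <- si_pre + stats::rnorm(length(si_pre), 0,
                                  truth$noise_sd * base_pre)

  # main-bolus series: SPGR readout + noise; the aorta additionally gets
  # the acquisition-window boxcar
  render_main <- function(conc_master, t_master, relax, average = FALSE) {
    si <- spgr_signal(conc_master$y, M0, acq$main, relax)
    si_frames <- if (average) {
      frame_average(t_master, si, t_main, frame_main)
    } else {
      interp_zero(t_master, si, t_main)
    }
    base <- spgr_signal(0, M0, acq$main, relax)
    si_frames + stats::rnorm(length(si_frames), 0, truth$noise_sd * base)
  }
  si_aorta <- render_main(main$aorta, main$aorta$t, relax_blood,
                          average = frame_average)
  si_portal <- render_main(main$portal, main$portal$t, relax_blood)
  liver_master <- simulate_liver(aif_plasma, pv_plasma, truth$kinetic,
                                 main$aorta$t, dt_max = 0.05)
  si_liver <- render_main(liver_master, liver_master$t, relax_liver)

  structure(list(truth = truth, protocol = protocol,
                 prebolus_si = time_series(t_pre, si_pre, "a.u."),
                 mainbolus_aorta_si = time_series(t_main, si_aorta, "a.u."),
                 portal_si = time_series(t_main, si_portal, "a.u."),
                 liver_si = time_series(t_main, si_liver, "a.u."),
                 true = list(
                   prebolus_aorta_blood = pre$aorta,
                   aif_plasma = aif_plasma,
                   portal_plasma = pv_plasma,
                   liver_conc = liver_conc)),
            class = "synthetic_subject")
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf(
    "<synthetic_subject> seed %d | k1a %.4g k1p %.4g k2 %.4g /s | hct %.2f\n",
    x$truth$seed, x$truth$kinetic$k1a, x$truth$kinetic$k1p,
    x$truth$kinetic$k2, x$truth$hematocrit))
  cat("  pre-bolus SI : "); print(x$prebolus_si)
  cat("  main-bolus SI: "); print(x$mainbolus_aorta_si)
  invisible(x)
}

#' Fractional between-subject variability of the cohort generator
#'
#' Log-normal sigma per varied truth parameter; zero means the parameter is
#' fixed at its default across the cohort.
#'
#' @param k1a,k1p,k2,aif_amplitude,aif_scale,hematocrit log-scale standard
#'   deviations.
#' @return Named numeric vector.
#' @export
cohort_variability <- function(k1a = 0.4, k1p = 0.25, k2 = 0.25,
                               aif_amplitude = 0.2, aif_scale = 0.15,
                               hematocrit = 0.06) {
  c(k1a = k1a, k1p = k1p, k2 = k2, aif_amplitude = aif_amplitude,
    aif_scale = aif_scale, hematocrit = hematocrit)
}

#' Generate a synthetic cohort, optionally with test-retest replicates
#'
#' Subject truths are drawn log-normally around the [subject_truth()]
#' defaults with the sigmas of [cohort_variability()]. Seeding is
#' hierarchical and reproducible: subject i uses child seed
#' `master_seed + i`; its retest replicate shares the truth but uses noise
#' seed `master_seed + i + 1e6`, so the two visits differ only in noise —
#' the test-retest situation.
#'
#' @param n number of subjects (0 gives an empty cohort).
#' @param master_seed integer master seed.
#' @param variability a [cohort_variability()] vector.
#' @param retest also generate a second visit per subject.
#' @param protocol an [injection_protocol()].
#' @param truth_defaults baseline [subject_truth()] whose fields are
#'   perturbed.
#' @param ... passed on to [generate_subject()].
#' @return List of [generate_subject()] results; with `retest = TRUE` each
#'   element has a `$retest` field holding the second visit.
#' @export
generate_cohort <- function(n, master_seed,
                            variability = cohort_variability(),
                            retest = FALSE,
                            protocol = injection_protocol(weight = 70),
                            truth_defaults = subject_truth(), ...) {
  stopifnot(n >= 0, is.finite(master_seed))
  master_seed <- as.integer(master_seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    child <- master_seed + i
    set.seed(child)
    ln <- function(base, sig) base * exp(stats::rnorm(1, 0, sig))
    kin <- truth_defaults$kinetic
    truth <- subject_truth(
      kinetic = kinetic_params(ln(kin$k1a, variability[["k1a"]]),
                               ln(kin$k1p, variability[["k1p"]]),
                               ln(kin$k2, variability[["k2"]]),
                               kin$tau_a, kin$tau_p),
      aif_amplitude = ln(truth_defaults$aif$amplitude,
                         variability[["aif_amplitude"]]),
      aif_arrival = truth_defaults$aif$arrival,
      aif_shape = truth_defaults$aif$shape,
      aif_scale = ln(truth_defaults$aif$scale,
                     variability[["aif_scale"]]),
      recirc_fraction = truth_defaults$aif$recirc_fraction,
      recirc_delay = truth_defaults$aif$recirc_delay,
      recirc_dispersion = truth_defaults$aif$recirc_dispersion,
      portal_delay = truth_defaults$portal$delay,
      portal_dispersion = truth_defaults$portal$dispersion,
      hematocrit = min(0.59, ln(truth_defaults$hematocrit,
                                variability[["hematocrit"]])),
      T10_blood = truth_defaults$T10_blood,
      T10_liver = truth_defaults$T10_liver,
      r1 = truth_defaults$r1,
      noise_sd = truth_defaults$noise_sd,
      inflow_amplitude = truth_defaults$inflow$amplitude,
      inflow_period = truth_defaults$inflow$period,
      seed = child)
    subj <- generate_subject(truth, protocol, ...)
    subj$subject_id <- sprintf("S%03d", i)
    if (retest) {
      truth2 <- truth
      truth2$seed <- as.integer(child + 1e6)
      subj$retest <- generate_subject(truth2, protocol, ...)
      subj$retest$subject_id <- subj$subject_id
    }
    out[[i]] <- subj
  }
  out
}
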