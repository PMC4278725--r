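# shared in-code fixtures: acquisition settings of the two sequences,
# gamma-variate curve builder, and a brute-force injection-convolution
# oracle independent of reconstruct_aif()

acq_spgr <- function() acquisition_params("spgr", TR = 0.00296,
                                          TE = 0.00095, flip_angle = 12)
acq_sr <- function() acquisition_params("sat_recovery", TR = 0.0023,
                                        TE = 0.00091, flip_angle = 12,
                                        TS = 0.12)
relax_blood <- function(r1 = 6.3) relaxation_params(T10 = 1.2, r1 = r1)

gamma_curve <- function(t, t0 = 5, shape = 3, scale = 2, amp = 1) {
  x <- t - t0
  ifelse(x > 0, amp * (x / (shape * scale))^shape * exp(shape - x / scale), 0)
}

# oracle: response to a rectangular injection of the given rate/duration,
# by direct discrete convolution of the impulse response
oracle_inject <- function(t, h, rate, dur) {
  dt <- t[2] - t[1]
  n <- max(1L, round(dur / dt))
  kern <- rep(rate * dur / (n * dt), n)
  stats::convolve(h, rev(kern), type = "open")[seq_along(h)] * dt
}

quiet_truth <- function(...) subject_truth(noise_sd = 0,
                                           inflow_amplitude = 0, ...)
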