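test_that("impulse response has gamma-variate first-pass morphology", {
  t <- seq(0, 60, 0.05)
  tr <- subject_truth()
  pure <- tr$aif; pure$recirc_fraction <- 0
  h <- impulse_aif(t, pure)
  expect_true(all(h$y >= 0))
  # closed-form peak location of the gamma variate: arrival + shape * scale
  expect_equal(h$t[which.max(h$y)],
               pure$arrival + pure$shape * pure$scale, tolerance = 0.06)
  expect_equal(max(h$y), pure$amplitude, tolerance = 1e-6)

  zero <- pure; zero$amplitude <- 0
  expect_equal(max(impulse_aif(t, zero)$y), 0)

  full <- impulse_aif(t, tr$aif)
  expect_gt(pracma::trapz(full$t, full$y), 0)
  # recirculation bump stays below 40% of the first-pass peak
  late <- full$y[full$t > tr$aif$arrival + 2 * tr$aif$shape * tr$aif$scale]
  expect_lt(max(late), 0.4 * max(full$y))
  expect_error(subject_truth(recirc_fraction = 0.5), "recirc_fraction")
})

test_that("portal input is a dispersed, delayed, mass-conserving copy", {
  tr <- subject_truth()
  pro <- injection_protocol(weight = 70)
  inp <- make_inputs(tr, pro, "main", t_max = 400)
  expect_lt(max(inp$portal$y), max(inp$aorta$y))
  ia <- which.max(inp$aorta$y); ip <- which.max(inp$portal$y)
  expect_gt(inp$portal$t[ip], inp$aorta$t[ia])
  # mass conservation over a long horizon (normalised kernel)
  expect_equal(pracma::trapz(inp$portal$t, inp$portal$y),
               pracma::trapz(inp$aorta$t, inp$aorta$y), tolerance = 0.01)

  # vanishing dispersion degenerates to a pure delayed copy
  tr2 <- subject_truth(portal_dispersion = 1e-9, portal_delay = 5)
  inp2 <- make_inputs(tr2, pro, "main", t_max = 120)
  shifted <- liverdce:::interp_zero(inp2$aorta$t, inp2$aorta$y,
                                    inp2$aorta$t - 5)
  expect_equal(inp2$portal$y, shifted, tolerance = 1e-9)

  # doubling the dose doubles both curves
  pro2 <- injection_protocol(weight = 70, main_dose_per_kg = 0.1)
  inp3 <- make_inputs(tr, pro2, "main", t_max = 400)
  expect_equal(pracma::trapz(inp3$aorta$t, inp3$aorta$y),
               2 * pracma::trapz(inp$aorta$t, inp$aorta$y),
               tolerance = 5e-3)
})

test_that("subject generation is seed-deterministic", {
  tr <- subject_truth(seed = 33)
  pro <- injection_protocol(weight = 70)
  s1 <- generate_subject(tr, pro)
  s2 <- generate_subject(tr, pro)
  expect_identical(s1$prebolus_si$y, s2$prebolus_si$y)
  expect_identical(s1$liver_si$y, s2$liver_si$y)
  tr2 <- subject_truth(seed = 34)
  s3 <- generate_subject(tr2, pro)
  expect_false(identical(s1$prebolus_si$y, s3$prebolus_si$y))
})

test_that("noise-free signals invert back to the true concentrations", {
  tr <- quiet_truth(seed = 8)
  pro <- injection_protocol(weight = 70)
  s <- generate_subject(tr, pro)
  acq <- acquisition_defaults()
  rb <- relaxation_params(tr$T10_blood, tr$r1)
  conv <- signal_to_concentration(s$prebolus_si, 25, acq$pre, rb)
  truth <- resample(s$true$prebolus_aorta_blood, conv$series$t)
  expect_lt(max(abs(conv$series$y - truth$y)) / max(truth$y), 1e-6)
})

test_that("the main-bolus peak sits in the saturated SPGR regime", {
  tr <- subject_truth()
  pro <- injection_protocol(weight = 70)
  inp <- make_inputs(tr, pro, "main", t_max = 120)
  rel <- relaxation_params(tr$T10_blood, tr$r1)
  slope <- function(cc) (spgr_signal(cc + 1e-4, 1, acq_spgr(), rel) -
                           spgr_signal(cc - 1e-4, 1, acq_spgr(), rel)) / 2e-4
  c_half <- uniroot(function(cc) slope(cc) - 0.5 * slope(1e-4),
                    c(0.01, 20))$root
  expect_gt(max(inp$aorta$y), c_half)
})

test_that("the degraded main-bolus AIF loses peak and gains width", {
  # full-pipeline property: the saturated, frame-averaged 3.2 s aortic
  # readout clips the measured first-pass peak relative to the
  # reconstructed pre-bolus AIF (deterministic at zero noise)
  pro <- injection_protocol(weight = 70)
  cfg <- pipeline_config(list(simulate = list(n_subjects = 0)))
  tr <- quiet_truth(seed = 1)
  subj <- generate_subject(tr, pro)
  res <- process_subject(subj$prebolus_si, subj$mainbolus_aorta_si,
                         subj$portal_si, subj$liver_si,
                         tr$hematocrit, pro, cfg,
                         T10_liver = tr$T10_liver, fit = FALSE)
  expect_lt(res$shape_main$cpeak, res$shape_pre$cpeak)
  expect_gt(res$shape_main$fwhm, res$shape_pre$fwhm)
})

test_that("cohort generation is hierarchical-seeded and calibrated", {
  expect_length(generate_cohort(0, 1), 0)

  vz <- cohort_variability(0, 0, 0, 0, 0, 0)
  same <- generate_cohort(2, 5, variability = vz)
  expect_equal(same[[1]]$truth$kinetic, same[[2]]$truth$kinetic)

  co <- generate_cohort(20, 11)
  k1a <- vapply(co, function(s) s$truth$kinetic$k1a, numeric(1))
  # log-normal around the default: cohort mean within 3 SDs
  def <- subject_truth()$kinetic$k1a
  sig <- cohort_variability()[["k1a"]]
  mu_ln <- def * exp(sig^2 / 2)
  sd_ln <- mu_ln * sqrt(exp(sig^2) - 1)
  expect_lt(abs(mean(k1a) - mu_ln), 3 * sd_ln / sqrt(20))

  # retest replicates share the truth but not the noise stream
  rt <- generate_cohort(1, 3, retest = TRUE)[[1]]
  expect_equal(rt$truth$kinetic, rt$retest$truth$kinetic)
  expect_false(identical(rt$liver_si$y, rt$retest$liver_si$y))
})
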