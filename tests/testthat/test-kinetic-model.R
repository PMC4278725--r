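make_input_pair <- function(t = seq(0, 120, 0.2)) {
  ca <- time_series(t, gamma_curve(t, t0 = 8, amp = 6), "mmol/L")
  cp <- time_series(t, gamma_curve(t, t0 = 14, shape = 2.5, scale = 4,
                                   amp = 3), "mmol/L")
  list(ca = ca, cp = cp, t = t)
}

test_that("zero inflow gives zero output, constants reach the fixed point", {
  inp <- make_input_pair()
  zero <- simulate_liver(inp$ca, inp$cp, kinetic_params(0, 0, 0.1),
                         seq(0, 100, 2))
  expect_equal(zero$y, rep(0, length(zero$y)))
  cst <- time_series(seq(0, 2000, 1), rep(2, 2001), "mmol/L")
  ss <- simulate_liver(cst, cst, kinetic_params(0.01, 0.05, 0.1),
                       c(1500, 2000), dt_max = 0.2)
  expect_equal(ss$y, rep(2 * 0.06 / 0.1, 2), tolerance = 1e-4)
})

test_that("exponential-kernel solver agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  set.seed(17)
  inp <- make_input_pair()
  out_t <- seq(0, 110, 2)
  for (k in 1:3) {
    kp <- kinetic_params(runif(1, 0.002, 0.02), runif(1, 0.02, 0.1),
                         runif(1, 0.02, 0.2),
                         tau_a = runif(1, 0, 5), tau_p = runif(1, 0, 8))
    got <- simulate_liver(inp$ca, inp$cp, kp, out_t, dt_max = 0.05)
    rhs <- function(t, y, p) {
      ca <- if (t - p$tau_a <= 0) 0 else
        approx(inp$ca$t, inp$ca$y, t - p$tau_a, rule = 2)$y
      cp <- if (t - p$tau_p <= 0) 0 else
        approx(inp$cp$t, inp$cp$y, t - p$tau_p, rule = 2)$y
      list(p$k1a * ca + p$k1p * cp - p$k2 * y)
    }
    ref <- deSolve::ode(c(C = 0), out_t, rhs, kp, method = "lsoda",
                        rtol = 1e-8, atol = 1e-10)[, "C"]
    expect_lt(max(abs(got$y - ref)), 1e-4 * max(got$y))
  }
})

test_that("discrete mass balance holds to quadrature tolerance", {
  inp <- make_input_pair(seq(0, 200, 0.1))
  kp <- kinetic_params(0.01, 0.06, 0.07, tau_a = 1, tau_p = 3)
  fine <- seq(0, 200, 0.1)
  cl <- simulate_liver(inp$ca, inp$cp, kp, fine, dt_max = 0.1)
  u <- kp$k1a * liverdce:::interp_zero(inp$ca$t, inp$ca$y, fine - kp$tau_a) +
    kp$k1p * liverdce:::interp_zero(inp$cp$t, inp$cp$y, fine - kp$tau_p)
  inflow <- pracma::trapz(fine, u)
  outflow <- kp$k2 * pracma::trapz(fine, cl$y)
  expect_gte(inflow + 1e-12, cl$y[length(fine)])
  expect_equal(inflow, cl$y[length(fine)] + outflow,
               tolerance = 1e-3 * inflow)
})

test_that("noiseless self-consistency: simulate then refit recovers rates", {
  inp <- make_input_pair(seq(0, 180, 0.2))
  kp <- kinetic_params(0.01, 0.05, 0.1, tau_a = 2, tau_p = 4)
  liver <- simulate_liver(inp$ca, inp$cp, kp, seq(0, 180, 3.2))
  fit <- fit_dual_input(inp$ca, inp$cp, liver)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$k1a / kp$k1a - 1), 0.01)
  expect_lt(abs(fit$params$k1p / kp$k1p - 1), 0.01)
  expect_lt(abs(fit$params$k2 / kp$k2 - 1), 0.01)
  expect_lte(abs(fit$params$tau_a - kp$tau_a), 0.5)
  expect_lte(abs(fit$params$tau_p - kp$tau_p), 0.5)
})

test_that("an absent portal channel collapses to its bound", {
  inp <- make_input_pair(seq(0, 120, 0.2))
  kp <- kinetic_params(0.02, 0, 0.08, tau_a = 2, tau_p = 0)
  zero_p <- time_series(inp$t, rep(0, length(inp$t)), "mmol/L")
  liver <- simulate_liver(inp$ca, zero_p, kp, seq(0, 120, 3.2))
  fit <- fit_dual_input(inp$ca, zero_p, liver,
                        fit_options(delay_grid_a = 2, delay_grid_p = 0))
  expect_lt(fit$params$k1p, 1e-4)
  expect_lt(abs(fit$params$k1a / kp$k1a - 1), 0.01)
})

test_that("scaling the liver curve scales the inflow rates only", {
  inp <- make_input_pair(seq(0, 120, 0.2))
  kp <- kinetic_params(0.01, 0.05, 0.1, tau_a = 2, tau_p = 4)
  liver <- simulate_liver(inp$ca, inp$cp, kp, seq(0, 120, 3.2))
  opts <- fit_options(delay_grid_a = 2, delay_grid_p = 4)
  f1 <- fit_dual_input(inp$ca, inp$cp, liver, opts)
  alpha <- 1.7
  f2 <- fit_dual_input(inp$ca, inp$cp,
                       time_series(liver$t, alpha * liver$y, "mmol/L"), opts)
  expect_equal(f2$params$k1a, alpha * f1$params$k1a, tolerance = 1e-3)
  expect_equal(f2$params$k1p, alpha * f1$params$k1p, tolerance = 1e-3)
  expect_equal(f2$params$k2, f1$params$k2, tolerance = 1e-3)
})

test_that("fitted rates are invariant to internal grid refinement", {
  inp <- make_input_pair(seq(0, 120, 0.2))
  kp <- kinetic_params(0.01, 0.05, 0.1, tau_a = 2, tau_p = 4)
  liver <- simulate_liver(inp$ca, inp$cp, kp, seq(0, 120, 3.2))
  f1 <- fit_dual_input(inp$ca, inp$cp, liver,
                       fit_options(delay_grid_a = 2, delay_grid_p = 4,
                                   dt_max = 0.2))
  f2 <- fit_dual_input(inp$ca, inp$cp, liver,
                       fit_options(delay_grid_a = 2, delay_grid_p = 4,
                                   dt_max = 0.1))
  for (nm in c("k1a", "k1p", "k2"))
    expect_lt(abs(f2$params[[nm]] / f1$params[[nm]] - 1), 1e-3)
})

test_that("shifting inputs and liver together leaves fitted rates alone", {
  inp <- make_input_pair(seq(0, 120, 0.2))
  kp <- kinetic_params(0.01, 0.05, 0.1, tau_a = 2, tau_p = 4)
  liver <- simulate_liver(inp$ca, inp$cp, kp, seq(0, 120, 3.2))
  opts <- fit_options(delay_grid_a = seq(0, 8, 0.5),
                      delay_grid_p = seq(0, 8, 0.5))
  f1 <- fit_dual_input(inp$ca, inp$cp, liver, opts)
  delta <- 3   # multiple of the delay-grid step
  shift <- function(ts) time_series(ts$t + delta, ts$y, ts$units)
  f2 <- fit_dual_input(shift(inp$ca), shift(inp$cp), shift(liver), opts)
  for (nm in c("k1a", "k1p", "k2"))
    expect_lt(abs(f2$params[[nm]] / f1$params[[nm]] - 1), 5e-3)
})

test_that("perfusion derivation follows the flow-conversion formulas", {
  p <- derive_perfusion(kinetic_params(0.01, 0.05, 0.1))
  expect_equal(p$Fa, 60)
  expect_equal(p$Fp, 300)
  expect_equal(p$Ft, 360)
  expect_equal(p$ART, 100 / 6, tolerance = 1e-10)
  expect_equal(p$PV, 500 / 6, tolerance = 1e-10)
  expect_equal(p$DV, 60)
  expect_equal(p$MTT, 10)
  only_p <- derive_perfusion(kinetic_params(0, 0.05, 0.1))
  expect_equal(only_p$ART, 0)
  expect_equal(only_p$PV, 100)
  # DV = Ft * MTT / 60 is an algebraic identity of the conversions
  set.seed(2)
  for (k in 1:5) {
    pp <- derive_perfusion(kinetic_params(runif(1, 0, 0.05),
                                          runif(1, 0, 0.1),
                                          runif(1, 0.01, 0.3)))
    expect_equal(pp$DV, pp$Ft * pp$MTT / 60, tolerance = 1e-10)
  }
  expect_error(kinetic_params(0.01, 0.05, 0), "k2")
})
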