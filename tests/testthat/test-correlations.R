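test_that("dimensionless groups reproduce the published phase numbers", {
  fluid <- newtonian(16.7)
  g250 <- dimensionless_groups(flask250(250, 15), fluid)
  g450 <- dimensionless_groups(flask250(450, 15), fluid)
  expect_equal(round(g250$Ph, 2), 1.21)
  expect_equal(round(g450$Ph, 2), 1.44)
  expect_lt(g250$Re_film, g250$Re)
  expect_gt(g250$Re_film, 0)
})

test_that("phase number scales linearly with shaking diameter", {
  fluid <- newtonian(16.7)
  base <- dimensionless_groups(flask250(250, 15, d0_mm = 25), fluid)
  doubled <- dimensionless_groups(flask250(250, 15, d0_mm = 50), fluid)
  expect_equal(doubled$Ph, 2 * base$Ph, tolerance = 1e-12)
  # Re_film itself does not depend on d0
  expect_equal(doubled$Re_film, base$Re_film, tolerance = 1e-12)
})

test_that("phase number is monotone in frequency and viscosity", {
  n_grid <- c(150, 250, 350, 450)
  Ph_n <- vapply(n_grid, function(n) {
    dimensionless_groups(flask250(n, 15), newtonian(16.7))$Ph
  }, numeric(1))
  expect_true(all(diff(Ph_n) > 0))
  eta_grid <- c(1, 5, 20, 80, 150)
  Ph_eta <- vapply(eta_grid, function(e) {
    dimensionless_groups(flask250(250, 15), newtonian(e))$Ph
  }, numeric(1))
  expect_true(all(diff(Ph_eta) < 0))
})

test_that("overfilled flasks and degenerate inputs are rejected", {
  expect_error(shaking_conditions(n = 1, d = 0.02, d0 = 0.025,
                                  VL = mL_to_m3(250)),
               "filling volume")
  expect_error(newton_number(-1), "positive")
  expect_error(newton_number(0), "positive")
})

test_that("modified Newton number matches the scripted oracle values", {
  expect_equal(newton_number(1000), 0.8430062628417154, tolerance = 1e-12)
  expect_equal(newton_number(341.7), 1.4265698024596496, tolerance = 1e-12)
  Re <- 10^seq(0, 6, length.out = 60)
  expect_true(all(diff(newton_number(Re)) < 0))
})

test_that("in-phase power input matches the hand-evaluated chain", {
  P <- power_input_inphase(flask250(250, 25), newtonian(80))
  expect_equal(P, 5252.417112769707, tolerance = 1e-10)
  # vanishing frequency sends P/VL to zero (n^3 prefactor dominates)
  P_slow <- power_input_inphase(
    shaking_conditions(n = 1e-6, d = 0.0813, d0 = 0.025, VL = mL_to_m3(25)),
    newtonian(80))
  expect_lt(P_slow, 1e-8)
  # power input rises with viscosity at fixed kinematics
  etas <- c(10, 30, 80, 150)
  Ps <- vapply(etas, function(e) {
    power_input_inphase(flask250(250, 25), newtonian(e))
  }, numeric(1))
  expect_true(all(diff(Ps) > 0))
})

test_that("power correlations are invariant under consistent unit rescaling", {
  # evaluate in a g/mm/s unit system: density g/mm^3 = 1e-6 x SI,
  # viscosity g/(mm s) = SI numeric, P/V in g/(mm s^3) = SI numeric,
  # kinematic viscosity mm^2/s = 1e6 x SI
  cond_si <- flask250(250, 25)
  P_si <- power_input_inphase(cond_si, newtonian(80))
  cond_mm <- shaking_conditions(n = rpm_to_hz(250), d = 81.3, d0 = 25,
                                VL = 25e3)
  fluid_mm <- fluid_spec(rho = 1e-6 * 1000, eta = 0.080)
  P_mm <- power_input_inphase(cond_mm, fluid_mm)
  expect_equal(P_mm, P_si, tolerance = 1e-10)

  kla_si <- kla_correlation(flask250(300, 25), newtonian(1), DL = 2e-9)
  cond_mm2 <- shaking_conditions(n = rpm_to_hz(300), d = 81.3, d0 = 25,
                                 VL = 25e3, g = 9.81e3)
  kla_mm <- kla_correlation(cond_mm2, fluid_spec(rho = 1e-6 * 1000,
                                                 eta = 0.001),
                            DL = 2e-9 * 1e6)
  expect_equal(kla_mm, kla_si, tolerance = 1e-10)

  g_si <- effective_shear_giese(P_si, K = 0.104, m = 0.956,
                                VL = 25e-6, d = 0.0813)
  # K in g/(mm s^(2-m)) keeps its SI numeric value, as does P/V
  g_mm <- effective_shear_giese(P_si, K = 0.104, m = 0.956,
                                VL = 25e3, d = 81.3)
  expect_equal(g_mm, g_si, tolerance = 1e-10)
})

test_that("kLa correlation matches its term-by-term oracle and scalings", {
  kla <- kla_correlation(flask250(300, 25), newtonian(1), DL = 2e-9)
  expect_equal(kla, 0.06989733021468647, tolerance = 1e-12)
  expect_equal(kla * 3600, 251.6, tolerance = 1e-3)
  kla2n <- kla_correlation(flask250(600, 25), newtonian(1), DL = 2e-9)
  expect_equal(kla2n, 2 * kla, tolerance = 1e-12)
  kla4D <- kla_correlation(flask250(300, 25), newtonian(1), DL = 8e-9)
  expect_equal(kla4D, 2 * kla, tolerance = 1e-12)
})

test_that("out-of-phase quotient behaves per the exponential model", {
  q <- oophase_quotient(1.26)
  expect_equal(q$quotient, 1 - 3.43 * exp(-2.02 * 1.26), tolerance = 1e-12)
  # ~30% reduction after rounding to one significant figure
  expect_equal(signif((1 - q$quotient) * 100, 1), 30)
  expect_false(q$warning_flag)
  root <- log(3.43) / 2.02
  expect_equal(oophase_quotient(root)$quotient, 0, tolerance = 1e-12)
  expect_true(oophase_quotient(root / 2)$warning_flag)
  expect_equal(oophase_quotient(root / 2)$clamped, 0)
  expect_equal(oophase_quotient(50)$quotient, 1, tolerance = 1e-12)
  Ph <- seq(0.3, 4, by = 0.05)
  expect_true(all(diff(oophase_quotient(Ph)$quotient) > 0))
  expect_true(all(oophase_quotient(Ph)$quotient < 1))
})

test_that("regime classification uses the 1.26/0.91 thresholds", {
  expect_equal(as.character(classify_regime(1.30)), "in_phase")
  expect_equal(as.character(classify_regime(1.26)), "in_phase")
  expect_equal(as.character(classify_regime(1.00)), "transition")
  expect_equal(as.character(classify_regime(0.91)), "transition")
  expect_equal(as.character(classify_regime(0.90)), "out_of_phase")
})

test_that("corrected power input multiplies the clamped quotient", {
  cond <- flask250(250, 25)
  fluid <- newtonian(37)
  out <- power_input_corrected(cond, fluid)
  expect_equal(out$P_per_V / out$P_per_V_inphase,
               max(oophase_quotient(out$Ph)$quotient, 0), tolerance = 1e-12)
  # deep in-phase: correction below 1%
  fast <- shaking_conditions(n = rpm_to_hz(400), d = 0.0813,
                             d0 = 0.075, VL = mL_to_m3(25))
  out_fast <- power_input_corrected(fast, newtonian(1))
  expect_gt(out_fast$Ph, 3)
  expect_gt(out_fast$P_per_V / out_fast$P_per_V_inphase, 0.99)
  # deep out-of-phase clamps at zero with a warning
  slow <- shaking_conditions(n = rpm_to_hz(450), d = 0.0813, d0 = 0.0125,
                             VL = mL_to_m3(15))
  expect_warning(out_slow <- power_input_corrected(slow, newtonian(104)),
                 "clamped")
  expect_lt(out_slow$Ph, log(3.43) / 2.02)
  expect_equal(out_slow$P_per_V, 0)
})

test_that("effective shear rate matches its direct-evaluation oracle", {
  g <- effective_shear_giese(5252.417112769707, K = 0.104, m = 0.956,
                             VL = 25e-6, d = 0.0813)
  expect_equal(g, 436.4693650011804, tolerance = 1e-10)
  # m = 1 reduces the exponent to a square-root law
  g1 <- effective_shear_giese(5000, K = 0.1, m = 1, VL = 25e-6, d = 0.0813)
  expect_equal(g1,
               sqrt(2.06 * (5000 / 0.1) * (25e-6^(1 / 3) / 0.0813)^(-0.33)),
               tolerance = 1e-12)
})

test_that("effective-viscosity fixed point converges and is well posed", {
  cond <- flask250(250, 25)
  fp <- effective_viscosity_fixed_point(cond, pvp_broth())
  expect_true(fp$converged)
  # published rounding: about 80 mPa.s to the nearest 10
  expect_equal(round(fp$eta_eff * 1e3 / 10) * 10, 80)
  # m = 1: fixed point is K exactly
  fp1 <- effective_viscosity_fixed_point(cond,
                                         fluid_spec(rho = 1000, K = 0.05,
                                                    m = 1))
  expect_equal(fp1$eta_eff, 0.05, tolerance = 1e-12)
  # initialization independence within 10x tolerance
  fp_a <- effective_viscosity_fixed_point(cond, pvp_broth(), eta0 = 0.104)
  fp_b <- effective_viscosity_fixed_point(cond, pvp_broth(), eta0 = 1e-3)
  expect_equal(fp_a$eta_eff, fp_b$eta_eff, tolerance = 1e-9)
  # self-consistency: returned gamma and eta satisfy the power law
  expect_equal(fp$eta_eff, 0.104 * fp$gamma_eff^(0.956 - 1),
               tolerance = 1e-8)
})

test_that("correction fit recovers generating parameters", {
  Ph <- seq(0.7, 3, length.out = 40)
  y <- 1 - 3.43 * exp(-2.02 * Ph)
  fit <- fit_correction(Ph, y)
  expect_equal(fit$a, 3.43, tolerance = 1e-6)
  expect_equal(fit$b, 2.02, tolerance = 1e-6)
  # noisy recovery within 5% at sd 0.02, n = 100, fixed seed
  set.seed(7)
  Ph_n <- stats::runif(100, 0.7, 3)
  y_n <- 1 - 3.43 * exp(-2.02 * Ph_n) + stats::rnorm(100, sd = 0.02)
  fit_n <- fit_correction(Ph_n, y_n)
  expect_equal(fit_n$a, 3.43, tolerance = 0.05)
  expect_equal(fit_n$b, 2.02, tolerance = 0.05)
  # degenerate and insufficient data
  expect_error(fit_correction(c(1, 2), c(0.5, 0.9)), "at least 3")
  expect_warning(flat <- fit_correction(1:5, rep(1, 5)), "unidentifiable")
  expect_equal(flat$a, 0)
})
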