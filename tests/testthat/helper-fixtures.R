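# shared fixtures: the 250 mL flask geometry and common fluids

flask250 <- function(n_rpm, VL_mL, d0_mm = 25, d_m = 0.0813) {
  shaking_conditions(n = rpm_to_hz(n_rpm), d = d_m, d0 = mm_to_m(d0_mm),
                     VL = mL_to_m3(VL_mL))
}

newtonian <- function(eta_mPas, rho = 1000) {
  fluid_spec(rho = rho, eta = mPas_to_Pas(eta_mPas))
}

pvp_broth <- function() fluid_spec(rho = 1000, K = 0.104, m = 0.956)

# random symmetric 3x3 strain tensors packed as component arrays
random_sym_tensors <- function(n, seed = 42) {
  set.seed(seed)
  comps <- replicate(6, array(stats::rnorm(n), dim = c(n, 1, 1)),
                     simplify = FALSE)
  names(comps) <- c("Sxx", "Syy", "Szz", "Sxy", "Sxz", "Syz")
  comps
}
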