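# analytic snapshots used across several blocks
couette_grid <- function(res = 16, gamma0 = 10, L = 0.1) {
  synthetic_field("couette", gamma0 = gamma0, resolution = res,
                  box = c(L, L, L))$grid
}

test_that("planar Couette flow yields exact strain measures", {
  grid <- couette_grid(gamma0 = 10)
  derived <- strain_rate_fields(grid)
  # the field is linear, so even one-sided boundary stencils are exact
  expect_equal(max(abs(derived$S_norm - 10)), 0, tolerance = 1e-10)
  expect_equal(max(abs(derived$lambda1 - 5)), 0, tolerance = 1e-10)
})

test_that("rigid rotation carries no strain", {
  grid <- synthetic_field("rigid_rotation", Omega = 25, resolution = 16)$grid
  derived <- strain_rate_fields(grid)
  expect_lt(max(derived$S_norm), 1e-10)
  expect_lt(max(derived$lambda1), 1e-10)
  ps <- postprocess_snapshot(grid, fluid_spec(rho = 1000, eta = 0.1))
  expect_lt(ps$eps, 1e-20)
})

test_that("closed-form lambda1 agrees with the dense eigensolver oracle", {
  comps <- random_sym_tensors(1000)
  lam <- shakeflask:::.sym3_lambda1(comps$Sxx, comps$Syy, comps$Szz,
                                    comps$Sxy, comps$Sxz, comps$Syz)
  S_norm <- with(comps, sqrt(2 * (Sxx^2 + Syy^2 + Szz^2) +
                               4 * (Sxy^2 + Sxz^2 + Syz^2)))
  for (i in seq_len(1000)) {
    M <- matrix(c(comps$Sxx[i], comps$Sxy[i], comps$Sxz[i],
                  comps$Sxy[i], comps$Syy[i], comps$Syz[i],
                  comps$Sxz[i], comps$Syz[i], comps$Szz[i]), 3, 3)
    lam_oracle <- max(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
    expect_lt(abs(lam[i] - lam_oracle), 1e-10 * max(S_norm[i], 1e-300))
  }
})

test_that("traceless strain tensors satisfy S_norm >= sqrt(3) * lambda1", {
  set.seed(3)
  for (i in 1:200) {
    s <- stats::rnorm(5)
    Sxx <- s[1]; Syy <- s[2]; Szz <- -(s[1] + s[2])
    lam <- shakeflask:::.sym3_lambda1(array(Sxx), array(Syy), array(Szz),
                                      array(s[3]), array(s[4]), array(s[5]))
    S_norm <- sqrt(2 * (Sxx^2 + Syy^2 + Szz^2) + 4 * sum(s[3:5]^2))
    expect_gte(S_norm * (1 + 1e-9), sqrt(3) * max(lam, 0))
  }
})

test_that("energy dissipation reproduces the Couette closed form", {
  grid <- couette_grid(gamma0 = 10)
  fluid <- fluid_spec(rho = 1000, eta = 0.1)
  out <- energy_dissipation(grid, fluid)
  expect_equal(out$eps, 0.01, tolerance = 1e-12)       # (eta/rho)*gamma0^2
  expect_equal(out$P_per_V, 10, tolerance = 1e-12)     # eps * rho
  expect_equal(out$P_per_V, out$eps * fluid$rho)
  # quiescent field dissipates nothing
  still <- synthetic_field("slab_interface", resolution = 8)$grid
  expect_equal(energy_dissipation(still, fluid)$eps, 0)
})

test_that("turbulence fields add the beta*-weighted contribution", {
  grid <- couette_grid(gamma0 = 10, res = 8)
  grid$k <- array(0.01, dim = dim(grid$u))
  grid$omega <- array(10, dim = dim(grid$u))
  fluid <- fluid_spec(rho = 1000, eta = 0.1)
  out <- energy_dissipation(grid, fluid)
  expect_equal(out$eps, 0.01 + 0.09 * 10 * 0.01, tolerance = 1e-12)
})

test_that("interfacial area integrates |grad alpha| to geometric areas", {
  slab <- synthetic_field("slab_interface", resolution = 24)
  area <- interfacial_area(slab$grid)
  expect_equal(area$area_total, slab$reference$area_total, tolerance = 0.01)
  # uniform alpha: no interface
  full <- couette_grid(res = 8)
  expect_equal(interfacial_area(full)$area_total, 0)
  # diffuse sphere recovers 4*pi*r^2 within 2%
  drop <- synthetic_field("droplet", resolution = 48, box = c(0.1, 0.1, 0.1),
                          r = 0.025, interface_thickness = 0.009)
  expect_equal(interfacial_area(drop$grid)$area_total,
               4 * pi * 0.025^2, tolerance = 0.02)
})

test_that("uniform-dissipation kLa factorizes into closed form", {
  # Couette shear (uniform local dissipation) with a planar interface
  res <- 24L
  L <- 0.1
  gamma0 <- 10
  x <- (seq_len(res) - 0.5) * L / res
  Z <- array(rep(x, each = res * res), dim = c(res, res, res))
  thick <- 6 * L / res
  alpha <- pmin(pmax((0.5 * L - Z) / thick + 0.5, 0), 1)
  grid <- field_grid(x, x, x, u = gamma0 * Z,
                     v = array(0, dim = c(res, res, res)),
                     w = array(0, dim = c(res, res, res)), alpha = alpha)
  fluid <- fluid_spec(rho = 1000, eta = 0.05)
  DL <- 2e-9
  out <- kla_fields(grid, fluid, DL)
  nu <- fluid$nu
  eps_u <- (fluid$eta / fluid$rho) * gamma0^2
  kla_ref <- 0.4 * sqrt(DL) * (eps_u / nu)^(1 / 4) * (L * L) / L^3
  expect_equal(out$kLa_total, kla_ref, tolerance = 0.01)
  # liquid normalization rescales by domain/liquid volume
  expect_equal(out$kLa_liquid,
               out$kLa_total * L^3 / liquid_volume(grid), tolerance = 1e-10)
  # sqrt dependence on DL is exact for fixed fields
  out4 <- kla_fields(grid, fluid, 4 * DL)
  expect_equal(out4$kLa_total, 2 * out$kLa_total, tolerance = 1e-12)
  # no dissipation -> no transfer
  stillg <- field_grid(x, x, x, u = array(0, dim = c(res, res, res)),
                       v = array(0, dim = c(res, res, res)),
                       w = array(0, dim = c(res, res, res)), alpha = alpha)
  expect_equal(kla_fields(stillg, fluid, DL)$kLa_total, 0)
})

test_that("shear estimators return their Couette means and alpha weighting", {
  grid <- couette_grid(gamma0 = 10)
  derived <- strain_rate_fields(grid)
  expect_equal(shear_rate_fields(grid, derived, "strain_norm")$gamma_mean,
               10, tolerance = 1e-10)
  expect_equal(shear_rate_fields(grid, derived, "eigen")$gamma_mean,
               12.5, tolerance = 1e-10)
  expect_error(shear_rate_fields(grid, derived, "bogus"))
  # alpha weighting averages over the liquid region only: quadratic
  # shear profile, liquid in the lower half of the box
  res <- 20L
  L <- 1
  xc <- (seq_len(res) - 0.5) / res
  Z <- array(rep(xc, each = res * res), dim = c(res, res, res))
  grid2 <- field_grid(xc, xc, xc, u = Z^2,
                      v = array(0, dim = c(res, res, res)),
                      w = array(0, dim = c(res, res, res)),
                      alpha = (Z < 0.5) * 1)
  d2 <- strain_rate_fields(grid2)
  liquid_mean <- mean(d2$S_norm[Z < 0.5])
  got <- shear_rate_fields(grid2, d2, "strain_norm")$gamma_mean
  expect_equal(got, liquid_mean, tolerance = 1e-12)
  full_mean <- mean(d2$S_norm)
  expect_gt(abs(got - full_mean) / full_mean, 0.1)
})

test_that("non-Newtonian shear iteration converges to 2.5*lambda1", {
  grid <- couette_grid(gamma0 = 10, res = 8)
  derived <- strain_rate_fields(grid)
  out <- shear_rate_nonnewtonian(derived, K = 0.104, m = 0.956)
  expect_equal(max(abs(out$gamma_cell - 2.5 * derived$lambda1)),
               0, tolerance = 1e-8 * 2.5 * max(derived$lambda1))
  expect_lte(out$iterations, 12L)
  # consistency: returned viscosity is the power law at the iterate
  expect_equal(out$eta_cell[2, 2, 2],
               0.104 * out$gamma_cell[2, 2, 2]^(0.956 - 1), tolerance = 1e-10)
  # m = 1 terminates immediately with the Newtonian estimator
  out1 <- shear_rate_nonnewtonian(derived, K = 0.1, m = 1)
  expect_identical(out1$iterations, 1L)
  expect_equal(out1$gamma_cell, 2.5 * derived$lambda1, tolerance = 1e-15)
  # zero strain cells stay at zero
  still <- strain_rate_fields(synthetic_field("slab_interface",
                                              resolution = 8)$grid)
  expect_equal(max(shear_rate_nonnewtonian(still, 0.1, 0.9)$gamma_cell), 0)
  # diverging regime rejected with an explanation
  expect_error(shear_rate_nonnewtonian(derived, 0.1, 0.4), "diverges")
})

test_that("interior errors shrink at second order under grid refinement", {
  # smooth shear profile u = sin(2*pi*z/L): S_norm = |2*pi/L*cos(2*pi*z/L)|
  make <- function(res) {
    L <- 1
    xc <- (seq_len(res) - 0.5) / res
    Z <- array(rep(xc, each = res * res), dim = c(res, res, res))
    grid <- field_grid(xc, xc, xc, u = sin(2 * pi * Z),
                       v = array(0, dim = c(res, res, res)),
                       w = array(0, dim = c(res, res, res)),
                       alpha = array(1, dim = c(res, res, res)))
    derived <- strain_rate_fields(grid)
    interior <- 2:(res - 1)
    exact <- abs(2 * pi * cos(2 * pi * Z))
    max(abs(derived$S_norm - exact)[interior, interior, interior])
  }
  e16 <- make(16)
  e32 <- make(32)
  ratio <- e16 / e32
  expect_gt(ratio, 3.4)
  expect_lt(ratio, 4.6)
})

test_that("tiny grids are rejected for gradient work", {
  x <- c(0.25, 0.75)
  arr <- array(0, dim = c(2, 2, 2))
  grid <- field_grid(x, x, x, arr, arr, arr, alpha = array(1, dim = dim(arr)))
  expect_error(strain_rate_fields(grid), "at least 3")
})
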