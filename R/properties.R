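#' Hard-sphere molecular radius from molecular weight
#'
#' \deqn{r = \left(\frac{3\,MW}{4\pi\,\rho_{eff}\,N_A}\right)^{1/3}}
#' with an effective density fitted across many solute/solvent
#' combinations (default 619 kg/m^3).
#'
#' @param MW Molecular weight (kg/mol). Use [gmol_to_kgmol()] for g/mol.
#' @param rho_eff Effective density (kg/m^3).
#' @return Hard-sphere radius in metres.
#' @export
hard_sphere_radius <- function(MW, rho_eff = 619) {
  if (any(!is.finite(MW)) || any(MW <= 0)) {
    stop("'MW' must be positive and finite", call. = FALSE)
  }
  .check_positive(rho_eff, "rho_eff")
  NAv <- physical_constants[["NA_const"]]
  (3 * MW / (4 * pi * rho_eff * NAv))^(1 / 3)
}

#' @rdname bench-units
#' @export
gmol_to_kgmol <- function(x) x * 1e-3

#' Gierer-Wirtz microfriction correction factor
#'
#' For small solutes the continuum assumption behind Stokes-Einstein
#' fails; the correction factor
#' \deqn{f_{GW} = \left(\frac{3\beta}{2} + \frac{1}{1+\beta}\right)^{-1}}
#' rescales the friction term, where
#' \eqn{\beta = (MW_{solute}/MW_{solvent})^{1/3}} is the solute/solvent
#' radius ratio under the hard-sphere model.  With equal molecular
#' weights \eqn{f_{GW} = 1/2}; the factor decreases monotonically with
#' increasing \eqn{\beta}.
#'
#' @param beta Radius ratio(s), > 0.
#' @return Correction factor(s) in (0, 1].
#' @export
gierer_wirtz_factor <- function(beta) {
  if (any(!is.finite(beta)) || any(beta <= 0)) {
    stop("'beta' must be positive and finite", call. = FALSE)
  }
  1 / (3 * beta / 2 + 1 / (1 + beta))
}

#' Diffusion coefficient of a small solute
#'
#' Stokes-Einstein-Gierer-Wirtz estimate of the molecular diffusion
#' coefficient,
#' \deqn{D_L = \frac{k_B T}{6\pi\,\eta\,r_{solute}\,f_{GW}},}
#' with the solute radius from [hard_sphere_radius()] and the
#' microfriction factor from [gierer_wirtz_factor()] with
#' \eqn{\beta = (MW_{solute}/MW_{solvent})^{1/3}}.
#'
#' @param MW_solute Solute molecular weight (kg/mol).
#' @param MW_solvent Solvent molecular weight (kg/mol).
#' @param T Temperature (K).
#' @param eta Solvent dynamic viscosity (Pa s).
#' @param rho_eff Effective hard-sphere density (kg/m^3).
#' @return Diffusion coefficient in m^2/s.
#' @examples
#' # oxygen in water at 20 degC, 1 mPa.s: ~1.8e-9 m^2/s
#' diffusion_coefficient(gmol_to_kgmol(32), gmol_to_kgmol(18),
#'                       T = 293.15, eta = 1e-3)
#' @export
diffusion_coefficient <- function(MW_solute, MW_solvent, T, eta,
                                  rho_eff = 619) {
  .check_positive(MW_solute, "MW_solute")
  .check_positive(MW_solvent, "MW_solvent")
  .check_positive(T, "T")
  .check_positive(eta, "eta")
  beta <- (MW_solute / MW_solvent)^(1 / 3)
  r_solute <- hard_sphere_radius(MW_solute, rho_eff)
  f_GW <- gierer_wirtz_factor(beta)
  kB <- physical_constants[["kB"]]
  kB * T / (6 * pi * eta * r_solute * f_GW)
}

#' Power-law (Ostwald-de Waele) rheology
#'
#' Shear stress and effective viscosity of a power-law fluid at a given
#' shear rate: \eqn{\tau = K\gamma^m} and
#' \eqn{\eta_{eff} = K\gamma^{m-1}}, so that
#' \eqn{\tau = \eta_{eff}\gamma} identically.
#'
#' @param K Flow consistency index (Pa s^m).
#' @param m Flow behavior index.
#' @param gamma Shear rate(s) (1/s), strictly positive: at zero shear
#'   the effective viscosity of a shear-thinning fluid (m < 1) is
#'   unbounded.
#' @return A list with `tau` (Pa) and `eta_eff` (Pa s).
#' @export
power_law_eval <- function(K, m, gamma) {
  .check_positive(K, "K")
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m)) {
    stop("'m' must be a single finite number", call. = FALSE)
  }
  if (any(!is.finite(gamma)) || any(gamma <= 0)) {
    stop("'gamma' must be strictly positive (effective viscosity is ",
         "undefined at zero shear for m < 1)", call. = FALSE)
  }
  list(tau = K * gamma^m, eta_eff = K * gamma^(m - 1))
}
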