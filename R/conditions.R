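#' Operating point of a shaken flask
#'
#' Bundles the geometric and kinematic quantities that define one shake
#' flask run.  All arguments are SI; use [rpm_to_hz()], [mm_to_m()] and
#' [mL_to_m3()] (or [read_conditions()]) to convert bench units.
#'
#' @param n Shaking frequency (1/s).
#' @param d Largest inner flask diameter (m).
#' @param d0 Shaking (orbit) diameter (m).
#' @param VL Filling volume (m^3).
#' @param T Temperature (K). Carried for property evaluation; the
#'   hydrodynamic correlations do not use it directly.
#' @param g Gravitational acceleration (m/s^2).
#' @return An object of class `shaking_conditions`.
#' @details The film-geometry argument of the film Reynolds number
#'   requires \eqn{(4/\pi)(V_L^{1/3}/d)^2 \le 1}; conditions violating
#'   this (overfilled flasks) are rejected.
#' @examples
#' shaking_conditions(n = rpm_to_hz(250), d = 0.0813, d0 = 0.025,
#'                    VL = mL_to_m3(15))
#' @export
shaking_conditions <- function(n, d, d0, VL, T = 293.15, g = 9.81) {
  .check_positive(n, "n")
  .check_positive(d, "d")
  .check_positive(d0, "d0")
  .check_positive(VL, "VL")
  .check_positive(T, "T")
  .check_positive(g, "g")
  film_arg <- (4 / pi) * (VL^(1 / 3) / d)^2
  if (film_arg > 1) {
    stop("filling volume too large for flask diameter: ",
         sprintf("(4/pi)*(VL^(1/3)/d)^2 = %.3f exceeds 1", film_arg),
         call. = FALSE)
  }
  structure(list(n = n, d = d, d0 = d0, VL = VL, T = T, g = g),
            class = "shaking_conditions")
}

#' @export
print.shaking_conditions <- function(x, ...) {
  cat("Shaking conditions:\n")
  cat(sprintf("  n  = %.4g 1/s (%.4g rpm)\n", x$n, x$n * 60))
  cat(sprintf("  d  = %.4g m, d0 = %.4g m\n", x$d, x$d0))
  cat(sprintf("  VL = %.4g mL, T = %.4g K, g = %.4g m/s^2\n",
              x$VL * 1e6, x$T, x$g))
  invisible(x)
}

#' Nominal 250 mL flask preset
#'
#' Returns the largest inner diameter (m) assumed for an unbaffled
#' narrow-neck 250 mL Erlenmeyer flask.  The value is a nominal geometry
#' choice and can always be overridden by passing `d` explicitly.
#'
#' @param name Preset name; only `"250mL"` is provided.
#' @return Largest inner flask diameter in metres.
#' @export
flask_preset <- function(name = "250mL") {
  presets <- c("250mL" = 0.0813)
  if (!name %in% names(presets)) {
    stop("unknown flask preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  unname(presets[[name]])
}

#' Fluid description: density plus rheology
#'
#' A fluid is either Newtonian (constant dynamic viscosity `eta`) or a
#' shear-thinning power-law (Ostwald-de Waele) fluid with consistency
#' index `K` and flow behavior index `m`.  Surface tension and contact
#' angle are carried as provenance only; no computation here uses them.
#'
#' @param rho Density (kg/m^3).
#' @param eta Dynamic viscosity (Pa s) for a Newtonian fluid.
#' @param K Flow consistency index (Pa s^m) for a power-law fluid.
#' @param m Flow behavior index (dimensionless, 0 < m <= 1.5).
#' @param sigma Surface tension (N/m), optional provenance.
#' @param theta Contact angle (degrees), optional provenance.
#' @return An object of class `fluid_spec` with a `rheology` field of
#'   `"newtonian"` or `"power_law"` and, for Newtonian fluids, the
#'   kinematic viscosity `nu = eta/rho`.
#' @examples
#' water <- fluid_spec(rho = 998, eta = 1e-3)
#' pvp   <- fluid_spec(rho = 1000, K = 0.104, m = 0.956)
#' @export
fluid_spec <- function(rho, eta = NULL, K = NULL, m = NULL,
                       sigma = NULL, theta = NULL) {
  .check_positive(rho, "rho")
  newtonian <- !is.null(eta)
  powerlaw <- !is.null(K) || !is.null(m)
  if (newtonian && powerlaw) {
    stop("supply either 'eta' (Newtonian) or 'K' and 'm' (power law), not both",
         call. = FALSE)
  }
  if (!newtonian && !powerlaw) {
    stop("rheology missing: supply 'eta' or the pair 'K', 'm'", call. = FALSE)
  }
  if (newtonian) {
    .check_positive(eta, "eta")
    out <- list(rho = rho, rheology = "newtonian", eta = eta, nu = eta / rho)
  } else {
    if (is.null(K) || is.null(m)) {
      stop("power-law rheology needs both 'K' and 'm'", call. = FALSE)
    }
    .check_positive(K, "K")
    if (!is.numeric(m) || length(m) != 1L || !is.finite(m) ||
        m <= 0 || m > 1.5) {
      stop("flow behavior index 'm' must lie in (0, 1.5]", call. = FALSE)
    }
    out <- list(rho = rho, rheology = "power_law", K = K, m = m)
  }
  out$sigma <- sigma
  out$theta <- theta
  structure(out, class = "fluid_spec")
}

#' @export
print.fluid_spec <- function(x, ...) {
  cat("Fluid: rho =", x$rho, "kg/m^3;",
      if (x$rheology == "newtonian") {
        sprintf("Newtonian, eta = %.4g mPa.s", x$eta * 1e3)
      } else {
        sprintf("power law, K = %.4g mPa.s^m, m = %.4g", x$K * 1e3, x$m)
      }, "\n")
  invisible(x)
}

# Resolve a single Newtonian viscosity or fail loudly.
.resolve_eta <- function(fluid) {
  if (!inherits(fluid, "fluid_spec")) stop("'fluid' must be a fluid_spec",
                                           call. = FALSE)
  if (fluid$rheology != "newtonian") {
    stop("operation requires a Newtonian viscosity; use ",
         "effective_viscosity_fixed_point() to reduce a power-law fluid ",
         "to an effective Newtonian viscosity first", call. = FALSE)
  }
  fluid$eta
}
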