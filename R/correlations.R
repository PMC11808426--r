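#' Dimensionless groups of a shaken flask run
#'
#' Computes the flask Reynolds number, the film Reynolds number and the
#' phase number for one operating point with a Newtonian fluid.
#'
#' @details
#' The groups are
#' \deqn{Re = \rho n d^2 / \eta,}
#' \deqn{Re_{film} = Re \cdot \frac{\pi}{2}\left[1 -
#'   \sqrt{1 - \frac{4}{\pi}\left(\frac{V_L^{1/3}}{d}\right)^2}\,\right]^2,}
#' \deqn{Ph = \frac{d_0}{d}\,(1 + 3\log_{10} Re_{film}).}
#' The film Reynolds number rescales the flask Reynolds number with the
#' geometry of the rotating liquid film; note the squared outer bracket.
#' The phase number indicates whether the bulk liquid follows the
#' orbital shaking motion ("in phase") or collapses to the flask bottom
#' ("out of phase"); see [classify_regime()].
#'
#' @param cond A [shaking_conditions()] object.
#' @param fluid A Newtonian [fluid_spec()].
#' @return A list of class `dimensionless_state` with elements `Re`,
#'   `Re_film`, `Ph` and `Ne_prime` (the latter `NA` here; see
#'   [newton_number()]).
#' @examples
#' cond <- shaking_conditions(rpm_to_hz(250), d = 0.0813, d0 = 0.025,
#'                            VL = mL_to_m3(15))
#' dimensionless_groups(cond, fluid_spec(rho = 1000, eta = 16.7e-3))
#' @export
dimensionless_groups <- function(cond, fluid) {
  stopifnot(inherits(cond, "shaking_conditions"))
  eta <- .resolve_eta(fluid)
  Re <- fluid$rho * cond$n * cond$d^2 / eta
  film_arg <- 1 - (4 / pi) * (cond$VL^(1 / 3) / cond$d)^2
  if (film_arg < 0) {
    stop("film geometry argument negative; flask overfilled", call. = FALSE)
  }
  Re_film <- Re * (pi / 2) * (1 - sqrt(film_arg))^2
  if (Re_film <= 0) {
    stop("film Reynolds number is nonpositive; phase number undefined",
         call. = FALSE)
  }
  Ph <- (cond$d0 / cond$d) * (1 + 3 * log10(Re_film))
  structure(list(Re = Re, Re_film = Re_film, Ph = Ph, Ne_prime = NA_real_),
            class = "dimensionless_state")
}

#' @export
print.dimensionless_state <- function(x, ...) {
  cat(sprintf("Re = %.6g, Re_film = %.6g, Ph = %.4f", x$Re, x$Re_film, x$Ph))
  if (is.finite(x$Ne_prime)) cat(sprintf(", Ne' = %.4f", x$Ne_prime))
  cat("\n")
  invisible(x)
}

#' Modified Newton number correlation
#'
#' In-phase power-number correlation for unbaffled shake flasks,
#' \deqn{Ne' = 70\,Re^{-1} + 25\,Re^{-0.6} + 1.5\,Re^{-0.2},}
#' valid for in-phase operation (phase numbers above about 1.26).
#' Strictly decreasing in `Re`.
#'
#' @param Re Reynolds number (vectorized, all > 0).
#' @return Modified Newton number `Ne'` (dimensionless).
#' @export
newton_number <- function(Re) {
  if (any(!is.finite(Re)) || any(Re <= 0)) {
    stop("'Re' must be positive and finite", call. = FALSE)
  }
  70 * Re^-1 + 25 * Re^-0.6 + 1.5 * Re^-0.2
}

#' In-phase volumetric power input
#'
#' Volumetric power input from the modified-Newton-number correlation,
#' \deqn{P/V_L = Ne'(Re)\,\rho\,n^3 d^4\,V_L^{-2/3},}
#' where `Ne'` is defined through \eqn{Ne' = P/(\rho n^3 d^4 V_L^{1/3})}.
#' Valid for in-phase operation; see [power_input_corrected()] for the
#' out-of-phase corrected value.
#'
#' @inheritParams dimensionless_groups
#' @return Volumetric power input in W/m^3.
#' @examples
#' cond <- shaking_conditions(rpm_to_hz(250), d = 0.0813, d0 = 0.025,
#'                            VL = mL_to_m3(25))
#' power_input_inphase(cond, fluid_spec(rho = 1000, eta = 80e-3))
#' @export
power_input_inphase <- function(cond, fluid) {
  stopifnot(inherits(cond, "shaking_conditions"))
  eta <- .resolve_eta(fluid)
  Re <- fluid$rho * cond$n * cond$d^2 / eta
  newton_number(Re) * fluid$rho * cond$n^3 * cond$d^4 * cond$VL^(-2 / 3)
}

#' Out-of-phase correction model
#'
#' Exponential model of the ratio between the actual volumetric power
#' input and the in-phase correlation as a function of phase number,
#' \deqn{y(Ph) = 1 - a\,e^{-b\,Ph}.}
#' The default constants (a = 3.43, b = 2.02) were fitted to the
#' quotient of resolved two-phase simulations and the in-phase
#' correlation over a broad set of shaking conditions.
#'
#' @param a Amplitude (dimensionless, > 0).
#' @param b Decay rate per unit phase number (> 0).
#' @return An object of class `correction_model` with fields `a`, `b`
#'   and `valid_from = log(a)/b`, the phase number below which the
#'   model extrapolates to negative quotients.
#' @seealso [oophase_quotient()], [fit_correction()]
#' @export
correction_model <- function(a = 3.43, b = 2.02) {
  .check_positive(a, "a")
  .check_positive(b, "b")
  structure(list(a = a, b = b, valid_from = log(a) / b),
            class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf("Out-of-phase correction y = 1 - %.4g*exp(-%.4g*Ph)", x$a, x$b),
      sprintf("(nonnegative from Ph = %.4g)\n", x$valid_from))
  if (!is.null(attr(x, "residual_norm"))) {
    cat(sprintf("  fit residual norm: %.4g\n", attr(x, "residual_norm")))
  }
  invisible(x)
}

#' Out-of-phase power-input quotient
#'
#' Evaluates the correction model \eqn{y = 1 - a e^{-b Ph}}.  The raw
#' quotient turns negative below \eqn{Ph = \ln(a)/b} (about 0.61 for the
#' default constants), outside the range of the data behind the fit; a
#' clamped variant `max(y, 0)` is returned alongside together with a
#' flag marking clamped entries.
#'
#' @param Ph Phase number(s), > 0.
#' @param model A [correction_model()].
#' @return A list with `quotient` (raw), `clamped` (nonnegative) and
#'   `warning_flag` (logical, `TRUE` where clamping occurred).
#' @export
oophase_quotient <- function(Ph, model = correction_model()) {
  stopifnot(inherits(model, "correction_model"))
  if (any(!is.finite(Ph)) || any(Ph <= 0)) {
    stop("'Ph' must be positive and finite", call. = FALSE)
  }
  y <- 1 - model$a * exp(-model$b * Ph)
  list(quotient = y, clamped = pmax(y, 0), warning_flag = y < 0)
}

#' Classify in-phase versus out-of-phase operation
#'
#' Classifies the operating regime from the phase number using the two
#' published critical values: 1.26, above which operation is fully in
#' phase, and 0.91, below which the bulk liquid collapses.  The
#' transition between them is gradual; the band in between is labelled
#' `transition`.  Boundaries are inclusive on the in-phase side
#' (`Ph >= 1.26` is `in_phase`, `Ph >= 0.91` at least `transition`).
#'
#' @param Ph Phase number(s), > 0.
#' @return Character vector with levels `in_phase`, `transition`,
#'   `out_of_phase`; the thresholds are attached as attribute
#'   `thresholds`.
#' @export
classify_regime <- function(Ph) {
  if (any(!is.finite(Ph)) || any(Ph <= 0)) {
    stop("'Ph' must be positive and finite", call. = FALSE)
  }
  label <- ifelse(Ph >= 1.26, "in_phase",
                  ifelse(Ph >= 0.91, "transition", "out_of_phase"))
  attr(label, "thresholds") <- c(in_phase = 1.26, out_of_phase = 0.91)
  label
}

#' Out-of-phase corrected volumetric power input
#'
#' Multiplies the in-phase correlation value by the clamped
#' out-of-phase quotient evaluated at the operating point's phase
#' number.  Below the model's validity limit the corrected power input
#' is 0 and the report carries a warning flag.
#'
#' @inheritParams dimensionless_groups
#' @param model A [correction_model()].
#' @return A list with `P_per_V` (corrected, W/m^3), `P_per_V_inphase`
#'   (uncorrected), `quotient` (raw), `Ph`, `regime` and `warning_flag`.
#' @export
power_input_corrected <- function(cond, fluid, model = correction_model()) {
  groups <- dimensionless_groups(cond, fluid)
  raw <- power_input_inphase(cond, fluid)
  q <- oophase_quotient(groups$Ph, model)
  if (q$warning_flag) {
    warning(sprintf(paste0("phase number %.3f is below the correction ",
                           "model's validity limit %.3f; corrected power ",
                           "input clamped to 0"),
                    groups$Ph, model$valid_from), call. = FALSE)
  }
  list(P_per_V = raw * q$clamped,
       P_per_V_inphase = raw,
       quotient = q$quotient,
       Ph = groups$Ph,
       regime = as.character(classify_regime(groups$Ph)),
       warning_flag = q$warning_flag)
}

#' kLa correlation for shake flasks
#'
#' Gas-liquid volumetric mass transfer rate from the operating
#' conditions,
#' \deqn{k_La = 0.5\, d^{73/36}\, n\, d_0^{1/4}\, V_L^{-8/9}\,
#'   \nu^{-13/54}\, g^{-7/54}\, D_L^{1/2},}
#' the empirical shake-flask correlation fitted over a range of
#' viscosities.  The exponent set is dimensionless overall, so any
#' consistent unit system reproduces the SI value.
#'
#' @inheritParams dimensionless_groups
#' @param DL Diffusion coefficient of the transferred species (m^2/s);
#'   see [diffusion_coefficient()].
#' @return kLa in 1/s.
#' @export
kla_correlation <- function(cond, fluid, DL) {
  stopifnot(inherits(cond, "shaking_conditions"))
  eta <- .resolve_eta(fluid)
  .check_positive(DL, "DL")
  nu <- eta / fluid$rho
  0.5 * cond$d^(73 / 36) * cond$n * cond$d0^(1 / 4) * cond$VL^(-8 / 9) *
    nu^(-13 / 54) * cond$g^(-7 / 54) * DL^(1 / 2)
}

#' Effective shear rate for shear-thinning broths
#'
#' Representative (effective) shear rate in a shaken flask for a
#' power-law fluid,
#' \deqn{\gamma_{eff} = \left[2.06\,\frac{P/V_L}{K}
#'   \left(\frac{V_L^{1/3}}{d}\right)^{-0.33}\right]^{1/(m+1)},}
#' used to map a shear-thinning broth onto an equivalent Newtonian
#' viscosity via the power law.
#'
#' @param P_per_V Volumetric power input (W/m^3).
#' @param K Flow consistency index (Pa s^m).
#' @param m Flow behavior index (0 < m <= 1.5).
#' @param VL Filling volume (m^3).
#' @param d Largest inner flask diameter (m).
#' @return Effective shear rate in 1/s.
#' @export
effective_shear_giese <- function(P_per_V, K, m, VL, d) {
  .check_positive(P_per_V, "P_per_V")
  .check_positive(K, "K")
  .check_positive(VL, "VL")
  .check_positive(d, "d")
  if (!is.numeric(m) || m <= 0 || m > 1.5) {
    stop("'m' must lie in (0, 1.5]", call. = FALSE)
  }
  (2.06 * (P_per_V / K) * (VL^(1 / 3) / d)^(-0.33))^(1 / (m + 1))
}

#' Effective Newtonian viscosity of a power-law broth
#'
#' Self-consistent effective viscosity for a shear-thinning fluid in a
#' shaken flask: the loop viscosity -> Reynolds number -> modified
#' Newton number -> volumetric power input (optionally corrected for
#' out-of-phase operation) -> effective shear rate -> power-law
#' viscosity is iterated to a fixed point.
#'
#' @inheritParams dimensionless_groups
#' @param fluid A power-law [fluid_spec()].
#' @param use_correction Apply the out-of-phase correction inside the
#'   loop? Default `FALSE`: the effective-shear correlation was derived
#'   for in-phase operation.
#' @param model [correction_model()] used when `use_correction = TRUE`.
#' @param eta0 Initial viscosity guess (Pa s); defaults to `K`
#'   (the power-law viscosity at unit shear rate).
#' @param tol Relative convergence tolerance on the viscosity iterate.
#' @param max_iter Iteration cap.
#' @return A list with `eta_eff` (Pa s), `gamma_eff` (1/s), `P_per_V`
#'   (W/m^3, as used inside the loop), `Ph`, `Re`, `iterations` and
#'   `converged`.  On non-convergence the last iterate is returned with
#'   `converged = FALSE` and a warning.
#' @details Near `m = 1` the map is a mild contraction; if the iterate
#'   oscillates, under-relaxation with factor 0.5 is engaged.  With
#'   `m = 1` the fixed point is `eta_eff = K` exactly.
#' @examples
#' cond <- shaking_conditions(rpm_to_hz(250), d = 0.0813, d0 = 0.025,
#'                            VL = mL_to_m3(25))
#' pvp <- fluid_spec(rho = 1000, K = 0.104, m = 0.956)
#' effective_viscosity_fixed_point(cond, pvp)$eta_eff  # ~0.08 Pa.s
#' @export
effective_viscosity_fixed_point <- function(cond, fluid,
                                            use_correction = FALSE,
                                            model = correction_model(),
                                            eta0 = NULL,
                                            tol = 1e-10,
                                            max_iter = 500L) {
  stopifnot(inherits(cond, "shaking_conditions"))
  if (!inherits(fluid, "fluid_spec") || fluid$rheology != "power_law") {
    stop("'fluid' must carry power-law rheology (K, m)", call. = FALSE)
  }
  K <- fluid$K
  m <- fluid$m
  eta <- if (is.null(eta0)) K else eta0
  .check_positive(eta, "eta0")

  step <- function(eta) {
    newt <- fluid_spec(rho = fluid$rho, eta = eta)
    P_per_V <- power_input_inphase(cond, newt)
    Ph <- dimensionless_groups(cond, newt)$Ph
    if (use_correction) {
      P_per_V <- P_per_V * oophase_quotient(Ph, model)$clamped
      if (P_per_V <= 0) {
        stop("corrected power input clamped to 0 inside the viscosity loop; ",
             "condition is deeply out of phase and the effective-shear ",
             "correlation does not apply", call. = FALSE)
      }
    }
    gamma <- effective_shear_giese(P_per_V, K, m, cond$VL, cond$d)
    list(eta = K * gamma^(m - 1), gamma = gamma, P_per_V = P_per_V, Ph = Ph)
  }

  prev_delta <- 0
  it <- 0L
  repeat {
    it <- it + 1L
    s <- step(eta)
    delta <- s$eta - eta
    # under-relax only when successive updates change sign (oscillation)
    eta_new <- if (it > 1L && delta * prev_delta < 0) {
      eta + 0.5 * delta
    } else {
      s$eta
    }
    rel <- abs(eta_new - eta) / eta
    prev_delta <- delta
    eta <- eta_new
    if (rel < tol || it >= max_iter) break
  }
  converged <- rel < tol
  if (!converged) {
    warning(sprintf(paste0("viscosity fixed point not converged after %d ",
                           "iterations (last relative change %.3g); ",
                           "returning last iterate"), it, rel),
            call. = FALSE)
  }
  final <- step(eta)
  newt <- fluid_spec(rho = fluid$rho, eta = eta)
  list(eta_eff = eta,
       gamma_eff = final$gamma,
       P_per_V = final$P_per_V,
       Ph = dimensionless_groups(cond, newt)$Ph,
       Re = fluid$rho * cond$n * cond$d^2 / eta,
       iterations = it,
       converged = converged)
}

#' Fit the out-of-phase correction model
#'
#' Least-squares fit of \eqn{y = 1 - a e^{-b\,Ph}} to observed
#' power-input quotients (e.g. resolved-simulation over correlation
#' ratios) as a function of phase number.
#'
#' @param Ph Phase numbers (>= 3 distinct values).
#' @param quotient Observed quotients, same length.
#' @return A [correction_model()] with attributes `residual_norm` and
#'   `fit` (the underlying `nls` object).  If the data carry no decay
#'   signal (all quotients within `2e-3` of 1) the amplitude is
#'   reported as 0 and `b` as `NA` with a warning (unidentifiable).
#' @export
fit_correction <- function(Ph, quotient) {
  if (length(Ph) != length(quotient)) {
    stop("'Ph' and 'quotient' must have equal length", call. = FALSE)
  }
  keep <- is.finite(Ph) & is.finite(quotient)
  Ph <- Ph[keep]; quotient <- quotient[keep]
  if (length(unique(Ph)) < 3L) {
    stop("need at least 3 points with distinct phase numbers", call. = FALSE)
  }
  deficit <- 1 - quotient
  if (all(abs(deficit) < 2e-3)) {
    warning("all quotients are ~1; decay rate 'b' unidentifiable",
            call. = FALSE)
    out <- structure(list(a = 0, b = NA_real_, valid_from = NA_real_),
                     class = "correction_model")
    attr(out, "residual_norm") <- sqrt(sum(deficit^2))
    return(out)
  }
  # log-linear start values from points with a positive deficit
  pos <- deficit > 0
  start_fit <- stats::lm(log(deficit[pos]) ~ Ph[pos])
  b0 <- max(-unname(stats::coef(start_fit)[2]), 1e-3)
  a0 <- exp(unname(stats::coef(start_fit)[1]))
  fit <- minpack.lm::nlsLM(quotient ~ 1 - a * exp(-b * Ph),
                           start = list(a = a0, b = b0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  out <- correction_model(a = unname(est["a"]), b = unname(est["b"]))
  attr(out, "residual_norm") <- sqrt(sum(stats::residuals(fit)^2))
  attr(out, "fit") <- fit
  out
}
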