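#' Physical constants
#'
#' CODATA values of the Boltzmann and Avogadro constants used throughout
#' the diffusion-coefficient estimation.
#'
#' @format Named numeric vector with elements `kB` (J/K) and `NA_const`
#'   (1/mol).
#' @export
physical_constants <- c(kB = 1.380649e-23, NA_const = 6.02214076e23)

# Interface-unit conversions.  All internal computation is SI; the
# bench units (rpm, mm, mL, mPa.s, degC) are accepted only at the
# boundary, through these helpers and the tabular readers.

#' Convert bench units to SI
#'
#' Small converters for the units customary in shaken-bioreactor work.
#' All package computations are carried out in SI; these are applied once
#' at the interface layer.
#'
#' @param x Numeric vector in the bench unit.
#' @return Numeric vector in the SI unit.
#' @name bench-units
NULL

#' @rdname bench-units
#' @export
rpm_to_hz <- function(x) x / 60

#' @rdname bench-units
#' @export
mm_to_m <- function(x) x * 1e-3

#' @rdname bench-units
#' @export
mL_to_m3 <- function(x) x * 1e-6

#' @rdname bench-units
#' @export
mPas_to_Pas <- function(x) x * 1e-3

#' @rdname bench-units
#' @export
degC_to_K <- function(x) x + 273.15

.check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}
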