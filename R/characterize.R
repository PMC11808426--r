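#' Characterize shake-flask operating conditions
#'
#' Runs the full desk-scale characterization for each row of an
#' operating-condition table: dimensionless groups, regime label,
#' modified Newton number, volumetric power input (raw and corrected
#' for out-of-phase operation), kLa from the bench correlation, and —
#' for power-law fluids — the effective shear rate and effective
#' Newtonian viscosity from the self-consistent fixed point.
#'
#' @param conditions Data.frame in SI units as returned by
#'   [read_conditions()] (columns `n`, `d`, `d0`, `VL`, `rho`, `T`,
#'   `g`, and `eta` or `K` + `m`).
#' @param model [correction_model()] used for the corrected power
#'   input.
#' @param DL Diffusion coefficient (m^2/s) for the kLa correlation, or
#'   `NULL` to estimate it per row for oxygen in water at the row's
#'   temperature and (effective) viscosity via
#'   [diffusion_coefficient()].
#' @param use_correction_in_loop Apply the out-of-phase correction
#'   inside the effective-viscosity loop (default `FALSE`; the
#'   effective-shear correlation was derived for in-phase operation).
#' @return A data.frame with one row per condition: `Re`, `Re_film`,
#'   `Ph`, `regime`, `Ne_prime`, `P_per_V` (W/m^3), `P_per_V_corrected`
#'   (W/m^3), `quotient`, `kLa` (1/s), `DL` (m^2/s), `gamma_eff` (1/s,
#'   `NA` for Newtonian rows), `eta_eff_mPas` and an `error` column
#'   carrying per-row validation messages (`NA` elsewhere).  Rows that
#'   fail validation are reported, not fatal.
#' @examples
#' tab <- data.frame(n = rpm_to_hz(c(250, 450)), d = 0.0813, d0 = 0.025,
#'                   VL = mL_to_m3(15), rho = 1000, T = 293.15, g = 9.81,
#'                   eta = 16.7e-3)
#' characterize(tab)[, c("Ph", "regime")]
#' @export
characterize <- function(conditions, model = correction_model(), DL = NULL,
                         use_correction_in_loop = FALSE) {
  n_rows <- nrow(conditions)
  template <- data.frame(
    Re = NA_real_, Re_film = NA_real_, Ph = NA_real_,
    regime = NA_character_, Ne_prime = NA_real_,
    P_per_V = NA_real_, P_per_V_corrected = NA_real_, quotient = NA_real_,
    kLa = NA_real_, DL = NA_real_,
    gamma_eff = NA_real_, eta_eff_mPas = NA_real_,
    error = NA_character_, stringsAsFactors = FALSE)
  out <- template[rep(1L, n_rows), , drop = FALSE]
  rownames(out) <- NULL
  if (n_rows == 0L) return(out)

  for (i in seq_len(n_rows)) {
    row <- conditions[i, ]
    res <- tryCatch({
      cond <- shaking_conditions(n = row$n, d = row$d, d0 = row$d0,
                                 VL = row$VL, T = row$T, g = row$g)
      has_eta <- !is.null(row[["eta"]]) && !is.na(row[["eta"]])
      if (has_eta) {
        fluid <- fluid_spec(rho = row$rho, eta = row[["eta"]])
        gamma_eff <- NA_real_
        eta_eff <- row[["eta"]]
      } else {
        pl <- fluid_spec(rho = row$rho, K = row[["K"]], m = row[["m"]])
        fp <- effective_viscosity_fixed_point(
          cond, pl, use_correction = use_correction_in_loop, model = model)
        fluid <- fluid_spec(rho = row$rho, eta = fp$eta_eff)
        gamma_eff <- fp$gamma_eff
        eta_eff <- fp$eta_eff
      }
      groups <- dimensionless_groups(cond, fluid)
      Ne <- newton_number(groups$Re)
      raw <- power_input_inphase(cond, fluid)
      q <- oophase_quotient(groups$Ph, model)
      DL_i <- if (is.null(DL)) {
        diffusion_coefficient(gmol_to_kgmol(32), gmol_to_kgmol(18),
                              T = cond$T, eta = fluid$eta)
      } else DL
      data.frame(
        Re = groups$Re, Re_film = groups$Re_film, Ph = groups$Ph,
        regime = as.character(classify_regime(groups$Ph)), Ne_prime = Ne,
        P_per_V = raw, P_per_V_corrected = raw * q$clamped,
        quotient = q$quotient,
        kLa = kla_correlation(cond, fluid, DL_i), DL = DL_i,
        gamma_eff = gamma_eff, eta_eff_mPas = eta_eff * 1e3,
        error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      bad <- template
      bad$error <- conditionMessage(e)
      bad
    })
    out[i, ] <- res
  }
  out
}

#' Write a characterization report
#'
#' Writes the [characterize()] output next to its inputs as a
#' tab-delimited table, preceded by comment lines recording the
#' defaults and model constants so the report is reproducible from its
#' own metadata.
#'
#' @param report Data.frame from [characterize()].
#' @param path Output file.
#' @param conditions The input condition table (echoed into the
#'   report's columns).
#' @param model The [correction_model()] used.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, conditions = NULL,
                         model = correction_model()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# shakeflask characterization report (%s)",
            format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("# correction model: y = 1 - %.6g*exp(-%.6g*Ph)",
            model$a, model$b),
    "# film Reynolds number uses the squared outer bracket",
    "# regime thresholds: in_phase Ph >= 1.26, out_of_phase Ph < 0.91",
    "# all quantities SI unless suffixed otherwise"), con)
  full <- if (is.null(conditions)) report else cbind(conditions, report)
  utils::write.table(full, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
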