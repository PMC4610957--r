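# mathematical lower bound of the energy map's domain: at t_d = ln2*e the
# inner logarithm is -1 and the energy is exactly 0
T_D_MATH_FLOOR <- log(2) * exp(1)

#' Per-cell growth energy of a doubling time (DT-EC map)
#'
#' Converts a doubling time into the growth energy of a single cell:
#' \deqn{E_G = \ln[(\ln(\ln 2 / t_D))^2] \ \mathrm{Emad}.}
#' The inner logarithm is squared before the outer logarithm is taken; for
#' every biological doubling time \eqn{\ln(\ln 2 / t_D) < 0}, so this is the
#' only real-valued reading. The map is strictly increasing in \eqn{t_D} on
#' its domain.
#'
#' Doubling times below \eqn{\ln 2 \cdot e \approx 1.88} s are rejected
#' (the energy would be negative and the inverse branch ill-defined);
#' values above that bound but below \code{floor} (default one hour) are
#' biologically implausible and emit a warning.
#'
#' @param t_d Doubling time in seconds.
#' @param floor Plausibility floor in seconds (default 3600).
#' @return Growth energy in Emad.
#' @examples
#' growth_energy(log(2) * exp(exp(1)))  # exactly 2
#' growth_energy(590466.43)             # ~5.228 Emad (doubling in ~6.8 d)
#' @export
growth_energy <- function(t_d, floor = 3600) {
  stopifnot(is.numeric(t_d))
  if (any(!is.finite(t_d)) || any(t_d < T_D_MATH_FLOOR))
    stop(sprintf("t_d must be >= ln2*e (= %.4g) seconds; energy undefined below",
                 T_D_MATH_FLOOR))
  if (any(t_d < floor))
    warning(sprintf("t_d below the %g-second plausibility floor", floor))
  log((log(LN2 / t_d))^2)
}

#' Doubling time corresponding to a growth energy
#'
#' Inverse of \code{\link{growth_energy}} on the biological branch
#' (\eqn{\ln(\ln 2 / t_D) < 0}, i.e. \eqn{t_D > \ln 2 \cdot e}):
#' \deqn{t_D = \ln 2 \cdot \exp(+\sqrt{\exp(E_G)}).}
#'
#' @param e_g Growth energy in Emad (finite).
#' @return Doubling time in seconds.
#' @export
energy_to_doubling_time <- function(e_g) {
  stopifnot(is.numeric(e_g))
  if (any(!is.finite(e_g))) stop("e_g must be finite")
  LN2 * exp(sqrt(exp(e_g)))
}

#' Convert Emad to MeV
#'
#' Multiplies by the conversion factor 23234.59 MeV per Emad.
#' @param e Energy in Emad.
#' @return Energy in MeV.
#' @examples
#' emad_to_mev(1)  # 23234.59
#' @export
emad_to_mev <- function(e) e * MEV_PER_EMAD

#' Convert MeV to Emad
#' @param e Energy in MeV.
#' @return Energy in Emad.
#' @export
mev_to_emad <- function(e) e / MEV_PER_EMAD

#' Histologic-grade (total tumor) energy
#'
#' The tumor's total growth energy: per-cell growth energy times the
#' inoculated (hypoxic) cell count \eqn{C_0 \times h}, reported in Emad and
#' in MeV.
#'
#' @param t_d Doubling time in seconds.
#' @param inoculum Cell count \eqn{C_0 \times h}, >= 1.
#' @param floor Passed to \code{\link{growth_energy}}.
#' @return An object of class \code{energy_result} with fields
#'   \code{e_per_cell} (Emad), \code{hg_emad}, \code{hg_mev},
#'   \code{inoculum}.
#' @export
histologic_grade <- function(t_d, inoculum, floor = 3600) {
  if (!is.numeric(inoculum) || inoculum < 1) stop("inoculum must be >= 1")
  e <- growth_energy(t_d, floor = floor)
  structure(list(e_per_cell = e,
                 hg_emad = e * inoculum,
                 hg_mev = emad_to_mev(e * inoculum),
                 inoculum = inoculum),
            class = "energy_result")
}

#' @export
print.energy_result <- function(x, ...) {
  cat(sprintf("<energy_result> %.4f Emad/cell x %g cells = %.6g Emad (%.6g MeV)\n",
              x$e_per_cell, x$inoculum, x$hg_emad, x$hg_mev))
  invisible(x)
}

#' Energy yield of a regimen (dose energy)
#'
#' The energy imparted to the tumor by the regimen: the difference between
#' the treated and control arms' per-cell growth energies, scaled by the
#' inoculum,
#' \deqn{E_{Dose} = [E_G^{Treated} - E_G^{Control}] \times C_0 h,}
#' in Emad, with the MeV value as a presentation conversion. Each arm's
#' doubling time comes from \code{\link{effective_kinetics}}, so shrinking
#' (treated) arms are virtualized first. Slower treated growth gives a
#' positive yield; negative values (treated grew faster) are allowed.
#'
#' @param record A \code{\link{treatment_record}}.
#' @param strategy Virtualization strategy.
#' @return An object of class \code{dose_energy} with fields
#'   \code{e_dose_emad}, \code{e_dose_mev}, \code{treated_e_per_cell},
#'   \code{control_e_per_cell}, \code{treated_t_d}, \code{control_t_d},
#'   \code{virtual_used}, \code{strategy}.
#' @examples
#' rec <- dtec_table1()[[8]]
#' dose_energy(rec)  # ~1.47e5 Emad for the A549 model
#' @export
dose_energy <- function(record, strategy = virtual_strategies) {
  stopifnot(inherits(record, "treatment_record"))
  strategy <- match.arg(strategy)
  wrap <- function(expr, arm) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("record %d, %s arm: %s", record$treatment_id, arm,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  kc <- wrap(effective_kinetics(record$control, strategy), "control")
  kt <- wrap(effective_kinetics(record$treated, strategy), "treated")
  ec <- wrap(growth_energy(kc$t_d), "control")
  et <- wrap(growth_energy(kt$t_d), "treated")
  de <- (et - ec) * record$inoculum
  structure(list(e_dose_emad = de,
                 e_dose_mev = emad_to_mev(de),
                 treated_e_per_cell = et,
                 control_e_per_cell = ec,
                 treated_t_d = kt$t_d,
                 control_t_d = kc$t_d,
                 virtual_used = kc$virtual || kt$virtual,
                 strategy = strategy),
            class = "dose_energy")
}

#' @export
print.dose_energy <- function(x, ...) {
  cat(sprintf("<dose_energy> %.6g Emad (%.6g MeV)%s\n",
              x$e_dose_emad, x$e_dose_mev,
              if (isTRUE(x$virtual_used)) " [virtual growth used]" else ""))
  invisible(x)
}
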