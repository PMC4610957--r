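# run expr with a local RNG state seeded from `seed`, restoring any global
# state afterwards; keeps all randomness tied to the explicit seed
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate an exponential tumor-volume trajectory
#'
#' Renders one phase of exact exponential growth (or shrinkage, for a
#' negative timescale) with optional multiplicative lognormal measurement
#' noise on the endpoint volume: \eqn{v_{end} = v_0 \cdot 2^{\pm d/|t|}
#' \cdot e^{\epsilon}}, \eqn{\epsilon \sim N(0, \sigma^2)}. Deterministic
#' when \code{noise_sigma = 0}.
#'
#' @param t_d_or_t_half Signed timescale in seconds: positive = doubling
#'   time, negative = minus the half-life (shrinkage).
#' @param v0 Start volume in cm^3.
#' @param duration Phase duration in seconds.
#' @param noise_sigma Lognormal sigma of the endpoint volume (>= 0).
#' @param seed Mandatory when \code{noise_sigma > 0}.
#' @param arm Arm label for the trajectory.
#' @return A single-phase \code{\link{trajectory}}.
#' @examples
#' simulate_trajectory(7 * 86400, 0.1, 14 * 86400)  # two doublings -> 0.4
#' @export
simulate_trajectory <- function(t_d_or_t_half, v0, duration, noise_sigma = 0,
                                seed = NULL, arm = c("control", "treated")) {
  arm <- match.arg(arm)
  stopifnot(is.numeric(t_d_or_t_half), t_d_or_t_half != 0,
            is.numeric(v0), v0 > 0, is.numeric(duration), duration > 0,
            is.numeric(noise_sigma), noise_sigma >= 0)
  v_end <- v0 * 2^(duration / t_d_or_t_half)
  if (noise_sigma > 0) {
    if (is.null(seed)) stop("seed is mandatory when noise_sigma > 0")
    v_end <- v_end * with_local_seed(seed, exp(stats::rnorm(1, 0, noise_sigma)))
  }
  trajectory(list(volume_phase(v0, v_end, duration)), arm = arm)
}

#' Configuration for a synthetic cohort
#'
#' Defaults mirror the scale of the packaged dose-840 treatments: control
#' doubling time 7 days, inoculum 1e6 cells, a 24.5-day observation window,
#' doses spanning 100-2000 ug/ml and an energy yield of 175 Emad per ug/ml
#' through the origin.
#'
#' @param n_records Number of records (>= 1).
#' @param control_t_d Control doubling time(s) in seconds (recycled).
#' @param inoculum Cell count C0 x h.
#' @param dose_grid Doses in ug/ml (recycled to \code{n_records}).
#' @param true_slope Generating slope, Emad per ug/ml.
#' @param true_intercept Generating intercept, Emad.
#' @param noise_sigma Lognormal sigma of endpoint volumes (>= 0).
#' @param observation_span Observation window in seconds.
#' @param v0 Start volume in cm^3 for both arms.
#' @param seed Integer seed; mandatory.
#' @return A validated \code{cohort_config} list.
#' @export
cohort_config <- function(n_records = 20,
                          control_t_d = 7 * SECONDS_PER_DAY,
                          inoculum = 1e6,
                          dose_grid = seq(100, 2000, length.out = n_records),
                          true_slope = 175,
                          true_intercept = 0,
                          noise_sigma = 0,
                          observation_span = 24.5 * SECONDS_PER_DAY,
                          v0 = 0.1,
                          seed) {
  if (missing(seed) || !is.numeric(seed)) stop("an integer seed is mandatory")
  stopifnot(n_records >= 1, all(control_t_d > 0), inoculum >= 1,
            all(dose_grid > 0), noise_sigma >= 0, observation_span > 0, v0 > 0)
  structure(list(n_records = as.integer(n_records),
                 control_t_d = control_t_d, inoculum = inoculum,
                 dose_grid = dose_grid, true_slope = true_slope,
                 true_intercept = true_intercept, noise_sigma = noise_sigma,
                 observation_span = observation_span, v0 = v0,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a ground-truthed treatment cohort
#'
#' Generates treatment records whose energy yields follow a known linear
#' dose-energy law: for each dose d the latent yield is
#' \eqn{E = slope \cdot d + intercept}; the treated arm's per-cell energy
#' is the control energy plus \eqn{E / C_0 h}, and its doubling time comes
#' from the inverse DT-EC map. Both arms are rendered as endpoint
#' trajectories, with multiplicative lognormal noise on the endpoint
#' volumes when \code{noise_sigma > 0}. With \code{noise_sigma = 0} the
#' analysis pipeline recovers the generating parameters exactly.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return List with \code{records} (list of \code{treatment_record},
#'   \code{regimen_text} empty) and \code{truth} (the generating
#'   parameters plus per-record latent \code{e_dose}, \code{control_t_d},
#'   \code{treated_t_d}).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_records
  doses <- rep_len(config$dose_grid, n)
  tds <- rep_len(config$control_t_d, n)
  with_local_seed(config$seed, {
    records <- vector("list", n)
    truth_rows <- vector("list", n)
    for (i in seq_len(n)) {
      e_dose <- config$true_slope * doses[i] + config$true_intercept
      e_control <- growth_energy(tds[i])
      e_treated <- e_control + e_dose / config$inoculum
      t_d_treated <- energy_to_doubling_time(e_treated)
      if (!is.finite(t_d_treated))
        stop(sprintf("dose %g drives the treated energy outside the invertible domain",
                     doses[i]))
      span <- config$observation_span
      noisy_end <- function(t_d) {
        v <- config$v0 * 2^(span / t_d)
        if (config$noise_sigma > 0)
          v <- v * exp(stats::rnorm(1, 0, config$noise_sigma))
        v
      }
      control <- trajectory(list(volume_phase(config$v0, noisy_end(tds[i]), span)),
                            arm = "control")
      treated <- trajectory(list(volume_phase(config$v0, noisy_end(t_d_treated), span)),
                            arm = "treated")
      records[[i]] <- treatment_record(
        treatment_id = i, study_label = "synthetic",
        cell_line = sprintf("synthetic-%02d", i),
        inoculum = config$inoculum, dose_ug_per_ml = doses[i],
        regimen_text = "", control = control, treated = treated)
      truth_rows[[i]] <- data.frame(treatment_id = i, dose_ug_per_ml = doses[i],
                                    e_dose = e_dose, control_t_d = tds[i],
                                    treated_t_d = t_d_treated)
    }
    list(records = records,
         truth = list(true_slope = config$true_slope,
                      true_intercept = config$true_intercept,
                      noise_sigma = config$noise_sigma,
                      seed = config$seed,
                      per_record = do.call(rbind, truth_rows)))
  })
}

#' Write a simulated cohort in the treatment-table CSV schema
#'
#' @param cohort Output of \code{\link{simulate_cohort}}.
#' @param path CSV path for the records.
#' @param truth_path Optional JSON path for the ground-truth sidecar.
#' @return Invisibly, \code{path}.
#' @export
write_cohort <- function(cohort, path, truth_path = NULL) {
  rows <- lapply(cohort$records, function(r) {
    data.frame(treatment_id = r$treatment_id, study_label = r$study_label,
               cell_line = r$cell_line, inoculum = r$inoculum,
               dose_ug_per_ml = r$dose_ug_per_ml, regimen_text = r$regimen_text,
               control_phases = format_phase_string(r$control),
               treated_phases = format_phase_string(r$treated))
  })
  df <- do.call(rbind, rows)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  if (!is.null(truth_path))
    jsonlite::write_json(cohort$truth, truth_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(path)
}
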