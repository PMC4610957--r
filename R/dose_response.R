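#' Cluster near-identical dose-energy values
#'
#' Single-linkage grouping under a relative tolerance: two values are
#' linked when \eqn{|a-b| / \max(|a|,|b|) \le} \code{rel_tol}, and clusters
#' are the connected components of the link graph (so chains merge).
#' Used to find regimens with "identical" therapeutic effect.
#'
#' @param e_doses Named numeric vector (names are ids), or a list of
#'   \code{(id, value)} pairs; non-empty.
#' @param rel_tol Relative tolerance in (0, 0.5); default 0.05.
#' @return List of clusters, each a named numeric vector, sorted by size
#'   (then by value) descending.
#' @examples
#' cluster_identical(c(a = 1.0, b = 1.04, c = 2.0))
#' @export
cluster_identical <- function(e_doses, rel_tol = 0.05) {
  if (is.list(e_doses)) {
    vals <- vapply(e_doses, function(p) as.numeric(p[[2]]), numeric(1))
    names(vals) <- vapply(e_doses, function(p) as.character(p[[1]]), character(1))
    e_doses <- vals
  }
  stopifnot(is.numeric(e_doses), length(e_doses) >= 1L)
  if (!is.numeric(rel_tol) || rel_tol <= 0 || rel_tol >= 0.5)
    stop("rel_tol must lie in (0, 0.5)")
  if (is.null(names(e_doses))) names(e_doses) <- seq_along(e_doses)
  n <- length(e_doses)
  linked <- function(a, b) {
    m <- max(abs(a), abs(b))
    if (m == 0) TRUE else abs(a - b) / m <= rel_tol
  }
  # connected components by breadth-first search over the pairwise relation
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    comp[i] <- cid
    while (length(queue) > 0L) {
      u <- queue[[1L]]; queue <- queue[-1L]
      for (v in seq_len(n)) {
        if (is.na(comp[v]) && linked(e_doses[u], e_doses[v])) {
          comp[v] <- cid
          queue <- c(queue, v)
        }
      }
    }
  }
  clusters <- split(e_doses, comp)
  ord <- order(-vapply(clusters, length, integer(1)),
               -vapply(clusters, max, numeric(1)))
  unname(clusters[ord])
}

#' Fit the linear dose-energy model
#'
#' Ordinary least squares of the regimen energy yield (Emad) on the dose
#' (ug/ml), with or without an intercept, plus the Pearson correlation of
#' the raw pairs. Two-point fits are flagged as underdetermined (r is
#' +/- 1 by construction).
#'
#' @param points Data.frame or matrix with columns dose (ug/ml) and
#'   e_dose (Emad), or a list of pairs; n >= 2, doses not all equal.
#' @param through_origin Force a zero intercept (default FALSE).
#' @return An object of class \code{dose_energy_model}: \code{slope}
#'   (Emad per ug/ml), \code{intercept} (Emad), \code{pearson_r},
#'   \code{r_squared}, \code{n}, \code{through_origin},
#'   \code{underdetermined}, and the underlying \code{lm} fit.
#' @export
fit_dose_energy <- function(points, through_origin = FALSE) {
  if (is.list(points) && !is.data.frame(points))
    points <- do.call(rbind, lapply(points, function(p)
      data.frame(dose = p[[1]], e_dose = p[[2]])))
  points <- as.data.frame(points)
  names(points)[1:2] <- c("dose", "e_dose")
  if (nrow(points) < 2L) stop("need at least two (dose, energy) points")
  if (length(unique(points$dose)) < 2L && !through_origin)
    stop("degenerate design: all doses equal")
  fit <- if (through_origin) stats::lm(e_dose ~ 0 + dose, data = points)
         else stats::lm(e_dose ~ dose, data = points)
  cf <- stats::coef(fit)
  r <- if (length(unique(points$dose)) < 2L ||
           length(unique(points$e_dose)) < 2L) NA_real_
       else stats::cor(points$dose, points$e_dose)
  structure(list(slope = unname(cf[["dose"]]),
                 intercept = if (through_origin) 0 else unname(cf[["(Intercept)"]]),
                 pearson_r = r,
                 r_squared = if (through_origin)
                   suppressWarnings(summary(fit)$r.squared) else r^2,
                 n = nrow(points),
                 through_origin = through_origin,
                 underdetermined = nrow(points) == 2L && !through_origin,
                 fit = fit),
            class = "dose_energy_model")
}

#' @export
print.dose_energy_model <- function(x, ...) {
  cat(sprintf("<dose_energy_model> E = %.6g * dose %s %.6g  (n=%d, r=%.4f, R2=%.4f)%s\n",
              x$slope, if (x$intercept < 0) "-" else "+", abs(x$intercept),
              x$n, x$pearson_r, x$r_squared,
              if (isTRUE(x$underdetermined)) " [underdetermined]" else ""))
  invisible(x)
}

#' Predict a doubling time at a model value
#' @param model A \code{\link{dose_energy_model}}.
#' @param dose Dose in ug/ml.
#' @return Predicted energy yield in Emad.
#' @export
predict_e_dose <- function(model, dose) {
  stopifnot(inherits(model, "dose_energy_model"))
  model$slope * dose + model$intercept
}

#' Predict the treated doubling time from a proposed dose
#'
#' Inverts the energy bookkeeping: the model gives the energy yield of the
#' proposed dose, which raises the control arm's per-cell growth energy;
#' the inverse DT-EC map then returns the predicted treated doubling time
#' and, optionally, the volume fold-change over a horizon.
#'
#' @param model A \code{\link{dose_energy_model}}.
#' @param control_t_d Control (pre-therapy) doubling time in seconds.
#' @param inoculum Cell count C0 x h.
#' @param dose Proposed dose in ug/ml.
#' @param horizon Optional horizon in seconds for the fold-change.
#' @return List with \code{e_dose_emad}, \code{treated_e_per_cell},
#'   \code{predicted_t_d} (s) and, when \code{horizon} is given,
#'   \code{fold_change} = \eqn{2^{h / t_D}}.
#' @export
predict_response <- function(model, control_t_d, inoculum, dose,
                             horizon = NULL) {
  stopifnot(inherits(model, "dose_energy_model"))
  if (!is.numeric(inoculum) || inoculum < 1) stop("inoculum must be >= 1")
  e_dose <- predict_e_dose(model, dose)
  e_treated <- growth_energy(control_t_d) + e_dose / inoculum
  t_d <- energy_to_doubling_time(e_treated)
  if (!is.finite(t_d))
    stop("response exceeds model domain: predicted energy is not invertible")
  out <- list(e_dose_emad = e_dose,
              treated_e_per_cell = e_treated,
              predicted_t_d = t_d)
  if (!is.null(horizon)) out$fold_change <- 2^(horizon / t_d)
  out
}

#' Audit the dose column against the regimen text
#'
#' The tabulated dose (ug/ml) tracks the cumulative administered dose: in
#' the packaged table it equals 28 x (dose per injection x nominal dose
#' count) for 13 of the 14 rows. This is an empirical regularity of the
#' transcribed table, checked at warning level only; it never alters
#' analysis values. Rows off by more than \code{rel_tol} are flagged.
#'
#' @param record A \code{\link{treatment_record}}.
#' @param spec A \code{\link{regimen_spec}} parsed from the record's
#'   regimen text.
#' @param factor Expected ug/ml per cumulative mg/kg (default 28).
#' @param rel_tol Relative tolerance (default 0.005).
#' @return List: \code{treatment_id}, \code{cumulative_mg_kg},
#'   \code{expected_ug_per_ml}, \code{tabulated_ug_per_ml},
#'   \code{rel_error}, \code{consistent}.
#' @export
audit_dose_column <- function(record, spec, factor = 28, rel_tol = 0.005) {
  stopifnot(inherits(record, "treatment_record"), inherits(spec, "regimen_spec"))
  cumulative <- spec$dose_per_injection * spec$n_doses_nominal
  expected <- factor * cumulative
  rel <- abs(record$dose_ug_per_ml - expected) / expected
  list(treatment_id = record$treatment_id,
       cumulative_mg_kg = cumulative,
       expected_ug_per_ml = expected,
       tabulated_ug_per_ml = record$dose_ug_per_ml,
       rel_error = rel,
       consistent = rel <= rel_tol)
}
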