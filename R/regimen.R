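criterion_modes <- c("to_next_dose", "from_start")

#' Regimen-efficiency profile
#'
#' For a cell-cycle-specific agent an efficient schedule must keep the
#' induced intraday doubling time ahead of the dosing clock: at each dose
#' delivery the treated tumor's \code{\link{t_d_intraday}} is compared with
#' a time interval. Two readings of the comparison interval are exposed:
#' \describe{
#'   \item{to_next_dose (default)}{the period from therapy start to the
#'     next dose delivery (the last dose compares to the observation end).}
#'   \item{from_start}{the period from therapy start to this dose
#'     delivery.}
#' }
#' A dose is efficient when \eqn{t_D^{intraday} \ge} the interval (boundary
#' equality counts). A dose at t = 0 has \eqn{t_D^{intraday} = 0} by
#' linearity and is reported as not evaluable rather than inefficient.
#'
#' @param record A \code{\link{treatment_record}}; the treated arm is used.
#' @param spec A \code{\link{regimen_spec}}; injections after the treated
#'   observation span are dropped with a warning.
#' @param mode Comparison-interval mode.
#' @param strategy Virtualization strategy for shrinking treated arms.
#' @return An object of class \code{efficiency_assessment}: a \code{per_dose}
#'   data.frame (dose_time_s, t_d_intraday_s, comparison_interval_s,
#'   efficient), a \code{verdict} in \{efficient, inefficient, mixed,
#'   not_evaluable\}, and the \code{criterion_mode}.
#' @examples
#' rec <- dtec_table1()[[11]]
#' spec <- parse_regimen(rec$regimen_text)
#' efficiency_profile(rec, spec)
#' @export
efficiency_profile <- function(record, spec, mode = criterion_modes,
                               strategy = virtual_strategies) {
  stopifnot(inherits(record, "treatment_record"), inherits(spec, "regimen_spec"))
  mode <- match.arg(mode)
  strategy <- match.arg(strategy)
  span <- total_duration(record$treated)
  times <- spec$injection_times
  if (length(times) == 0L) stop("empty injection list")
  late <- times > span
  if (any(late)) {
    warning(sprintf("record %d: %d injection(s) after the observation span dropped",
                    record$treatment_id, sum(late)))
    times <- times[!late]
    if (length(times) == 0L)
      stop("no injections within the treated observation span")
  }
  n <- length(times)
  td <- vapply(times, function(t) {
    if (t == 0) 0 else t_d_intraday(record$treated, t, strategy)
  }, numeric(1))
  interval <- vapply(seq_len(n), function(k) {
    if (mode == "from_start") times[k]
    else if (k < n) times[k + 1L] else span
  }, numeric(1))
  efficient <- ifelse(times == 0, NA, td >= interval)
  evaluable <- efficient[!is.na(efficient)]
  verdict <- if (length(evaluable) == 0L) "not_evaluable"
    else if (all(evaluable)) "efficient"
    else if (!any(evaluable)) "inefficient"
    else "mixed"
  structure(list(per_dose = data.frame(dose_time_s = times,
                                       t_d_intraday_s = td,
                                       comparison_interval_s = interval,
                                       efficient = efficient),
                 verdict = verdict,
                 criterion_mode = mode,
                 strategy = strategy),
            class = "efficiency_assessment")
}

#' @export
print.efficiency_assessment <- function(x, ...) {
  cat(sprintf("<efficiency_assessment> mode=%s, verdict=%s\n",
              x$criterion_mode, x$verdict))
  df <- x$per_dose
  df[1:3] <- lapply(df[1:3], function(v) round(v / SECONDS_PER_DAY, 3))
  names(df)[1:3] <- c("dose_day", "t_d_intraday_d", "interval_d")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Is the intraday doubling time steadily increasing across doses?
#'
#' TRUE iff \code{\link{t_d_intraday}} evaluated at successive dose times is
#' strictly increasing. With the default whole-trajectory endpoints the
#' intraday doubling time is linear in t and the check always passes; with
#' \code{scope = "phase"} each dose is evaluated against the endpoints of
#' the phase containing it, so accelerating regrowth can fail the check.
#'
#' @param record A \code{\link{treatment_record}}.
#' @param spec A \code{\link{regimen_spec}} with >= 2 injection times.
#' @param scope Passed to \code{\link{t_d_intraday}}.
#' @param strategy Virtualization strategy.
#' @return Logical flag.
#' @export
steadiness_check <- function(record, spec, scope = c("whole", "phase"),
                             strategy = virtual_strategies) {
  stopifnot(inherits(record, "treatment_record"), inherits(spec, "regimen_spec"))
  scope <- match.arg(scope)
  strategy <- match.arg(strategy)
  span <- total_duration(record$treated)
  times <- spec$injection_times
  times <- times[times > 0 & times <= span]
  if (length(times) < 2L) stop("need at least two evaluable dose times")
  td <- vapply(times, function(t)
    t_d_intraday(record$treated, t, strategy, scope = scope), numeric(1))
  all(diff(td) > 0)
}

#' Classify a schedule as metronomic or standard
#'
#' Metronomic schedules deliver small doses at short intervals: the
#' schedule is metronomic iff the median inter-dose gap is at most
#' \code{gap_max_days} and the per-injection dose at most
#' \code{dose_max_mg_kg}; anything else (including single-injection
#' schedules, which have no gap) is standard.
#'
#' @param spec A \code{\link{regimen_spec}}.
#' @param gap_max_days Maximum median gap in days (default 3.5).
#' @param dose_max_mg_kg Maximum per-injection dose in mg/kg (default 1).
#' @return \code{"metronomic"} or \code{"standard"}.
#' @export
classify_schedule <- function(spec, gap_max_days = 3.5, dose_max_mg_kg = 1) {
  stopifnot(inherits(spec, "regimen_spec"))
  if (length(spec$injection_times) < 2L) return("standard")
  gap <- stats::median(diff(spec$injection_times)) / SECONDS_PER_DAY
  if (gap <= gap_max_days && spec$dose_per_injection <= dose_max_mg_kg)
    "metronomic" else "standard"
}
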