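LN2 <- log(2)

virtual_strategies <- c("half_life_equivalence", "reflection", "literal")

#' Signed exponential rate constant of a phase
#'
#' The net mitosis-minus-apoptosis rate per cell under the exponential
#' model: \eqn{(\ln v_{end} - \ln v_{start}) / duration}. Positive for
#' growth, negative for shrinkage. Static phases are rejected (the doubling
#' time would be infinite and the energy map undefined).
#'
#' @param phase A \code{\link{volume_phase}}.
#' @return Rate constant in 1/s.
#' @export
rate_constant <- function(phase) {
  stopifnot(inherits(phase, "volume_phase"))
  if (phase$direction == "static")
    stop("static phase: rate is zero and doubling time infinite (degenerate input)")
  (log(phase$v_end) - log(phase$v_start)) / phase$duration
}

#' Doubling time of a growing phase
#'
#' \eqn{t_D = \ln 2 \cdot duration / (\ln v_{end} - \ln v_{start})}, in
#' seconds. Shrinking phases must be virtualized first (see
#' \code{\link{virtualize}}); use \code{\link{half_life}} for their decay
#' timescale.
#'
#' @param phase A growing \code{\link{volume_phase}}.
#' @return Doubling time in seconds.
#' @export
doubling_time <- function(phase) {
  stopifnot(inherits(phase, "volume_phase"))
  if (phase$direction != "grow")
    stop("doubling_time requires a growing phase; virtualize() shrink phases first")
  LN2 * phase$duration / (log(phase$v_end) - log(phase$v_start))
}

#' Half-life of a shrinking phase
#'
#' \eqn{t_{1/2} = \ln 2 \cdot duration / (\ln v_{start} - \ln v_{end})}, in
#' seconds.
#'
#' @param phase A shrinking \code{\link{volume_phase}}.
#' @return Half-life in seconds.
#' @export
half_life <- function(phase) {
  stopifnot(inherits(phase, "volume_phase"))
  if (phase$direction != "shrink") stop("half_life requires a shrinking phase")
  LN2 * phase$duration / (log(phase$v_start) - log(phase$v_end))
}

#' Replace a shrinking phase by an equivalent virtual-growth phase
#'
#' Shrinking tumors have no doubling time, so the energy map does not apply
#' directly; the apoptotic portion is replaced by a virtual growth portion
#' over the same duration. Three readings of the equivalence are available:
#' \describe{
#'   \item{half_life_equivalence (default)}{\eqn{v'_{end} = v_{start}^2 /
#'     v_{end}}: the virtual doubling time equals the shrink half-life
#'     exactly (the log-volume change is mirrored).}
#'   \item{reflection}{\eqn{v'_{end} = 2 v_{start} - v_{end}}: the absolute
#'     volume loss is mirrored.}
#'   \item{literal}{\eqn{v'_{end} = v_{start} + v_{start}^2 / (v_{start} -
#'     v_{end})}: the shrink fraction equals the ratio of the initial volume
#'     to the virtual gain.}
#' }
#' Growing phases are returned unchanged with a notice.
#'
#' @param phase A \code{\link{volume_phase}}.
#' @param strategy Virtualization strategy.
#' @return A growing \code{volume_phase} with the same \code{v_start} and
#'   \code{duration}.
#' @examples
#' p <- volume_phase(0.4, 0.02, 85 * 86400)
#' virtualize(p)  # v_end 8.0, virtual doubling time == half-life
#' @export
virtualize <- function(phase, strategy = virtual_strategies) {
  stopifnot(inherits(phase, "volume_phase"))
  strategy <- match.arg(strategy)
  if (phase$direction == "grow") {
    message("phase already grows; returned unchanged")
    return(phase)
  }
  if (phase$direction == "static")
    stop("static phase cannot be virtualized (degenerate input)")
  v_end <- switch(strategy,
    half_life_equivalence = phase$v_start^2 / phase$v_end,
    reflection = 2 * phase$v_start - phase$v_end,
    literal = phase$v_start + phase$v_start^2 / (phase$v_start - phase$v_end))
  volume_phase(phase$v_start, v_end, phase$duration)
}

#' Effective kinetics of a (possibly multi-phase) trajectory
#'
#' Virtualizes every shrink phase, then aggregates with the time-weighted
#' rate: total virtual log-volume change over total duration. Returns a
#' single growth constant and doubling time for the arm.
#'
#' @param traj A \code{\link{trajectory}}.
#' @param strategy Virtualization strategy passed to \code{\link{virtualize}}.
#' @return An object of class \code{kinetics}: \code{rate} (1/s),
#'   \code{t_d} (s), \code{t_half} (s, NA unless the net trajectory
#'   shrinks), \code{virtual} flag, \code{strategy}.
#' @export
effective_kinetics <- function(traj, strategy = virtual_strategies) {
  stopifnot(inherits(traj, "trajectory"))
  strategy <- match.arg(strategy)
  if (all(vapply(traj$phases, function(p) p$direction == "static", logical(1))))
    stop("all-static trajectory: kinetics degenerate")
  virtual <- FALSE
  logsum <- 0
  for (p in traj$phases) {
    if (p$direction == "static") next  # contributes no log-volume change
    if (p$direction == "shrink") {
      p <- virtualize(p, strategy)
      virtual <- TRUE
    }
    logsum <- logsum + (log(p$v_end) - log(p$v_start))
  }
  dur <- total_duration(traj)
  rate <- logsum / dur
  structure(list(rate = rate,
                 t_d = if (rate > 0) LN2 / rate else NA_real_,
                 t_half = if (rate < 0) -LN2 / rate else NA_real_,
                 virtual = virtual,
                 strategy = strategy),
            class = "kinetics")
}

#' @export
print.kinetics <- function(x, ...) {
  cat(sprintf("<kinetics> rate %.4g /s; tD %.4g d%s%s\n",
              x$rate, x$t_d / SECONDS_PER_DAY,
              if (isTRUE(x$virtual)) " (virtual growth)" else "",
              sprintf(" [%s]", x$strategy)))
  invisible(x)
}

# total virtualized log-volume change of a trajectory
virtual_log_change <- function(traj, strategy) {
  k <- effective_kinetics(traj, strategy)
  k$rate * total_duration(traj)
}

#' Intraday doubling time at an intermediate time
#'
#' Under the exponential model with fixed initial and final volumes, the
#' doubling time evaluated at elapsed time t is linear in t:
#' \eqn{t_D(t) = \ln 2 \cdot t / (\ln V_{final} - \ln V_{initial})}.
#' For multi-phase or shrinking trajectories the whole-trajectory
#' virtualized log-volume change takes the place of the denominator
#' (\code{scope = "whole"}, the default). With \code{scope = "phase"} the
#' endpoints of the phase containing t are used instead, which makes the
#' evaluation sensitive to within-window kinetic changes.
#'
#' @param traj A \code{\link{trajectory}}.
#' @param t Elapsed time in seconds, 0 < t <= total duration.
#' @param strategy Virtualization strategy for shrink phases.
#' @param scope \code{"whole"} (default) or \code{"phase"}.
#' @return Doubling time in seconds at elapsed time t.
#' @examples
#' tr <- parse_phase_string("0.1->0.42@24.5d")
#' t_d_intraday(tr, 24.5 * 86400) / 86400  # ~11.83 days
#' @export
t_d_intraday <- function(traj, t, strategy = virtual_strategies,
                         scope = c("whole", "phase")) {
  stopifnot(inherits(traj, "trajectory"), is.numeric(t), length(t) == 1L)
  strategy <- match.arg(strategy)
  scope <- match.arg(scope)
  dur <- total_duration(traj)
  if (!is.finite(t) || t <= 0 || t > dur)
    stop(sprintf("t must lie in (0, %g] seconds", dur))
  if (scope == "whole") {
    L <- virtual_log_change(traj, strategy)
  } else {
    elapsed <- 0
    L <- NA_real_
    for (p in traj$phases) {
      if (t <= elapsed + p$duration || identical(p, traj$phases[[length(traj$phases)]])) {
        if (p$direction == "static")
          stop("phase containing t is static: doubling time undefined")
        if (p$direction == "shrink") p <- virtualize(p, strategy)
        L <- log(p$v_end) - log(p$v_start)
        break
      }
      elapsed <- elapsed + p$duration
    }
  }
  if (L <= 0) stop("non-growing (virtualized) trajectory: doubling time undefined")
  LN2 * t / L
}
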