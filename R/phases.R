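#' A monotone volume phase
#'
#' One monotone segment of a tumor-volume trajectory: a start volume, an end
#' volume and a duration. The direction label (\code{grow}, \code{shrink},
#' \code{static}) is derived from the volumes.
#'
#' @param v_start Start volume in cm^3, > 0.
#' @param v_end End volume in cm^3, > 0.
#' @param duration Phase duration in seconds, > 0.
#' @return An object of class \code{volume_phase}.
#' @examples
#' volume_phase(0.1, 1.2, 3.5 * 604800)
#' @export
volume_phase <- function(v_start, v_end, duration) {
  stopifnot(is.numeric(v_start), length(v_start) == 1L,
            is.numeric(v_end), length(v_end) == 1L,
            is.numeric(duration), length(duration) == 1L)
  if (!is.finite(v_start) || v_start <= 0) stop("v_start must be a positive volume (cm^3)")
  if (!is.finite(v_end) || v_end <= 0) stop("v_end must be a positive volume (cm^3)")
  if (!is.finite(duration) || duration <= 0) stop("duration must be positive (seconds)")
  direction <- if (v_end > v_start) "grow" else if (v_end < v_start) "shrink" else "static"
  structure(list(v_start = v_start, v_end = v_end, duration = duration,
                 direction = direction),
            class = "volume_phase")
}

#' @export
print.volume_phase <- function(x, ...) {
  cat(sprintf("<volume_phase> %s: %g -> %g cm^3 over %g d\n",
              x$direction, x$v_start, x$v_end, x$duration / SECONDS_PER_DAY))
  invisible(x)
}

#' A tumor-volume trajectory
#'
#' An ordered list of volume phases belonging to one study arm. Adjacent
#' phases must be volume-contiguous: each phase starts at the volume where
#' the previous one ended (exact on the supplied values).
#'
#' @param phases List of \code{\link{volume_phase}} objects, non-empty.
#' @param arm Arm label, \code{"control"} or \code{"treated"}.
#' @return An object of class \code{trajectory}.
#' @export
trajectory <- function(phases, arm = c("control", "treated")) {
  arm <- match.arg(arm)
  if (length(phases) == 0L) stop("trajectory requires at least one phase")
  ok <- vapply(phases, inherits, logical(1), what = "volume_phase")
  if (!all(ok)) stop("all phases must be volume_phase objects")
  if (length(phases) > 1L) {
    for (k in seq_len(length(phases) - 1L)) {
      if (phases[[k]]$v_end != phases[[k + 1L]]$v_start) {
        stop(sprintf("phases %d and %d are not volume-contiguous (%g != %g)",
                     k, k + 1L, phases[[k]]$v_end, phases[[k + 1L]]$v_start))
      }
    }
  }
  structure(list(phases = phases, arm = arm), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> arm=%s, %d phase(s), total %g d: %s\n",
              x$arm, length(x$phases),
              total_duration(x) / SECONDS_PER_DAY, format_phase_string(x)))
  invisible(x)
}

#' Total duration of a trajectory in seconds
#' @param traj A \code{\link{trajectory}}.
#' @export
total_duration <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  sum(vapply(traj$phases, `[[`, numeric(1), "duration"))
}

# parse one "<v0>-><v1>@<n><unit>" token into a volume_phase
parse_one_phase <- function(token) {
  m <- regmatches(token, regexec(
    "^\\s*([0-9]*\\.?[0-9]+)\\s*->\\s*([0-9]*\\.?[0-9]+)\\s*@\\s*([0-9]*\\.?[0-9]+)\\s*([dw])\\s*$",
    token))[[1]]
  if (length(m) == 0L) {
    stop(sprintf("malformed phase token '%s' (expected '<v0>-><v1>@<n><d|w>')", token))
  }
  scale <- if (m[5] == "w") SECONDS_PER_WEEK else SECONDS_PER_DAY
  volume_phase(as.numeric(m[2]), as.numeric(m[3]), as.numeric(m[4]) * scale)
}

#' Parse a trajectory description string
#'
#' The mini-grammar is \code{<v0>-><v1>@<n><unit>} with \code{;}-separated
#' phases; volumes in cm^3, \code{unit} is \code{d} (days) or \code{w}
#' (weeks; 1 w = 7 d, 1 d = 86,400 s). Durations are stored in seconds.
#'
#' @param text Phase string, e.g. \code{"0.15->0.09@6d;0.09->0.17@8d"}.
#' @param arm Arm label for the resulting trajectory.
#' @return A \code{\link{trajectory}}; phase contiguity is enforced.
#' @examples
#' parse_phase_string("0.1->1.2@3.5w")
#' parse_phase_string("0.15->0.09@6d;0.09->0.17@8d", arm = "treated")
#' @export
parse_phase_string <- function(text, arm = c("control", "treated")) {
  arm <- match.arg(arm)
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- strsplit(text, ";", fixed = TRUE)[[1]]
  if (length(tokens) == 0L || !nzchar(trimws(text))) stop("empty phase string")
  phases <- lapply(tokens, parse_one_phase)
  trajectory(phases, arm = arm)
}

#' Canonical phase-string form of a trajectory
#'
#' Inverse of \code{\link{parse_phase_string}} up to unit canonicalization:
#' durations are always rendered in days, so
#' \code{format_phase_string(parse_phase_string(x))} is the canonical form
#' of \code{x} and parses back to the identical trajectory.
#'
#' @param traj A \code{\link{trajectory}}.
#' @return A single string in the phase grammar.
#' @export
format_phase_string <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  paste(vapply(traj$phases, function(p) {
    sprintf("%s->%s@%sd",
            format(p$v_start, digits = 15, scientific = FALSE),
            format(p$v_end, digits = 15, scientific = FALSE),
            format(p$duration / SECONDS_PER_DAY, digits = 15, scientific = FALSE))
  }, character(1)), collapse = ";")
}
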