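#' A dosing schedule
#'
#' Explicit representation of a regimen: per-injection dose, the ordered
#' injection times in seconds from therapy start, the nominal dose count
#' implied by the regimen wording (rate x stated duration, so it may be
#' fractional, e.g. "thrice weekly for 3.5 weeks" implies 10.5 doses), and
#' the schedule class.
#'
#' @param dose_per_injection Dose per injection in mg/kg, > 0.
#' @param injection_times Strictly increasing injection times in seconds,
#'   first >= 0.
#' @param n_doses_nominal Nominal dose count from the regimen wording;
#'   defaults to \code{length(injection_times)}.
#' @param text Original regimen text, if any.
#' @return An object of class \code{regimen_spec} with a
#'   \code{schedule_class} field from \code{\link{classify_schedule}}.
#' @export
regimen_spec <- function(dose_per_injection, injection_times,
                         n_doses_nominal = length(injection_times),
                         text = NA_character_) {
  if (!is.numeric(dose_per_injection) || dose_per_injection <= 0)
    stop("dose_per_injection must be > 0 (mg/kg)")
  if (length(injection_times) < 1L) stop("at least one injection time required")
  if (any(injection_times < 0)) stop("injection times must be >= 0")
  if (is.unsorted(injection_times, strictly = TRUE))
    stop("injection times must be strictly increasing")
  spec <- structure(list(dose_per_injection = as.numeric(dose_per_injection),
                         injection_times = as.numeric(injection_times),
                         n_doses_nominal = as.numeric(n_doses_nominal),
                         schedule_class = NA_character_,
                         text = text),
                    class = "regimen_spec")
  spec$schedule_class <- classify_schedule(spec)
  spec
}

#' @export
print.regimen_spec <- function(x, ...) {
  cat(sprintf("<regimen_spec> %g mg/kg x %d injection(s) (%s), days %s\n",
              x$dose_per_injection, length(x$injection_times),
              x$schedule_class,
              paste(signif(x$injection_times / SECONDS_PER_DAY, 4),
                    collapse = ", ")))
  invisible(x)
}

word_to_int <- c(one = 1, two = 2, three = 3, four = 4, five = 5, six = 6,
                 seven = 7, eight = 8, nine = 9, ten = 10)

count_from <- function(s) {
  s <- tolower(s)
  if (s %in% names(word_to_int)) unname(word_to_int[s]) else as.numeric(s)
}

num_re <- "([0-9]*\\.?[0-9]+)"

# uniform injection times: n_discrete doses every `period` days from day 0
uniform_days <- function(period, n) period * (seq_len(ceiling(n)) - 1)

#' Parse a regimen description
#'
#' Understands the phrasings used in the packaged treatment table (explicit
#' dose days, "thrice weekly", "/week", "/2 weeks", "twice a week", "every
#' 3rd day") and expands them to an explicit injection-time list starting at
#' day 0 with uniform spacing where the text only gives a rate. Injections
#' scheduled after \code{observation_span} are dropped with a warning (the
#' nominal dose count, used by the dose-column audit, is not truncated).
#'
#' @param text Regimen description.
#' @param observation_span Observation window in seconds, or NULL for no
#'   truncation.
#' @return A \code{\link{regimen_spec}}.
#' @examples
#' parse_regimen("10 mg/kg on days 14, 18 and 22")
#' parse_regimen("15 mg/kg/2 weeks for 4 weeks")
#' @export
parse_regimen <- function(text, observation_span = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- tolower(trimws(text))
  dose <- NA_real_; days <- NULL; nominal <- NA_real_

  # "<k> doses of N mg/kg on days a and b" / "N mg/kg on days a, b and c"
  m <- regmatches(txt, regexec(paste0(
    "^(?:(\\w+) doses of )?", num_re,
    " mg/kg on days ([0-9]+(?:\\s*(?:,|and)\\s*[0-9]+)*)$"), txt))[[1]]
  if (length(m)) {
    dose <- as.numeric(m[3])
    days <- as.numeric(regmatches(m[4], gregexpr("[0-9]+", m[4]))[[1]])
    nominal <- length(days)
  }
  # "<k> doses of N mg/kg on M days" (evenly spread over M days)
  if (is.null(days)) {
    m <- regmatches(txt, regexec(paste0(
      "^(\\w+) doses of ", num_re, " mg/kg on ", num_re, " days$"), txt))[[1]]
    if (length(m)) {
      k <- count_from(m[2]); dose <- as.numeric(m[3]); span_d <- as.numeric(m[4])
      days <- seq(0, span_d, length.out = k)
      nominal <- k
    }
  }
  # "<k> doses of N mg/kg/week" (weekly)
  if (is.null(days)) {
    m <- regmatches(txt, regexec(paste0(
      "^(\\w+) doses of ", num_re, " mg/kg/week$"), txt))[[1]]
    if (length(m)) {
      k <- count_from(m[2]); dose <- as.numeric(m[3])
      days <- 7 * (seq_len(k) - 1)
      nominal <- k
    }
  }
  # "N mg/kg [body weight] [given] [i.v.] every 3rd day (total of k doses)"
  if (is.null(days)) {
    m <- regmatches(txt, regexec(paste0(
      "^", num_re,
      " mg/kg.* every ([0-9]+)(?:st|nd|rd|th) day \\(total of (\\w+) doses\\)$"),
      txt))[[1]]
    if (length(m)) {
      dose <- as.numeric(m[2]); period <- as.numeric(m[3]); k <- count_from(m[4])
      days <- period * (seq_len(k) - 1)
      nominal <- k
    }
  }
  # "N mg/kg thrice weekly for W weeks" (every 7/3 days)
  if (is.null(days)) {
    m <- regmatches(txt, regexec(paste0(
      "^", num_re, " mg/kg thrice weekly for ", num_re, " weeks?$"), txt))[[1]]
    if (length(m)) {
      dose <- as.numeric(m[2]); weeks <- as.numeric(m[3])
      nominal <- 3 * weeks
      days <- uniform_days(7 / 3, nominal)
    }
  }
  # "N mg/kg per injection twice a week for W weeks" (every 3.5 days)
  if (is.null(days)) {
    m <- regmatches(txt, regexec(paste0(
      "^", num_re, " mg/kg(?: per injection)? twice a week for ", num_re,
      " weeks?$"), txt))[[1]]
    if (length(m)) {
      dose <- as.numeric(m[2]); weeks <- as.numeric(m[3])
      nominal <- 2 * weeks
      days <- uniform_days(3.5, nominal)
    }
  }
  # "N mg/kg/2 weeks for W weeks" (every 2 weeks from day 0)
  if (is.null(days)) {
    m <- regmatches(txt, regexec(paste0(
      "^", num_re, " mg/kg/2 weeks for ", num_re, " weeks?$"), txt))[[1]]
    if (length(m)) {
      dose <- as.numeric(m[2]); weeks <- as.numeric(m[3])
      nominal <- weeks / 2
      days <- uniform_days(14, nominal)
    }
  }
  # "N mg/kg/week for W weeks"
  if (is.null(days)) {
    m <- regmatches(txt, regexec(paste0(
      "^", num_re, " mg/kg/week for ", num_re, " weeks?$"), txt))[[1]]
    if (length(m)) {
      dose <- as.numeric(m[2]); weeks <- as.numeric(m[3])
      nominal <- weeks
      days <- uniform_days(7, nominal)
    }
  }
  if (is.null(days)) {
    stop(sprintf(paste("unrecognized regimen phrasing: '%s';",
                       "supply explicit injection_times via regimen_spec()"),
                 text))
  }
  times <- days * SECONDS_PER_DAY
  if (!is.null(observation_span)) {
    late <- times > observation_span
    if (any(late)) {
      warning(sprintf("%d injection(s) after the %.3g-day observation span dropped",
                      sum(late), observation_span / SECONDS_PER_DAY))
      times <- times[!late]
    }
    if (length(times) == 0L)
      stop("all injections fall after the observation span")
  }
  regimen_spec(dose, times, n_doses_nominal = nominal, text = text)
}
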