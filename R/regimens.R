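#' Dosing regimens
#'
#' A regimen is an ordered table of dose events. Each event delivers a
#' fraction of the total vaccine dose, either instantaneously (an impulse,
#' `duration = 0`) or at a constant rate over `[start_time, start_time +
#' duration]`. Events carry a `component` tag so that antigen and adjuvant
#' can follow different schedules (e.g. a bolus of adjuvant alongside an
#' escalating antigen series). Amounts are dimensionless fractions of the
#' total dose; within each component they sum to the configured total.
#'
#' @name regimens
NULL

.regimen_components <- c("antigen", "adjuvant", "both")

new_regimen <- function(events, label) {
  stopifnot(is.data.frame(events))
  required <- c("start_time", "amount", "duration", "component")
  if (!all(required %in% names(events))) {
    stop("regimen events need columns: ", paste(required, collapse = ", "))
  }
  events <- events[order(events$start_time), required, drop = FALSE]
  rownames(events) <- NULL
  if (any(events$amount <= 0)) stop("event amounts must be > 0")
  if (any(events$duration < 0)) stop("event durations must be >= 0")
  if (any(events$start_time < 0)) stop("event start times must be >= 0")
  if (!all(events$component %in% .regimen_components)) {
    stop("component must be one of: ", paste(.regimen_components, collapse = ", "))
  }
  structure(list(events = events, label = label), class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  cat("<regimen>", x$label, "\n")
  print(x$events, row.names = FALSE)
  invisible(x)
}

#' Total amount scheduled for one vaccine component
#'
#' @param regimen A `regimen`.
#' @param component `"antigen"` or `"adjuvant"`; events tagged `"both"`
#'   count towards either.
#' @return Sum of event amounts for that component.
#' @export
regimen_total <- function(regimen, component = c("antigen", "adjuvant")) {
  component <- match.arg(component)
  ev <- regimen$events
  sum(ev$amount[ev$component %in% c(component, "both")])
}

#' Single bolus immunization
#'
#' The full dose of antigen and adjuvant given together as one impulse at
#' day 0 — the traditional comparator regimen.
#'
#' @return A `regimen` with one impulse event of amount 1.
#' @export
make_bolus <- function() {
  new_regimen(
    data.frame(start_time = 0, amount = 1, duration = 0, component = "both"),
    label = "bolus"
  )
}

#' Exponentially escalating multi-dose regimen
#'
#' `n_doses` impulses at days `0, interval, ..., (n_doses - 1) * interval`,
#' with amounts proportional to `exp(k)` for injection index
#' `k = 0 .. n_doses - 1`, normalized so they sum to `total`. With seven
#' doses two days apart this places the final injection — 63% of the total
#' dose — on day 12.
#'
#' @param n_doses Number of injections (>= 1).
#' @param interval Days between injections (> 0 when `n_doses > 1`).
#' @param total Total amount delivered (default 1).
#' @param component Which component follows this schedule (default both).
#' @return A `regimen`.
#' @export
make_exponential_ed <- function(n_doses, interval = 2, total = 1,
                                component = "both") {
  if (!is.numeric(n_doses) || length(n_doses) != 1L || n_doses < 1 ||
      n_doses != round(n_doses)) {
    stop("n_doses must be a single integer >= 1")
  }
  if (n_doses > 1 && (!is.numeric(interval) || interval <= 0)) {
    stop("interval must be > 0 when n_doses > 1")
  }
  k <- seq_len(n_doses) - 1
  frac <- exp(k) / sum(exp(k))
  events <- data.frame(
    start_time = k * if (n_doses > 1) interval else 0,
    amount = frac * total,
    duration = 0,
    component = component
  )
  new_regimen(events, label = sprintf("%ded", n_doses))
}

#' Two-dose extended-prime regimen
#'
#' An initial priming impulse of `first_fraction` of the dose at day 0 and
#' the remainder `interval` days later. The optimized two-dose extended
#' prime ("2-ED") is `make_two_dose(0.2, 7)`: 20% at day 0, 80% at day 7.
#'
#' @param first_fraction Fraction of the total dose in the first injection,
#'   in (0, 1]. With `first_fraction = 1` the second event is omitted and
#'   the regimen is bolus-equivalent.
#' @param interval Days between the two injections.
#' @param component Which component follows this schedule (default both).
#' @return A `regimen`.
#' @export
make_two_dose <- function(first_fraction, interval = 7, component = "both") {
  if (!is.numeric(first_fraction) || length(first_fraction) != 1L ||
      first_fraction <= 0 || first_fraction > 1) {
    stop("first_fraction must lie in (0, 1]")
  }
  if (first_fraction == 1) {
    events <- data.frame(start_time = 0, amount = 1, duration = 0,
                         component = component)
  } else {
    events <- data.frame(
      start_time = c(0, interval),
      amount = c(first_fraction, 1 - first_fraction),
      duration = 0,
      component = component
    )
  }
  new_regimen(events, label = sprintf("2dose:%g:%g", first_fraction, interval))
}

#' Mismatched schedules: bolus adjuvant with escalating antigen
#'
#' All adjuvant as a single impulse at day 0 while antigen follows the
#' exponentially escalating series. Used to probe the requirement that
#' antigen availability be synchronized with adjuvant-driven DC
#' recruitment: late antigen doses arrive after the adjuvant has cleared,
#' so Tfh priming is predicted to be weak despite escalating antigen.
#'
#' @inheritParams make_exponential_ed
#' @return A `regimen` whose antigen and adjuvant events differ.
#' @export
make_mismatched_ed <- function(n_doses = 7, interval = 2, total = 1) {
  ag <- make_exponential_ed(n_doses, interval, total, component = "antigen")
  events <- rbind(
    ag$events,
    data.frame(start_time = 0, amount = total, duration = 0,
               component = "adjuvant")
  )
  new_regimen(events, label = sprintf("%ded-ag+bolus-adj", n_doses))
}

#' Convert one event to a constant-rate extended release
#'
#' Replaces the selected event by a zero-order release of the same total
#' amount over `[start_time, start_time + duration]`. Used for the "dose 2
#' extended" regimens, e.g. the second (80%) dose of the two-dose extended
#' prime released over 10 days from day 7.
#'
#' @param regimen A `regimen`.
#' @param event_index Row index of the event to modify (events are sorted
#'   by start time).
#' @param duration Release duration in days; `0` leaves the event an
#'   impulse.
#' @return A `regimen` with the modified event; total amount is unchanged.
#' @export
with_extended_release <- function(regimen, event_index, duration) {
  ev <- regimen$events
  if (!is.numeric(event_index) || length(event_index) != 1L ||
      event_index < 1 || event_index > nrow(ev) ||
      event_index != round(event_index)) {
    stop("event_index out of range: regimen has ", nrow(ev), " events")
  }
  if (!is.numeric(duration) || length(duration) != 1L || duration < 0) {
    stop("duration must be >= 0")
  }
  ev$duration[event_index] <- duration
  label <- if (duration > 0) {
    sprintf("%s-ext%g@%d", regimen$label, duration, as.integer(event_index))
  } else {
    regimen$label
  }
  new_regimen(ev, label = label)
}

#' Instantaneous input rate and impulses of a regimen
#'
#' Returns the continuous (zero-order release) input rate at time `t` for
#' a component, together with any impulse amounts occurring exactly at
#' `t`. The rate plus impulses integrate to the component's scheduled
#' total over any window containing all events. Release windows are
#' half-open, `[start, start + duration)`.
#'
#' @param regimen A `regimen`.
#' @param t Time in days (scalar, >= 0).
#' @param component `"antigen"` or `"adjuvant"`.
#' @return List with `rate` (amount/day) and `impulses` (numeric vector of
#'   impulse amounts landing exactly at `t`; empty if none).
#' @export
input_rate <- function(regimen, t, component = c("antigen", "adjuvant")) {
  component <- match.arg(component)
  stopifnot(is.numeric(t), length(t) == 1L, t >= 0)
  ev <- regimen$events
  ev <- ev[ev$component %in% c(component, "both"), , drop = FALSE]
  releasing <- ev$duration > 0 & t >= ev$start_time &
    t < ev$start_time + ev$duration
  rate <- sum(ev$amount[releasing] / ev$duration[releasing])
  at_t <- ev$duration == 0 & ev$start_time == t
  list(rate = rate, impulses = ev$amount[at_t])
}

# impulse events for a component: data.frame(time, amount); internal
.impulse_events <- function(regimen, component) {
  ev <- regimen$events
  ev <- ev[ev$component %in% c(component, "both") & ev$duration == 0, ,
           drop = FALSE]
  data.frame(time = ev$start_time, amount = ev$amount)
}

# continuous release rate at (vector) time t for a component; internal
.release_rate <- function(regimen, t, component) {
  ev <- regimen$events
  ev <- ev[ev$component %in% c(component, "both") & ev$duration > 0, ,
           drop = FALSE]
  if (nrow(ev) == 0L) return(rep(0, length(t)))
  out <- numeric(length(t))
  for (i in seq_len(nrow(ev))) {
    inside <- t >= ev$start_time[i] & t < ev$start_time[i] + ev$duration[i]
    out[inside] <- out[inside] + ev$amount[i] / ev$duration[i]
  }
  out
}

# all event boundary times (impulses + release window edges); internal
.event_times <- function(regimen) {
  ev <- regimen$events
  sort(unique(c(ev$start_time, ev$start_time + ev$duration)))
}

#' Look up a shipped regimen by shorthand name
#'
#' Understands `bolus`, `7ed`, `2ed`, `ned:<n>`, `2ed-ext:<days>`,
#' `2dose:<frac>:<interval>`, and `mismatch`. The n-dose escalating series
#' keeps the 12-day span, so `ned:<n>` uses interval `12 / (n - 1)`.
#'
#' @param name Shorthand string.
#' @return A `regimen`.
#' @export
regimen_by_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (name == "bolus") return(make_bolus())
  if (name == "7ed") return(make_exponential_ed(7, 2))
  if (name == "2ed") return(make_two_dose(0.2, 7))
  if (name == "mismatch") return(make_mismatched_ed(7, 2))
  parts <- strsplit(name, ":", fixed = TRUE)[[1]]
  if (parts[1] == "ned" && length(parts) == 2L) {
    n <- as.integer(parts[2])
    if (is.na(n) || n < 1) stop("bad dose count in ", name)
    return(make_exponential_ed(n, if (n > 1) 12 / (n - 1) else 2))
  }
  if (parts[1] == "2ed-ext" && length(parts) == 2L) {
    d <- as.numeric(parts[2])
    if (is.na(d) || d < 0) stop("bad release duration in ", name)
    return(with_extended_release(make_two_dose(0.2, 7), 2, d))
  }
  if (parts[1] == "2dose" && length(parts) == 3L) {
    f <- as.numeric(parts[2]); iv <- as.numeric(parts[3])
    if (is.na(f) || is.na(iv)) stop("bad 2dose spec in ", name)
    return(make_two_dose(f, iv))
  }
  stop("unknown regimen name: ", name,
       " (try bolus, 7ed, 2ed, mismatch, ned:<n>, 2ed-ext:<days>, ",
       "2dose:<frac>:<interval>)")
}

#' Serialize / deserialize a regimen as a plain-text config
#'
#' The on-disk form is a JSON object with a `label` and a list of events
#' `{day, fraction, duration_days, component}`.
#'
#' @param regimen A `regimen`.
#' @param path File path to write to / read from.
#' @return `write_regimen` returns `path` invisibly; `read_regimen`
#'   returns the `regimen`.
#' @export
write_regimen <- function(regimen, path) {
  ev <- regimen$events
  obj <- list(
    label = regimen$label,
    events = data.frame(day = ev$start_time, fraction = ev$amount,
                        duration_days = ev$duration,
                        component = ev$component)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_regimen
#' @export
read_regimen <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- obj$events
  new_regimen(
    data.frame(start_time = ev$day, amount = ev$fraction,
               duration = ev$duration_days, component = ev$component),
    label = obj$label %||% "regimen"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
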